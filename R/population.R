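# Fibre populations: container, synthetic generation, CSV I/O.
# Lengths are always micrometres (um) internally.

#' Fibre population
#'
#' A bag of fibre lengths in um with an optional label. Thin container used
#' by the simulators and the binning functions, which also accept bare
#' numeric vectors.
#'
#' @param lengths Numeric vector of fibre lengths in um, all `> 0`.
#' @param label Free-text label (e.g. sample name or time point).
#' @return An object of class `fibre_population` with fields `lengths`,
#'   `label` and `unit` (always `"um"`).
#' @export
fibre_population <- function(lengths, label = "") {
  lengths <- as.numeric(lengths)
  check_positive_length(lengths)
  structure(list(lengths = lengths, label = label, unit = "um"),
            class = "fibre_population")
}

#' @export
print.fibre_population <- function(x, ...) {
  cat(sprintf("Fibre population%s: %d fibres, total length %.4g mm\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$lengths), sum(x$lengths) / 1000))
  if (length(x$lengths)) {
    q <- stats::quantile(x$lengths, c(0, .25, .5, .75, 1))
    cat(sprintf("  length (um): min %.3g, median %.3g, max %.3g\n",
                q[1], q[3], q[5]))
  }
  invisible(x)
}

#' @export
length.fibre_population <- function(x) length(x$lengths)

as_lengths <- function(x) {
  if (inherits(x, "fibre_population")) x$lengths else as.numeric(x)
}

#' Synthetic initial fibre population
#'
#' Emulates razor-cut flax fibre bundles before hydrolysis: a majority of
#' intact segments uniform on 3--7 mm plus a log-normal fines fraction
#' (debris and short fibres already present at 0 h). Fines are capped at
#' the top of the intact range.
#'
#' @param n_fibres Number of fibres to draw.
#' @param intact_fraction Expected fraction of intact (uniform) segments;
#'   the realised intact count is binomial.
#' @param intact_range Length range of intact segments, um.
#' @param fines_log_median Median of the log-normal fines lengths, um.
#' @param fines_log_sigma Log-scale standard deviation of the fines.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param label Label passed to [fibre_population()].
#' @return A [fibre_population()].
#' @examples
#' pop <- synthetic_population(1000, seed = 1)
#' pop
#' @export
synthetic_population <- function(n_fibres,
                                 intact_fraction = 0.8,
                                 intact_range = c(3000, 7000),
                                 fines_log_median = 500,
                                 fines_log_sigma = 0.8,
                                 seed = NULL,
                                 label = "synthetic") {
  if (n_fibres < 0) stop("`n_fibres` must be >= 0", call. = FALSE)
  if (intact_fraction < 0 || intact_fraction > 1) {
    stop("`intact_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (length(intact_range) != 2 || any(intact_range <= 0) ||
      intact_range[1] >= intact_range[2]) {
    stop("`intact_range` must be (min, max) with 0 < min < max",
         call. = FALSE)
  }
  if (fines_log_median <= 0 || fines_log_sigma <= 0) {
    stop("fines parameters must be > 0", call. = FALSE)
  }
  with_seed(seed, {
    n_intact <- stats::rbinom(1, n_fibres, intact_fraction)
    intact <- stats::runif(n_intact, intact_range[1], intact_range[2])
    fines <- stats::rlnorm(n_fibres - n_intact,
                           meanlog = log(fines_log_median),
                           sdlog = fines_log_sigma)
    fines <- pmin(fines, intact_range[2])
    fibre_population(c(intact, fines), label = label)
  })
}

#' Read a fibre length table
#'
#' One-column CSV with a header declaring the unit (`length_um` or
#' `length_mm`) and one strictly positive numeric value per row, as
#' exported by automated fibre image analysis. Millimetre inputs are
#' converted to um.
#'
#' @param path Path to the CSV file.
#' @param label Label for the population; defaults to the file name.
#' @return A [fibre_population()] (lengths in um).
#' @export
read_lengths <- function(path, label = basename(path)) {
  tab <- utils::read.csv(path, colClasses = "character",
                         strip.white = TRUE)
  unit_col <- names(tab)[1]
  scale <- switch(unit_col,
                  length_um = 1,
                  length_mm = 1000,
                  stop("unknown unit header '", unit_col,
                       "': expected 'length_um' or 'length_mm'",
                       call. = FALSE))
  vals <- suppressWarnings(as.numeric(tab[[1]]))
  bad <- which(is.na(vals) | vals <= 0)
  if (length(bad)) {
    stop(sprintf(
      "row %d of '%s' is not a positive number: '%s'",
      bad[1], path, tab[[1]][bad[1]]), call. = FALSE)
  }
  fibre_population(vals * scale, label = label)
}

#' Write a fibre length table
#'
#' Inverse of [read_lengths()]: one `length_um` column, one fibre per row.
#'
#' @param population A [fibre_population()] or numeric vector of um lengths.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_lengths <- function(population, path) {
  lengths <- as_lengths(population)
  check_positive_length(lengths)
  utils::write.csv(data.frame(length_um = lengths), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Evaluate `code` under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
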