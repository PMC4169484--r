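# Length-weighted binning into length classes, and ordered series of
# binned distributions. Bin edges are in mm (reporting convention);
# fibre lengths are in um.

#' Default length-class edges (mm)
#'
#' The standard reporting classes: long intact segments 3--7 mm, medium
#' 0.5--3 mm, and two short classes below 0.5 mm split at 0.25 mm.
#' @return Numeric vector of bin edges in mm.
#' @export
default_bin_edges <- function() c(0, 0.25, 0.5, 3, 7)

#' Bin fibre lengths into length classes
#'
#' Computes the share of each length class, length-weighted by default:
#' the fraction of total fibre length (not fibre count) falling in each
#' class, the statistic used to report hydrolysis progress. Bins are
#' half-open `[a, b)` with the last bin closed; lengths above the top edge
#' are folded into the last bin and flagged.
#'
#' @param lengths Fibre lengths in um ([fibre_population()] or numeric).
#' @param bin_edges Ascending bin edges in mm, at least two.
#' @param weight `"length"` (share of total length, default) or `"count"`
#'   (share of fibre count).
#' @return An object of class `length_distribution` with fields
#'   `bin_edges` (mm), `shares`, `weight`, `n_fibres`, `total_length_um`,
#'   `overflow` (any length above the top edge) and `empty`.
#' @examples
#' bin_length_weighted(c(1000, 2000, 3000))  # shares 0, 0, 0.5, 0.5
#' @export
bin_length_weighted <- function(lengths, bin_edges = default_bin_edges(),
                                weight = c("length", "count")) {
  weight <- match.arg(weight)
  lengths <- as_lengths(lengths)
  if (length(bin_edges) < 2 || is.unsorted(bin_edges, strictly = TRUE)) {
    stop("`bin_edges` must be >= 2 strictly ascending values (mm)",
         call. = FALSE)
  }
  n_bins <- length(bin_edges) - 1L
  if (length(lengths) == 0) {
    return(new_length_distribution(bin_edges, rep(0, n_bins), weight,
                                   n_fibres = 0L, total = 0,
                                   overflow = FALSE, empty = TRUE))
  }
  check_positive_length(lengths)
  edges_um <- bin_edges * 1000
  if (any(lengths < edges_um[1])) {
    stop("fibre length below the first bin edge", call. = FALSE)
  }
  bin <- findInterval(lengths, edges_um, rightmost.closed = TRUE)
  overflow <- any(bin > n_bins)
  bin[bin > n_bins] <- n_bins
  w <- if (weight == "length") lengths else rep(1, length(lengths))
  tot <- vapply(seq_len(n_bins),
                function(i) sum(w[bin == i]), numeric(1))
  new_length_distribution(bin_edges, tot / sum(w), weight,
                          n_fibres = length(lengths),
                          total = sum(lengths),
                          overflow = overflow, empty = FALSE)
}

new_length_distribution <- function(bin_edges, shares, weight, n_fibres,
                                    total, overflow, empty) {
  structure(
    list(bin_edges = bin_edges, shares = as.numeric(shares),
         weight = weight, n_fibres = n_fibres, total_length_um = total,
         overflow = overflow, empty = empty),
    class = "length_distribution"
  )
}

#' @export
print.length_distribution <- function(x, digits = 3, ...) {
  n <- length(x$shares)
  lab <- sprintf("[%g, %g%s mm", x$bin_edges[-(n + 1)], x$bin_edges[-1],
                 c(rep(")", n - 1), "]"))
  cat(sprintf("Length distribution (%s-weighted, %d fibres%s):\n",
              x$weight, x$n_fibres,
              if (x$overflow) ", overflow folded into top bin" else ""))
  print(stats::setNames(round(x$shares, digits), lab))
  invisible(x)
}

#' @export
as.data.frame.length_distribution <- function(x, ...) {
  n <- length(x$shares)
  data.frame(bin_lower_mm = x$bin_edges[-(n + 1)],
             bin_upper_mm = x$bin_edges[-1],
             share = x$shares)
}

#' Ordered series of binned length distributions
#'
#' Distributions at successive steps (or time points) on a common set of
#' bin edges; the unit of comparison for stagnation detection and
#' calibration.
#'
#' @param labels Strictly increasing numeric labels (step indices or
#'   hours).
#' @param distributions List of [bin_length_weighted()] results sharing
#'   identical bin edges.
#' @return An object of class `distribution_series`.
#' @export
distribution_series <- function(labels, distributions) {
  if (length(labels) != length(distributions)) {
    stop("`labels` and `distributions` must have equal length",
         call. = FALSE)
  }
  if (length(labels) && is.unsorted(labels, strictly = TRUE)) {
    stop("`labels` must be strictly increasing", call. = FALSE)
  }
  edges <- lapply(distributions, `[[`, "bin_edges")
  if (length(edges) > 1 &&
      !all(vapply(edges[-1], function(e) isTRUE(all.equal(e, edges[[1]])),
                  logical(1)))) {
    stop("all distributions in a series must share bin edges",
         call. = FALSE)
  }
  structure(list(labels = as.numeric(labels),
                 distributions = distributions),
            class = "distribution_series")
}

#' @export
length.distribution_series <- function(x) length(x$labels)

#' @export
print.distribution_series <- function(x, ...) {
  cat(sprintf("Distribution series: %d entries, labels %s..%s\n",
              length(x$labels),
              if (length(x$labels)) min(x$labels) else "-",
              if (length(x$labels)) max(x$labels) else "-"))
  invisible(x)
}

#' @export
as.data.frame.distribution_series <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$labels), function(i) {
    d <- as.data.frame(x$distributions[[i]])
    cbind(label = x$labels[i], d)
  }))
}

#' Write / read a distribution series as long-format CSV
#'
#' Columns `label`, `bin_lower_mm`, `bin_upper_mm`, `share`, one row per
#' (entry, bin).
#'
#' @param series A [distribution_series()].
#' @param path CSV path.
#' @return `write_distribution_series()` returns `path` invisibly;
#'   `read_distribution_series()` returns a [distribution_series()].
#' @export
write_distribution_series <- function(series, path) {
  stopifnot(inherits(series, "distribution_series"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_distribution_series
#' @export
read_distribution_series <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("label", "bin_lower_mm", "bin_upper_mm", "share")
  if (!all(need %in% names(tab))) {
    stop("series CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  labs <- sort(unique(tab$label))
  dists <- lapply(labs, function(l) {
    rows <- tab[tab$label == l, ]
    rows <- rows[order(rows$bin_lower_mm), ]
    edges <- c(rows$bin_lower_mm, rows$bin_upper_mm[nrow(rows)])
    new_length_distribution(edges, rows$share, weight = "length",
                            n_fibres = NA_integer_, total = NA_real_,
                            overflow = FALSE, empty = all(rows$share == 0))
  })
  distribution_series(labs, dists)
}
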