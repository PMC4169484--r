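# Comparison of binned distributions, stagnation detection and
# grid-search calibration of the weakening schedule.

#' Total-variation distance between two binned distributions
#'
#' `0.5 * sum(|p_i - q_i|)` over shared bins: the smallest fraction of
#' length-share that would have to move between classes to turn one
#' distribution into the other. Bounded in `[0, 1]`, symmetric, zero iff
#' the shares are equal.
#'
#' @param d1,d2 [bin_length_weighted()] results with identical bin edges.
#' @return Distance in `[0, 1]`.
#' @export
distribution_distance <- function(d1, d2) {
  stopifnot(inherits(d1, "length_distribution"),
            inherits(d2, "length_distribution"))
  if (!isTRUE(all.equal(d1$bin_edges, d2$bin_edges))) {
    stop("distributions must share identical bin edges", call. = FALSE)
  }
  0.5 * sum(abs(d1$shares - d2$shares))
}

#' Detect stagnation in a distribution series
#'
#' The length distribution has stagnated once it stops changing: this
#' returns the label of the first entry `s` such that every consecutive
#' pair among entries `s, s+1, ..., s+patience` is closer than `tol` in
#' total variation. The patience window prevents a single-step coincidence
#' from registering as a plateau.
#'
#' @param series A [distribution_series()] with at least 2 entries.
#' @param tol Total-variation tolerance, `> 0`.
#' @param patience Number of consecutive sub-`tol` distances required.
#' @return The label at which stagnation begins, or `NA` if the series
#'   never stagnates within its horizon.
#' @export
detect_stagnation <- function(series, tol = 0.01, patience = 2) {
  stopifnot(inherits(series, "distribution_series"))
  n <- length(series$labels)
  if (n < 2) stop("series must have at least 2 entries", call. = FALSE)
  if (tol <= 0) stop("`tol` must be > 0", call. = FALSE)
  if (patience < 1) stop("`patience` must be >= 1", call. = FALSE)
  d <- vapply(seq_len(n - 1), function(i) {
    distribution_distance(series$distributions[[i]],
                          series$distributions[[i + 1]])
  }, numeric(1))
  below <- d < tol
  for (s in seq_len(n - patience)) {
    if (all(below[s:(s + patience - 1)])) return(series$labels[s])
  }
  NA_real_
}

#' Calibrate the weakening schedule by grid search
#'
#' Scores every combination of candidate initial M_u/P, decay factor and
#' floor against an observed distribution series: each grid point is
#' simulated with [run_attrition()] from `initial_lengths` under
#' `replicates` seeds, the trajectory is binned on the observed series'
#' bin edges, simulated steps are aligned to observed labels by position
#' (step 0 to the first label, and so on; excess simulated steps are
#' dropped, missing ones padded with the terminal distribution), and the
#' objective is the per-label total-variation distance averaged over
#' labels and replicates. Combinations with `floor > initial` are invalid
#' and recorded with `NA` objective.
#'
#' @param observed A [distribution_series()] of observed (or reference)
#'   binned distributions.
#' @param initial_lengths The starting population the simulations run
#'   from, as in [run_attrition()].
#' @param initial_grid,decay_grid,floor_grid Candidate values for the
#'   three [weakening_schedule()] fields.
#' @param config A [sim_config()]; replicate seeds are derived from
#'   `config$seed`.
#' @param replicates Simulation replicates per grid point.
#' @return An object of class `calibration_result`: `best` (named list of
#'   the argmin schedule), `objective`, `grid` (data frame of all
#'   evaluated points with objectives) and `seeds`.
#' @export
calibrate_schedule <- function(observed, initial_lengths,
                               initial_grid, decay_grid, floor_grid,
                               config = sim_config(),
                               replicates = 2) {
  stopifnot(inherits(observed, "distribution_series"))
  if (!length(initial_grid) || !length(decay_grid) ||
      !length(floor_grid)) {
    stop("all three grids must be non-empty", call. = FALSE)
  }
  if (!length(observed)) {
    stop("`observed` series must be non-empty", call. = FALSE)
  }
  edges <- observed$distributions[[1]]$bin_edges
  base_seed <- config$seed %||% 0L
  seeds <- base_seed + seq_len(replicates)
  grid <- expand.grid(initial_mu_over_p = initial_grid,
                      decay_factor = decay_grid,
                      floor_mu_over_p = floor_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$objective <- vapply(seq_len(nrow(grid)), function(i) {
    if (grid$floor_mu_over_p[i] > grid$initial_mu_over_p[i]) {
      return(NA_real_)
    }
    sched <- weakening_schedule(grid$initial_mu_over_p[i],
                                grid$decay_factor[i],
                                grid$floor_mu_over_p[i])
    mean(vapply(seeds, function(s) {
      cfg <- sim_config(config$min_active_to_continue, config$max_steps,
                        seed = s)
      traj <- run_attrition(initial_lengths, sched, cfg)
      sim <- trajectory_series(traj, bin_edges = edges)
      series_objective(observed, sim)
    }, numeric(1)))
  }, numeric(1))
  best_i <- which.min(grid$objective)
  structure(
    list(best = as.list(grid[best_i, c("initial_mu_over_p",
                                       "decay_factor",
                                       "floor_mu_over_p")]),
         objective = grid$objective[best_i],
         grid = grid,
         seeds = seeds),
    class = "calibration_result"
  )
}

# Mean per-position TV distance of `sim` against `observed`; `sim`
# truncated or padded with its terminal distribution to match.
series_objective <- function(observed, sim) {
  n_obs <- length(observed)
  n_sim <- length(sim)
  mean(vapply(seq_len(n_obs), function(i) {
    j <- min(i, n_sim)
    distribution_distance(observed$distributions[[i]],
                          sim$distributions[[j]])
  }, numeric(1)))
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "Calibration over %d grid points (%d replicate seeds):\n",
    nrow(x$grid), length(x$seeds)))
  cat(sprintf(
    "  best schedule: initial %g, decay %g, floor %g (objective %.4g)\n",
    x$best$initial_mu_over_p, x$best$decay_factor,
    x$best$floor_mu_over_p, x$objective))
  invisible(x)
}

#' Serialise a calibration result to JSON
#'
#' @param result A [calibrate_schedule()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(result, path) {
  stopifnot(inherits(result, "calibration_result"))
  jsonlite::write_json(
    list(best = result$best, objective = result$objective,
         seeds = result$seeds, grid = result$grid),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
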