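# Step-wise stochastic attrition simulator and the random-segmentation
# null model. Each step emulates one round of free-fall mixing impacts:
# every active fibre draws one uniform load point; fibres too short to
# break are retired, fibres whose load point falls inside the probable
# failure region are cut in two, all others pass unchanged.

#' One attrition step
#'
#' Applies the mechanical break/pass/retire rule to a set of active fibre
#' lengths at a fixed strength M_u/P. Fibres with breakability ratio > 1
#' are retired (too short to break). Each remaining fibre, in input order,
#' draws one uniform number `u` from the current RNG stream; the candidate
#' break point is `u * length`, and if it falls inside the closed PFR
#' interval the fibre is replaced, in place, by its two halves. Total
#' length is conserved and every new fragment has length `>= mu_over_p`
#' (both ends of the PFR are at least that far from the fibre ends).
#'
#' @param active_lengths Numeric vector of active fibre lengths, um.
#' @param mu_over_p Strength-to-force ratio M_u/P for this step, um.
#' @return A list: `forwarded` (lengths entering the next step, input
#'   order preserved, broken fibres replaced by their halves),
#'   `newly_retired`, `fragments` (the halves created this step) and
#'   `counts` (named integer vector `broken`, `passed`, `retired`).
#' @export
attrition_step <- function(active_lengths, mu_over_p) {
  active_lengths <- as_lengths(active_lengths)
  check_positive_length(active_lengths)
  check_mu_over_p(mu_over_p)
  if (length(active_lengths) == 0) {
    return(list(forwarded = numeric(0), newly_retired = numeric(0),
                fragments = numeric(0),
                counts = c(broken = 0L, passed = 0L, retired = 0L)))
  }
  breakable <- is_breakable(active_lengths, mu_over_p)
  retired <- active_lengths[!breakable]
  len <- active_lengths[breakable]
  u <- stats::runif(length(len))
  point <- u * len
  bounds <- pfr_bounds(len, mu_over_p)
  hit <- point >= bounds$lower & point <= bounds$upper
  # interleave: each broken fibre contributes its two halves in place
  n_out <- ifelse(hit, 2L, 1L)
  ends <- cumsum(n_out)
  forwarded <- numeric(if (length(ends)) ends[length(ends)] else 0)
  forwarded[ends - n_out + 1L] <- ifelse(hit, point, len)
  forwarded[ends[hit]] <- len[hit] - point[hit]
  list(forwarded = forwarded,
       newly_retired = retired,
       fragments = c(rbind(point[hit], len[hit] - point[hit])),
       counts = c(broken = sum(hit),
                  passed = sum(!hit),
                  retired = length(retired)))
}

#' Run the mechanical attrition simulation
#'
#' Iterates [attrition_step()] with the step-dependent strength
#' [mu_over_p_at_step()]. Before each step the stop rule is checked: the
#' run ends when fewer than `config$min_active_to_continue` fibres would
#' be forwarded, or at `config$max_steps`. Retired fibres stay in a
#' retired pool: they leave the breakage loop but remain part of the
#' population for all reported length distributions.
#'
#' @param initial_lengths Initial population ([fibre_population()] or
#'   numeric vector of um lengths), non-empty.
#' @param schedule A [weakening_schedule()].
#' @param config A [sim_config()]; its `seed` makes the run reproducible.
#' @param verbose Emit a per-step log line (step, M_u/P, active, retired,
#'   broken) on standard error.
#' @return An object of class `trajectory`: fields `model`, `initial`,
#'   `steps` (list of per-step records with `step`, `mu_over_p`, `active`,
#'   `newly_retired`, `fragments`, `counts`), `schedule`, `config` and
#'   `stopped_by` (`"min_active"` or `"max_steps"`).
#' @examples
#' pop <- synthetic_population(500, seed = 1)
#' traj <- run_attrition(pop, config = sim_config(seed = 1))
#' traj
#' @export
run_attrition <- function(initial_lengths,
                          schedule = weakening_schedule(),
                          config = sim_config(),
                          verbose = FALSE) {
  initial <- as_lengths(initial_lengths)
  if (length(initial) == 0) {
    stop("initial population must be non-empty", call. = FALSE)
  }
  check_positive_length(initial)
  stopifnot(inherits(schedule, "weakening_schedule"),
            inherits(config, "sim_config"))
  with_seed(config$seed, {
    active <- initial
    steps <- list()
    stopped_by <- "min_active"
    k <- 0L
    while (length(active) >= config$min_active_to_continue) {
      if (k >= config$max_steps) {
        stopped_by <- "max_steps"
        break
      }
      k <- k + 1L
      mu <- mu_over_p_at_step(schedule, k)
      res <- attrition_step(active, mu)
      active <- res$forwarded
      steps[[k]] <- list(step = k, mu_over_p = mu,
                         active = active,
                         newly_retired = res$newly_retired,
                         fragments = res$fragments,
                         counts = res$counts)
      if (verbose) {
        message(sprintf(
          "step %d: mu_over_p=%.4g active=%d retired=%d broken=%d",
          k, mu, length(active), res$counts[["retired"]],
          res$counts[["broken"]]))
      }
    }
    new_trajectory(model = "mechanical", initial = initial, steps = steps,
                   schedule = schedule, config = config,
                   stopped_by = stopped_by)
  })
}

#' One random-segmentation step (null model)
#'
#' Splits every fibre, unconditionally, at a uniform random point. The
#' output has exactly twice as many fibres and the same total length.
#'
#' @param lengths Numeric vector of fibre lengths, um.
#' @return Numeric vector of `2 * length(lengths)` fragment lengths, the
#'   two halves of fibre `i` at positions `2i - 1` and `2i`.
#' @export
random_segmentation_step <- function(lengths) {
  lengths <- as_lengths(lengths)
  check_positive_length(lengths)
  if (length(lengths) == 0) return(numeric(0))
  point <- stats::runif(length(lengths)) * lengths
  c(rbind(point, lengths - point))
}

#' Run the random-segmentation null model
#'
#' Every fibre is split in two at a uniform point in every step, with no
#' strength threshold and no retirement, so the count doubles and the mean
#' length halves exactly each step. This is the population-balance null
#' against which the mechanical model's stagnation is judged: it never
#' settles at a nondegenerate distribution, it only drives all length into
#' the shortest class. Because the count grows as `2^n_steps`, the run
#' refuses step counts that would exceed `max_fibres`.
#'
#' @param initial_lengths Initial population, as in [run_attrition()].
#' @param n_steps Number of segmentation steps to run.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param max_fibres Refuse to run past this final fibre count.
#' @return A `trajectory` with `model = "random_segmentation"`.
#' @export
run_random_segmentation <- function(initial_lengths, n_steps,
                                    seed = NULL,
                                    max_fibres = 2^26) {
  initial <- as_lengths(initial_lengths)
  if (length(initial) == 0) {
    stop("initial population must be non-empty", call. = FALSE)
  }
  check_positive_length(initial)
  if (n_steps < 0) stop("`n_steps` must be >= 0", call. = FALSE)
  if (length(initial) * 2^n_steps > max_fibres) {
    stop(sprintf(
      "%d fibres doubled over %d steps exceeds max_fibres = %g",
      length(initial), n_steps, max_fibres), call. = FALSE)
  }
  with_seed(seed, {
    active <- initial
    steps <- vector("list", n_steps)
    for (k in seq_len(n_steps)) {
      n_in <- length(active)
      active <- random_segmentation_step(active)
      steps[[k]] <- list(step = k, mu_over_p = NA_real_,
                         active = active,
                         newly_retired = numeric(0),
                         fragments = NULL,
                         counts = c(broken = n_in, passed = 0L,
                                    retired = 0L))
    }
    new_trajectory(model = "random_segmentation", initial = initial,
                   steps = steps, schedule = NULL,
                   config = sim_config(seed = seed),
                   stopped_by = "n_steps")
  })
}

new_trajectory <- function(model, initial, steps, schedule, config,
                           stopped_by) {
  structure(list(model = model, initial = initial, steps = steps,
                 schedule = schedule, config = config,
                 stopped_by = stopped_by),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "%s trajectory: %d fibres initially, %d steps (stopped by %s)\n",
    x$model, length(x$initial), length(x$steps), x$stopped_by))
  if (length(x$steps)) {
    last <- x$steps[[length(x$steps)]]
    n_retired <- sum(vapply(x$steps,
                            function(s) length(s$newly_retired),
                            integer(1)))
    cat(sprintf("  final: %d active, %d retired\n",
                length(last$active), n_retired))
  }
  invisible(x)
}

#' Number of simulation steps in a trajectory
#' @param trajectory A `trajectory`.
#' @return Integer step count (excluding the initial snapshot).
#' @export
n_steps <- function(trajectory) {
  stopifnot(inherits(trajectory, "trajectory"))
  length(trajectory$steps)
}

#' Fibre lengths at a given step of a trajectory
#'
#' Step 0 is the initial population. With `include_retired = TRUE`
#' (default) the retired pool accumulated up to that step is included, so
#' the returned lengths always sum to the initial total.
#'
#' @param trajectory A `trajectory` from [run_attrition()] or
#'   [run_random_segmentation()].
#' @param step Step index, `0..n_steps(trajectory)`.
#' @param include_retired Include retired fibres?
#' @return Numeric vector of um lengths.
#' @export
population_lengths <- function(trajectory, step,
                               include_retired = TRUE) {
  stopifnot(inherits(trajectory, "trajectory"))
  if (step < 0 || step > length(trajectory$steps)) {
    stop("`step` must be in 0..", length(trajectory$steps), call. = FALSE)
  }
  if (step == 0) return(trajectory$initial)
  active <- trajectory$steps[[step]]$active
  if (!include_retired) return(active)
  retired <- unlist(lapply(trajectory$steps[seq_len(step)],
                           `[[`, "newly_retired"), use.names = FALSE)
  c(active, retired)
}

#' Binned distribution series of a trajectory
#'
#' Bins the population at step 0 through the final step into a
#' [distribution_series()].
#'
#' @inheritParams population_lengths
#' @inheritParams bin_length_weighted
#' @return A [distribution_series()] labelled by step index.
#' @export
trajectory_series <- function(trajectory,
                              bin_edges = default_bin_edges(),
                              include_retired = TRUE,
                              weight = "length") {
  stopifnot(inherits(trajectory, "trajectory"))
  labels <- 0:length(trajectory$steps)
  dists <- lapply(labels, function(s) {
    bin_length_weighted(
      population_lengths(trajectory, s, include_retired),
      bin_edges = bin_edges, weight = weight)
  })
  distribution_series(labels, dists)
}

#' Serialise a trajectory to JSON
#'
#' Per-step metadata (step index, M_u/P, event counts, active/retired
#' counts, total lengths) plus the schedule and configuration; the full
#' length vectors are included only on request. Identical seed and inputs
#' give byte-identical files.
#'
#' @param trajectory A `trajectory`.
#' @param path Output path.
#' @param include_lengths Also write the per-step length vectors.
#' @return `path`, invisibly.
#' @export
write_trajectory_json <- function(trajectory, path,
                                  include_lengths = FALSE) {
  stopifnot(inherits(trajectory, "trajectory"))
  steps <- lapply(trajectory$steps, function(s) {
    rec <- list(step = s$step, mu_over_p = s$mu_over_p,
                counts = as.list(s$counts),
                n_active = length(s$active),
                n_newly_retired = length(s$newly_retired),
                active_total_um = sum(s$active),
                newly_retired_total_um = sum(s$newly_retired))
    if (include_lengths) {
      rec$active_lengths_um <- s$active
      rec$newly_retired_lengths_um <- s$newly_retired
    }
    rec
  })
  out <- list(model = trajectory$model,
              n_initial = length(trajectory$initial),
              initial_total_um = sum(trajectory$initial),
              schedule = unclass(trajectory$schedule),
              config = unclass(trajectory$config),
              stopped_by = trajectory$stopped_by,
              steps = steps)
  if (include_lengths) out$initial_lengths_um <- trajectory$initial
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
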