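# Weakening schedule and simulation configuration.

#' Enzymatic weakening schedule for M_u/P
#'
#' Geometric decay of the strength-to-force ratio over simulation steps,
#' clamped at a floor: `max(floor, initial * decay^(k - 1))` at step `k`.
#' The decay represents progressive enzymatic weakening of the fibre wall;
#' the defaults (400 um at step 1, 25% reduction per step, floor 40 um)
#' reproduce the reference parameterisation of the mechanical model.
#'
#' @param initial_mu_over_p M_u/P at step 1, in um.
#' @param decay_factor Multiplicative factor applied per step, in (0, 1).
#' @param floor_mu_over_p Lower clamp for M_u/P, in um;
#'   `0 < floor <= initial`.
#' @return An object of class `weakening_schedule`.
#' @export
weakening_schedule <- function(initial_mu_over_p = 400,
                               decay_factor = 0.75,
                               floor_mu_over_p = 40) {
  if (!is.finite(initial_mu_over_p) || initial_mu_over_p <= 0) {
    stop("`initial_mu_over_p` must be > 0", call. = FALSE)
  }
  if (!is.finite(decay_factor) || decay_factor <= 0 || decay_factor >= 1) {
    stop("`decay_factor` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.finite(floor_mu_over_p) || floor_mu_over_p <= 0 ||
      floor_mu_over_p > initial_mu_over_p) {
    stop("`floor_mu_over_p` must satisfy 0 < floor <= initial",
         call. = FALSE)
  }
  structure(
    list(initial_mu_over_p = initial_mu_over_p,
         decay_factor = decay_factor,
         floor_mu_over_p = floor_mu_over_p),
    class = "weakening_schedule"
  )
}

#' @export
print.weakening_schedule <- function(x, ...) {
  cat(sprintf(
    "Weakening schedule: M_u/P = %g um at step 1, x%g per step, floor %g um\n",
    x$initial_mu_over_p, x$decay_factor, x$floor_mu_over_p))
  invisible(x)
}

#' M_u/P in force at a given step
#'
#' @param schedule A [weakening_schedule()].
#' @param step_index Step number, 1-based. Vectorised.
#' @return M_u/P in um; non-increasing in `step_index`.
#' @examples
#' sched <- weakening_schedule()
#' mu_over_p_at_step(sched, 1:10)  # 400, 300, ... clamped to 40 at step 10
#' @export
mu_over_p_at_step <- function(schedule, step_index) {
  stopifnot(inherits(schedule, "weakening_schedule"))
  if (any(step_index < 1) || any(step_index != round(step_index))) {
    stop("`step_index` must be an integer >= 1", call. = FALSE)
  }
  pmax(schedule$floor_mu_over_p,
       schedule$initial_mu_over_p *
         schedule$decay_factor^(step_index - 1))
}

#' Simulation run configuration
#'
#' @param min_active_to_continue The run stops before a step when fewer than
#'   this many active fibres would be forwarded into it.
#' @param max_steps Safety cap on the number of steps; termination of the
#'   mechanical model is almost sure but not bounded.
#' @param seed Integer RNG seed, or `NULL` to use the current RNG stream.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(min_active_to_continue = 100,
                       max_steps = 500,
                       seed = NULL) {
  if (min_active_to_continue < 1) {
    stop("`min_active_to_continue` must be >= 1", call. = FALSE)
  }
  if (max_steps < 1) stop("`max_steps` must be >= 1", call. = FALSE)
  structure(
    list(min_active_to_continue = as.integer(min_active_to_continue),
         max_steps = as.integer(max_steps),
         seed = if (!is.null(seed)) as.integer(seed)),
    class = "sim_config"
  )
}

#' Read a schedule + run configuration from a YAML or JSON file
#'
#' The file holds two optional mappings, `schedule` (fields of
#' [weakening_schedule()]) and `config` (fields of [sim_config()]); absent
#' fields take the package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with components `schedule` and `config`.
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  sched_args <- raw$schedule %||% list()
  conf_args <- raw$config %||% list()
  known_s <- c("initial_mu_over_p", "decay_factor", "floor_mu_over_p")
  known_c <- c("min_active_to_continue", "max_steps", "seed")
  bad <- c(setdiff(names(sched_args), known_s),
           setdiff(names(conf_args), known_c))
  if (length(bad)) {
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  list(schedule = do.call(weakening_schedule, sched_args),
       config = do.call(sim_config, conf_args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
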