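# Beam-theory mechanics for a simply supported fibre under a transverse
# point load. All lengths are in micrometres (um); the single mechanical
# parameter is the ratio M_u/P (failure moment over characteristic impact
# force), which has units of length. Forces never appear on their own: the
# moment envelope is expressed per unit force.

#' Bending-moment envelope of a simply supported fibre
#'
#' Maximum bending moment attainable at a given position along a simply
#' supported fibre as the transverse load point varies, per unit force.
#' For a fibre of length `L` supported at its ends, the envelope is the
#' parabola `L * (x/L) * (1 - x/L)`: the moment diagram for any single load
#' position is triangular, and sweeping the load point over the fibre traces
#' out this parabolic envelope. Its maximum, `L/4`, is the moment beneath a
#' central load.
#'
#' @param rel_pos Relative position `x/L` along the fibre, in `[0, 1]`.
#'   Vectorised; recycled against `length`.
#' @param length Fibre length in um, strictly positive.
#' @return Bending moment per unit force, in um.
#' @seealso [pfr_extent()], [pfr_bounds()]
#' @examples
#' moment_envelope(0.5, 1000)   # 250, the central-load maximum L/4
#' moment_envelope(0.25, 1000)  # 187.5
#' @export
moment_envelope <- function(rel_pos, length) {
  check_positive_length(length)
  if (any(rel_pos < 0 | rel_pos > 1)) {
    stop("`rel_pos` must lie in [0, 1]", call. = FALSE)
  }
  length * rel_pos * (1 - rel_pos)
}

#' Breakability ratio of a fibre
#'
#' Ratio of the failure moment to the maximum moment attainable beneath a
#' central force: `(M_u/P) / (L/4) = 4 * mu_over_p / L`. A fibre can break
#' only where the moment envelope reaches the failure moment, so a ratio
#' above 1 means the fibre is too short to break at the current strength.
#'
#' @param length Fibre length in um, strictly positive. Vectorised.
#' @param mu_over_p Strength-to-force ratio M_u/P in um, non-negative.
#' @return Dimensionless ratio, `>= 0`.
#' @export
breakability_ratio <- function(length, mu_over_p) {
  check_positive_length(length)
  check_mu_over_p(mu_over_p)
  4 * mu_over_p / length
}

#' Can a fibre break at the current strength?
#'
#' `TRUE` iff the breakability ratio is `<= 1`, i.e. the fibre is at least
#' as long as the threshold length `4 * mu_over_p`. Fibres with ratio
#' strictly above 1 are too short to break and are retired by the
#' simulator. At the threshold itself the fibre counts as breakable but its
#' probable failure region has zero extent, so its break probability is 0.
#'
#' @inheritParams breakability_ratio
#' @return Logical vector.
#' @export
is_breakable <- function(length, mu_over_p) {
  breakability_ratio(length, mu_over_p) <= 1
}

#' Relative extent of the probable failure region
#'
#' Fraction of the fibre length, centred on the midpoint, over which the
#' moment envelope equals or exceeds the failure moment:
#' `sqrt(1 - 4 * mu_over_p / length)` when the fibre is breakable, else 0.
#' Under a uniform random load point this extent is also the single-event
#' break probability.
#'
#' Computed as `sqrt(max(0, 1 - ratio))` so floating-point noise at the
#' breakability threshold cannot produce a negative sqrt argument.
#'
#' @inheritParams breakability_ratio
#' @return Fraction in `[0, 1]`.
#' @examples
#' pfr_extent(3200, 400)  # sqrt(0.5) ~= 0.707
#' pfr_extent(1600, 400)  # 0: threshold fibre
#' @export
pfr_extent <- function(length, mu_over_p) {
  ratio <- breakability_ratio(length, mu_over_p)
  ifelse(ratio < 1, sqrt(pmax(0, 1 - ratio)), 0)
}

#' Absolute bounds of the probable failure region
#'
#' The PFR occupies the central fraction [pfr_extent()] of the fibre:
#' `[L/2 - L*e/2, L/2 + L*e/2]`. Degenerate (`lower == upper == L/2`) for
#' fibres at or below the breakability threshold.
#'
#' @inheritParams breakability_ratio
#' @return A list with numeric components `lower` and `upper`, in um.
#' @export
pfr_bounds <- function(length, mu_over_p) {
  e <- pfr_extent(length, mu_over_p)
  list(lower = length / 2 * (1 - e), upper = length / 2 * (1 + e))
}

check_positive_length <- function(length) {
  if (length(length) == 0) return(invisible(TRUE))
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("fibre `length` must be finite and strictly positive (um)",
         call. = FALSE)
  }
  invisible(TRUE)
}

check_mu_over_p <- function(mu_over_p) {
  if (any(!is.finite(mu_over_p)) || any(mu_over_p < 0)) {
    stop("`mu_over_p` must be finite and >= 0 (um)", call. = FALSE)
  }
  invisible(TRUE)
}
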