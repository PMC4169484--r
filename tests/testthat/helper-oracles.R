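# Independent oracles and small fixture builders shared across tests.

# Measure of {x/L : envelope(x) >= mu} by dense midpoint grid scan of the
# moment envelope; independent of the closed-form extent.
grid_scan_extent <- function(length, mu_over_p, n = 1e5) {
  x <- (seq_len(n) - 0.5) / n
  mean(length * x * (1 - x) >= mu_over_p)
}

# A length_distribution with prescribed shares, for metric-space tests.
dist_from_shares <- function(shares, edges = default_bin_edges()) {
  stopifnot(length(shares) == length(edges) - 1)
  # build via binning a population engineered to land one fibre per bin,
  # then overwrite shares: the constructor is not exported, so go through
  # the public API and patch.
  d <- bin_length_weighted(rep(1000, 1), bin_edges = edges)
  d$shares <- shares / sum(shares)
  d
}

random_simplex <- function(n_bins) {
  x <- stats::rexp(n_bins)
  x / sum(x)
}
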