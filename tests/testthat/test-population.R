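test_that("synthetic population emulates cut segments plus fines", {
  expect_length(synthetic_population(0, seed = 1)$lengths, 0)

  pop <- synthetic_population(500, intact_fraction = 1, seed = 2)
  expect_true(all(pop$lengths >= 3000 & pop$lengths <= 7000))

  pop2 <- synthetic_population(500, intact_fraction = 0, seed = 2)
  expect_true(all(pop2$lengths > 0 & pop2$lengths <= 7000))  # fines capped

  a <- synthetic_population(1000, seed = 33)
  b <- synthetic_population(1000, seed = 33)
  expect_identical(a$lengths, b$lengths)
  c <- synthetic_population(1000, seed = 34)
  expect_false(identical(a$lengths, c$lengths))

  expect_error(synthetic_population(10, intact_range = c(7000, 3000)),
               "intact_range")
  expect_error(synthetic_population(10, intact_fraction = 2),
               "intact_fraction")
})

test_that("length tables round-trip and convert units", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_lengths(c(1000, 2500), f)
  expect_equal(read_lengths(f)$lengths, c(1000, 2500))

  writeLines(c("length_mm", "3.5", "0.2"), f)
  expect_equal(read_lengths(f)$lengths, c(3500, 200))

  writeLines(c("length_um", "100", "-1"), f)
  expect_error(read_lengths(f), "row 2")
  writeLines(c("length_um", "100", "abc"), f)
  expect_error(read_lengths(f), "row 2")
  writeLines(c("width_um", "100"), f)
  expect_error(read_lengths(f), "unknown unit header")
})

test_that("length-weighted binning reproduces hand-computed shares", {
  d <- bin_length_weighted(4000)  # single 4 mm fibre, default classes
  expect_equal(d$shares, c(0, 0, 0, 1))

  d2 <- bin_length_weighted(c(1000, 2000, 3000), bin_edges = c(0, 0.5, 3, 7))
  expect_equal(d2$shares, c(0, 0.5, 0.5))  # 1+2 of 6 mm mid, 3 mm long

  expect_error(bin_length_weighted(1000, bin_edges = c(1, 0.5)),
               "ascending")
  expect_error(bin_length_weighted(100, bin_edges = c(0.5, 3)), "first bin")
})

test_that("binning invariants: normalisation, merging, permutation", {
  set.seed(5)
  for (rep in 1:5) {
    lengths <- exp(runif(300, log(30), log(6900)))
    edges <- c(0, sort(runif(4, 0.1, 6.9)), 7)
    d <- bin_length_weighted(lengths, bin_edges = edges)
    expect_equal(sum(d$shares), 1)
    # merging two adjacent bins sums their shares exactly
    merged <- bin_length_weighted(lengths, bin_edges = edges[-3])
    expect_equal(merged$shares[2], d$shares[2] + d$shares[3])
    # permutation invariance
    d_perm <- bin_length_weighted(sample(lengths), bin_edges = edges)
    expect_equal(d_perm$shares, d$shares)
  }
})

test_that("count weighting agrees with length weighting for equal fibres", {
  lengths <- rep(1200, 50)
  dl <- bin_length_weighted(lengths)
  dc <- bin_length_weighted(lengths, weight = "count")
  expect_equal(dl$shares, dc$shares)
  # and differs when lengths differ
  mixed <- c(100, 6900)
  expect_false(isTRUE(all.equal(
    bin_length_weighted(mixed)$shares,
    bin_length_weighted(mixed, weight = "count")$shares)))
})

test_that("degenerate binning inputs are flagged, not fatal", {
  d <- bin_length_weighted(numeric(0))
  expect_true(d$empty)
  expect_equal(d$shares, rep(0, 4))

  d_over <- bin_length_weighted(9000)  # above the 7 mm top edge
  expect_true(d_over$overflow)
  expect_equal(d_over$shares, c(0, 0, 0, 1))
})

test_that("distribution series enforce common edges and round-trip CSV", {
  d1 <- bin_length_weighted(c(1000, 4000))
  d2 <- bin_length_weighted(c(300, 700))
  s <- distribution_series(c(0, 1), list(d1, d2))
  expect_length(s, 2)
  expect_error(distribution_series(c(1, 0), list(d1, d2)), "increasing")
  d3 <- bin_length_weighted(1000, bin_edges = c(0, 1, 7))
  expect_error(distribution_series(c(0, 1), list(d1, d3)), "edges")

  f <- withr::local_tempfile(fileext = ".csv")
  write_distribution_series(s, f)
  s2 <- read_distribution_series(f)
  expect_equal(s2$labels, s$labels)
  for (i in 1:2) {
    expect_equal(s2$distributions[[i]]$shares, s$distributions[[i]]$shares)
    expect_equal(s2$distributions[[i]]$bin_edges, s$distributions[[i]]$bin_edges)
  }
})
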