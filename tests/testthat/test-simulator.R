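test_that("a single attrition step breaks, passes and retires correctly", {
  empty <- attrition_step(numeric(0), 400)
  expect_equal(empty$forwarded, numeric(0))
  expect_equal(empty$counts, c(broken = 0L, passed = 0L, retired = 0L))

  # everything below the 4*mu threshold is retired, nothing breaks
  short <- attrition_step(c(1000, 1500, 200), 400)
  expect_equal(sort(short$newly_retired), c(200, 1000, 1500))
  expect_equal(short$forwarded, numeric(0))
  expect_equal(short$counts[["broken"]], 0L)

  set.seed(10)
  lengths <- runif(500, 500, 7000)
  res <- attrition_step(lengths, 400)
  expect_equal(sum(res$counts), length(lengths))
  # conservation of total length
  expect_equal(sum(res$forwarded) + sum(res$newly_retired), sum(lengths),
               tolerance = 1e-12)
  # every fragment is at least mu_over_p long
  expect_true(all(res$fragments >= 400 - 1e-9))
  expect_equal(length(res$fragments), 2 * res$counts[["broken"]])
  # forwarded preserves input order with halves in place
  expect_length(res$forwarded,
                res$counts[["passed"]] + 2 * res$counts[["broken"]])
  expect_error(attrition_step(c(100, -5), 400), "positive")
})

test_that("break probability of one fibre equals the PFR extent", {
  set.seed(77)
  n <- 2e4
  res <- attrition_step(rep(3200, n), 400)  # extent sqrt(0.5)
  p_hat <- res$counts[["broken"]] / n
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(p_hat - sqrt(0.5)), 4 * se)
})

test_that("full attrition runs obey stop rule, conservation, monotone retirement", {
  pop <- synthetic_population(2000, seed = 3)
  traj <- run_attrition(pop, config = sim_config(seed = 4))
  expect_s3_class(traj, "trajectory")
  expect_equal(traj$stopped_by, "min_active")
  expect_lt(length(traj$steps[[n_steps(traj)]]$active), 100)

  tot0 <- sum(pop$lengths)
  n_retired_prev <- 0
  for (s in seq_len(n_steps(traj))) {
    lens <- population_lengths(traj, s)
    expect_lt(abs(sum(lens) - tot0) / tot0, 1e-9)
    rec <- traj$steps[[s]]
    expect_equal(sum(rec$counts),
                 length(if (s == 1) pop$lengths
                        else traj$steps[[s - 1]]$active))
    # retired pool only grows
    n_ret <- length(population_lengths(traj, s)) - length(rec$active)
    expect_gte(n_ret, n_retired_prev)
    n_retired_prev <- n_ret
  }
})

test_that("attrition edge cases: all-short start and tiny populations", {
  # 1 mm fibres cannot break at mu = 400: all retired in one step
  traj <- run_attrition(rep(1000, 200), config = sim_config(seed = 1))
  expect_equal(n_steps(traj), 1)
  expect_equal(length(traj$steps[[1]]$newly_retired), 200)
  expect_equal(traj$steps[[1]]$counts[["broken"]], 0L)

  # fewer fibres than the stop threshold: no step runs at all
  traj2 <- run_attrition(5000, config = sim_config(seed = 1))
  expect_equal(n_steps(traj2), 0)
  expect_equal(population_lengths(traj2, 0), 5000)

  # the max_steps cap is honoured and flagged
  traj3 <- run_attrition(synthetic_population(2000, seed = 5),
                         config = sim_config(max_steps = 3, seed = 5))
  expect_equal(n_steps(traj3), 3)
  expect_equal(traj3$stopped_by, "max_steps")
  expect_error(run_attrition(numeric(0)), "non-empty")
})

test_that("identical seeds give identical trajectories", {
  pop <- synthetic_population(1500, seed = 8)
  t1 <- run_attrition(pop, config = sim_config(seed = 21))
  t2 <- run_attrition(pop, config = sim_config(seed = 21))
  expect_identical(t1$steps, t2$steps)
  t3 <- run_attrition(pop, config = sim_config(seed = 22))
  expect_false(identical(t1$steps, t3$steps))
})

test_that("random segmentation doubles counts and halves means", {
  expect_equal(random_segmentation_step(numeric(0)), numeric(0))
  set.seed(9)
  two <- random_segmentation_step(4200)
  expect_length(two, 2)
  expect_equal(sum(two), 4200)

  pop <- synthetic_population(400, seed = 12)
  traj <- run_random_segmentation(pop, n_steps = 6, seed = 13)
  m0 <- mean(pop$lengths)
  for (k in 1:6) {
    lens <- population_lengths(traj, k)
    expect_length(lens, 400 * 2^k)                      # exact doubling
    expect_equal(mean(lens), m0 / 2^k, tolerance = 1e-9)  # mean halving
  }

  empty_run <- run_random_segmentation(pop, n_steps = 0, seed = 1)
  expect_equal(n_steps(empty_run), 0)
  expect_error(run_random_segmentation(pop, n_steps = 40),
               "max_fibres")
})

test_that("trajectory JSON serialisation is deterministic", {
  pop <- synthetic_population(500, seed = 6)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_trajectory_json(run_attrition(pop, config = sim_config(seed = 2)), f1)
  write_trajectory_json(run_attrition(pop, config = sim_config(seed = 2)), f2)
  expect_identical(readLines(f1), readLines(f2))
  parsed <- jsonlite::read_json(f1, simplifyVector = TRUE)
  expect_equal(parsed$model, "mechanical")
  expect_equal(parsed$n_initial, 500)
  expect_equal(nrow(parsed$steps), length(parsed$steps$step))
})
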