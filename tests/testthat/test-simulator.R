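test_that("identical config and seed give byte-identical output files", {
  cfg <- sim_config(seed = 77)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_sim_csvs(simulate_informant_study(cfg), d1)
  p2 <- write_sim_csvs(simulate_informant_study(cfg), d2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
  p3 <- write_sim_csvs(
    simulate_informant_study(sim_config(seed = 78)), withr::local_tempdir()
  )
  expect_false(identical(readLines(p1[["truth"]]), readLines(p3[["truth"]])))
})

test_that("perfect capture puts every dual-village death on both listings", {
  cfg <- sim_config(
    p_kader = 1, p_rt = 1, out_of_window_rate = 0, fabrication_rate = 0,
    seed = 5
  )
  sim <- simulate_informant_study(cfg)
  dual <- sim$truth$dual_village
  expect_true(all(sim$truth$captured_kader))
  expect_true(all(sim$truth$captured_rt[dual]))
  expect_false(any(sim$truth$captured_rt[!dual]))
  m <- sum(sim$truth$captured_kader & sim$truth$captured_rt & dual)
  expect_equal(m, sum(dual)) # m equals the union under perfect capture
})

test_that("empirical capture frequencies match configured probabilities", {
  set.seed(31)
  n <- 10000
  counts <- simulate_capture(n, p_a = 0.85, p_b = 0.71, n_reps = 1)
  se_a <- sqrt(0.85 * 0.15 / n)
  se_b <- sqrt(0.71 * 0.29 / n)
  expect_lt(abs(counts$n_a / n - 0.85), 3 * se_a)
  expect_lt(abs(counts$n_b / n - 0.71), 3 * se_b)
  # independence: joint frequency factorizes
  p_both <- 0.85 * 0.71
  expect_lt(abs(counts$m / n - p_both), 3 * sqrt(p_both * (1 - p_both) / n))
})

test_that("dependence and heterogeneity shift the overlap as configured", {
  set.seed(13)
  n <- 20000
  dep <- simulate_capture(n, 0.7, 0.7, delta = 1.5, n_reps = 1)
  # positive dependence inflates the overlap beyond p_a * p_b
  expect_gt(dep$m / n, 0.49 + 3 * sqrt(0.25 / n))

  het <- simulate_capture(n, 0.7, 0.7, heterogeneity_kappa = 2, n_reps = 1)
  expect_gt(het$m / n, 0.49 + 3 * sqrt(0.25 / n))
  # marginals stay at the configured mean under heterogeneity
  expect_lt(abs(het$n_a / n - 0.7), 3 * sqrt(0.21 / n))
})

test_that("expected dual-stratum cells at the study operating point", {
  set.seed(8)
  reps <- simulate_capture(121, p_a = 0.85, p_b = 0.71, n_reps = 400)
  both <- mean(reps$m)
  rt_only <- mean(reps$n_a - reps$m)
  kader_only <- mean(reps$n_b - reps$m)
  expect_equal(both, 121 * 0.85 * 0.71, tolerance = 0.02)
  expect_equal(rt_only, 121 * 0.85 * 0.29, tolerance = 0.05)
  expect_equal(kader_only, 121 * 0.15 * 0.71, tolerance = 0.08)
})

test_that("false positives and fabrications are injected at configured rates", {
  cfg <- sim_config(
    n_villages = c(urban = 200, rural = 0, rural_remote = 0),
    dual_fraction = c(urban = 1, rural = 0, rural_remote = 0),
    out_of_window_rate = 0.2, fabrication_rate = 0.05, seed = 17
  )
  sim <- simulate_informant_study(cfg)
  n_in <- sum(sim$truth$kind == "in_window")
  n_out <- sum(sim$truth$kind == "out_of_window")
  n_fab <- sum(sim$truth$kind == "fabricated")
  expect_equal(n_out / n_in, 0.2, tolerance = 0.25)
  expect_equal(n_fab / n_in, 0.05, tolerance = 0.5)
  # out-of-period deaths carry in-window listed dates (recall error), and are
  # never eligible
  oow <- sim$truth$kind == "out_of_window"
  expect_true(all(sim$truth$listed_date[oow] >= cfg$window$start_date))
  expect_true(all(sim$truth$listed_date[oow] <= cfg$window$end_date))
  expect_false(any(sim$truth$eligible_prd[oow]))
  # fabrications are unconfirmed and listed by exactly one network
  fab <- sim$truth$kind == "fabricated"
  expect_false(any(
    sim$verification_truth$death_confirmed[match(
      sim$truth$death_id[fab], sim$verification_truth$death_id
    )]
  ))
  expect_true(all(xor(
    sim$truth$captured_kader[fab], sim$truth$captured_rt[fab]
  )))
})

test_that("single-network villages never produce RT listings", {
  cfg <- sim_config(seed = 23)
  sim <- simulate_informant_study(cfg)
  rt_villages <- unique(sim$listings$rt$village_id)
  dual_villages <- unique(sim$truth$village_id[sim$truth$dual_village])
  expect_true(all(rt_villages %in% dual_villages))
  expect_true(any(grepl("rural_remote", sim$listings$kader$village_id)))
})

test_that("recovery experiment scores estimators against the latent truth", {
  res <- run_recovery_experiment(
    n_true = 121, p_a = 0.85, p_b = 0.71, n_replicates = 200,
    estimator = "lincoln_petersen", seed = 4
  )
  expect_equal(res$summary$n_used, 200)
  expect_lt(abs(res$summary$rel_bias), 0.05)
  expect_true(all(
    res$replicates$m <= pmin(res$replicates$n_a, res$replicates$n_b)
  ))
})
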