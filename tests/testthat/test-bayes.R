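# fully independent oracle for the dual-only posterior: direct summation over
# N with numerical integration over each capture probability (no Beta-function
# shortcuts shared with the implementation)
integrate_oracle <- function(n_a, n_b, m, cap_multiplier = 20) {
  u <- n_a + n_b - m
  Ns <- u:(cap_multiplier * u)
  lik <- vapply(Ns, function(N) {
    ia <- stats::integrate(
      function(p) p^n_a * (1 - p)^(N - n_a), 0, 1,
      rel.tol = 1e-10
    )$value
    ib <- stats::integrate(
      function(p) p^n_b * (1 - p)^(N - n_b), 0, 1,
      rel.tol = 1e-10
    )$value
    exp(lgamma(N + 1) - lgamma(N - u + 1)) * ia * ib
  }, numeric(1))
  data.frame(value = Ns, prob = lik / sum(lik))
}

test_that("grid posterior agrees with a direct numerical-integration oracle", {
  for (cfg in list(c(6, 5, 3), c(4, 7, 2), c(3, 3, 1))) {
    grid <- crc_grid_posterior(capture_summary(cfg[1], cfg[2], cfg[3]))
    oracle <- integrate_oracle(cfg[1], cfg[2], cfg[3])
    expect_equal(grid$N_dual$value, oracle$value)
    expect_lt(sum(abs(grid$N_dual$prob - oracle$prob)) / 2, 1e-6)
  }
})

test_that("Gibbs sampler recovers the exact posterior on small configurations", {
  # Rao-Blackwellized N-marginal from the sampled capture probabilities,
  # compared against the exact grid in total variation
  for (cfg in list(c(6, 5, 3), c(8, 8, 1))) {
    cs <- capture_summary(cfg[1], cfg[2], cfg[3])
    grid <- crc_grid_posterior(cs)
    fit <- suppressWarnings(
      bayesian_total(cs, n_iter = 4000, warmup = 500, chains = 2, seed = 99)
    )
    u <- cs$union
    support <- grid$N_dual$value
    q <- (1 - fit$draws[, "p_a"]) * (1 - fit$draws[, "p_b"])
    rb <- rowMeans(vapply(q, function(x) {
      w <- stats::dnbinom(support - u, size = u + 1, prob = 1 - x)
      w / sum(w)
    }, numeric(length(support))))
    expect_lt(sum(abs(rb - grid$N_dual$prob)) / 2, 0.02)
    # empirical histogram agrees more loosely
    emp <- tabulate(fit$draws[, "N_dual"] - u + 1, nbins = length(support))
    expect_lt(sum(abs(emp / sum(emp) - grid$N_dual$prob)) / 2, 0.1)
  }
})

test_that("sampler and exact grid agree at the study scale, including the single stratum", {
  cs <- capture_summary(103, 86, 73)
  grid <- crc_grid_posterior(cs, single_count = 353)
  fit <- bayesian_total(
    cs,
    single_count = 353, n_iter = 10000, warmup = 1000, chains = 2, seed = 5
  )
  expect_equal(fit$summaries$total$mean, grid$mean[["total"]], tolerance = 0.01)
  expect_equal(
    c(fit$summaries$total$ci_low, fit$summaries$total$ci_high),
    unname(grid$ci["total", ]),
    tolerance = 0.02
  )
  expect_true(all(fit$rhat < 1.05))
  expect_true(fit$converged)
})

test_that("point-mass capture priors collapse the posterior onto the union", {
  cs <- capture_summary(9, 9, 9)
  fit <- bayesian_total(
    cs,
    n_iter = 2000, warmup = 200, chains = 1, seed = 3,
    prior_a = c(1e6, 1), prior_b = c(1e6, 1)
  )
  expect_equal(unique(fit$draws[, "N_dual"]), 9)
  expect_equal(fit$summaries$N_dual$ci_low, 9)
  expect_equal(fit$summaries$N_dual$ci_high, 9)
})

test_that("fits are reproducible given a seed and record it", {
  cs <- capture_summary(20, 15, 9)
  f1 <- bayesian_total(cs, single_count = 30, n_iter = 1000, warmup = 100,
                       chains = 2, seed = 123)
  f2 <- bayesian_total(cs, single_count = 30, n_iter = 1000, warmup = 100,
                       chains = 2, seed = 123)
  expect_identical(f1$draws, f2$draws)
  expect_equal(f1$summaries$total$seed, 123L)
  f3 <- bayesian_total(cs, single_count = 30, n_iter = 1000, warmup = 100,
                       chains = 2, seed = 124)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("posterior mean approaches the point estimate as counts scale up", {
  base <- c(12, 10, 7)
  ratio <- vapply(c(1, 100), function(k) {
    cs <- capture_summary(base[1] * k, base[2] * k, base[3] * k)
    grid <- crc_grid_posterior(cs)
    grid$mean[["N_dual"]] / lincoln_petersen(cs)$total_raw
  }, numeric(1))
  expect_gt(abs(ratio[1] - 1), abs(ratio[2] - 1))
  expect_equal(ratio[2], 1, tolerance = 0.005)
})
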