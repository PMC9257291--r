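test_that("GLS oracle reduces to OLS without phylogeny and is exact on noiseless data", {
  set.seed(21)
  n <- 60
  X <- cbind(1, rnorm(n), rnorm(n))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  y <- drop(X %*% c(1, 2, -1)) + rnorm(n)
  g <- fit_gls(y, X, diag(n))
  ols <- unname(coef(lm(y ~ X - 1)))
  expect_equal(unname(g$beta), ols, tolerance = 1e-8)

  # noiseless: beta recovered exactly whatever lambda the profile picks
  d <- sim_phylo_data(n = 80, lambda = 0.5, s2 = 0, seed = 31)
  g0 <- fit_gls(d$y, d$X, d$V)
  expect_equal(unname(g0$beta), d$beta, tolerance = 1e-8)

  # lambda recovery at moderate n (median over seeds)
  lams <- sapply(1:5, function(s) {
    d <- sim_phylo_data(n = 400, lambda = 0.6, s2 = 4, seed = 100 + s)
    fit_gls(d$y, d$X, d$V)$lambda
  })
  expect_lt(abs(median(lams) - 0.6), 0.1)
})

test_that("sampler is deterministic under seed and keeps the scheduled draw count", {
  d <- sim_phylo_data(n = 60, seed = 41)
  sch <- mcmc_schedule(1500, 300, 7, seed = 5)
  f1 <- fit_mcmc(d$y, d$X, d$V, schedule = sch)
  f2 <- fit_mcmc(d$y, d$X, d$V, schedule = sch)
  expect_identical(f1$draws, f2$draws)
  expect_equal(nrow(f1$draws$beta), floor((1500 - 300) / 7))
  expect_equal(sch$n_keep, floor((1500 - 300) / 7))
  # the long-chain default protocol retains floor((75000-7500)/40) draws
  expect_equal(mcmc_schedule()$n_keep, 1687)
  f3 <- fit_mcmc(d$y, d$X, d$V, schedule = mcmc_schedule(1500, 300, 7, 6))
  expect_false(identical(f1$draws$beta, f3$draws$beta))
})

test_that("posterior means agree with the GLS oracle in a data-dominated regime", {
  d <- sim_phylo_data(n = 300, lambda = 0.5, s2 = 4, seed = 51)
  f <- fit_mcmc(d$y, d$X, d$V, schedule = short_schedule(seed = 51))
  g <- fit_gls(d$y, d$X, d$V)
  comb <- sqrt(f$summary$post_sd^2 + g$beta_se^2)
  expect_true(all(abs(f$summary$post_mean - g$beta) < 2 * comb))

  # invariance (to MC error) under simultaneous row/V permutation
  p <- sample(length(d$y))
  fp <- fit_mcmc(d$y[p], d$X[p, ], d$V[p, p], schedule = short_schedule(seed = 51))
  expect_true(all(abs(fp$summary$post_mean - f$summary$post_mean) <
                    2 * sqrt(2) * f$summary$post_sd))
})

test_that("lambda posterior concentrates at the simulation truth at the extremes", {
  d0 <- sim_phylo_data(n = 300, lambda = 0, s2 = 4, seed = 61)
  f0 <- fit_mcmc(d0$y, d0$X, d0$V, schedule = short_schedule(seed = 61))
  expect_lt(f0$lambda_mean, 0.15)

  d1 <- sim_phylo_data(n = 300, lambda = 1, s2 = 4, seed = 62)
  f1 <- fit_mcmc(d1$y, d1$X, d1$V, schedule = short_schedule(seed = 62))
  expect_gt(f1$lambda_mean, 0.85)
})

test_that("pMCMC follows the two-tail convention with floor and cap", {
  expect_equal(pmcmc(rep(1, 100) + runif(100)), 2 / 100)   # all positive
  expect_equal(pmcmc(c(rep(1, 50), rep(-1, 50))), 1)        # symmetric
  expect_equal(pmcmc(c(rep(1, 70), rep(-1, 30))), 0.6)
  expect_error(pmcmc(1), "at least 2")
})

test_that("effective sample size matches iid and AR(1) references", {
  set.seed(71)
  iid <- rnorm(2000)
  expect_lt(abs(effective_sample_size(iid) - 2000) / 2000, 0.15)

  rho <- 0.5; n <- 5000
  ar <- as.numeric(arima.sim(list(ar = rho), n))
  target <- n * (1 - rho) / (1 + rho)
  expect_lt(abs(effective_sample_size(ar) - target) / target, 0.20)

  expect_warning(z <- effective_sample_size(rep(3, 50)), "constant")
  expect_equal(z, 0)

  # cross-check against an established implementation on a real chain
  d <- sim_phylo_data(n = 50, seed = 72)
  f <- fit_mcmc(d$y, d$X, d$V, schedule = mcmc_schedule(2000, 200, 2, 72))
  own <- effective_sample_size(f$draws$beta[, 2])
  ref <- as.numeric(coda::effectiveSize(f$draws$beta[, 2]))
  expect_lt(abs(own - ref) / ref, 0.30)
})

test_that("HPD intervals are the shortest interval and bracket the quantile interval", {
  set.seed(81)
  x <- rexp(5000)             # skewed: HPD starts at the mode side
  h <- hpd_interval(x)
  q <- hpd_interval(x, method = "quantile")
  expect_lt(h[1], q[1])
  expect_lt(h[2] - h[1], q[2] - q[1])
  expect_lte(h[1], h[2])
  expect_gte(mean(x >= h[1] & x <= h[2]), 0.945)
})

test_that("tree-set averaging equals the arithmetic mean of per-tree summaries", {
  d <- sim_phylo_data(n = 80, seed = 91)
  trees <- lapply(1:3, function(i) simulate_yule(80, seed = 900 + i))
  avg <- fit_tree_set(d$y, d$X, trees, k = 3,
                      schedule = mcmc_schedule(1200, 200, 5, 1), seed = 91,
                      species_id = d$tree$tip.label)
  hand <- rowMeans(sapply(avg$fits, function(f) f$summary$post_mean))
  expect_equal(avg$coefficients$post_mean, hand)
  hand_l <- mean(sapply(avg$fits, `[[`, "lambda_mean"))
  expect_equal(avg$lambda_mean, hand_l)
  expect_equal(avg$tree_count, 3)

  # identical trees: average equals a single fit up to MC error
  same <- fit_tree_set(d$y, d$X, list(trees[[1]], trees[[1]]), k = 2,
                       schedule = mcmc_schedule(1200, 200, 5, 1), seed = 91,
                       species_id = d$tree$tip.label)
  one <- same$fits[[1]]
  expect_true(all(abs(same$coefficients$post_mean - one$summary$post_mean) <
                    3 * one$summary$post_sd / sqrt(nrow(one$draws$beta) / 10)))

  # determinism end to end
  again <- fit_tree_set(d$y, d$X, trees, k = 3,
                        schedule = mcmc_schedule(1200, 200, 5, 1), seed = 91,
                        species_id = d$tree$tip.label)
  expect_identical(avg$coefficients, again$coefficients)
  expect_error(fit_tree_set(d$y, d$X, trees, k = 5), "exceeds")
})

test_that("validation regression recovers exact and null relationships", {
  n <- 120
  tr <- simulate_yule(n, seed = 101)
  V <- vcv_from_tree(tr)
  set.seed(102)
  x <- rnorm(n)
  # exact linear function: slope recovered, R^2 near 1
  y <- 3 + 0.8 * scale(x)[, 1] + rnorm(n, sd = 1e-3)
  vr <- validation_regression(y, x, V, schedule = short_schedule(2000, 200, 4, 103))
  expect_equal(vr$slope, 0.8, tolerance = 0.01)
  expect_gt(vr$r_squared, 0.97)

  # independent x and y: CI covers 0, R^2 near 0
  y0 <- rnorm(n)
  vr0 <- validation_regression(y0, x, V, schedule = short_schedule(2000, 200, 4, 104))
  expect_lt(vr0$slope_ci[1], 0)
  expect_gt(vr0$slope_ci[2], 0)
  expect_lt(vr0$r_squared, 0.15)
})
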