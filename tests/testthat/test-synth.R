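test_that("trait simulation honours counts, strata and determinism", {
  spec <- simulation_spec(n_species = 120, n_missing = 15, n_museum = 40,
                          n_museum_missing = 4, n_trees = 2)
  tree <- simulate_yule(120, seed = 1)
  tab <- simulate_traits(tree, spec, seed = 2)
  expect_equal(nrow(tab), 120)
  incomplete <- !complete.cases(tab[, c("mass_g", "flock_size", "colonial",
                                        "n_predators", "activity")])
  expect_equal(sum(incomplete), 15)
  expect_equal(sum(incomplete & tab$has_museum_image), 4)
  expect_equal(sum(tab$has_museum_image), 40)
  expect_identical(tab, simulate_traits(tree, spec, seed = 2))

  spec0 <- simulation_spec(n_species = 50, n_missing = 0, n_museum = 20,
                           n_museum_missing = 0)
  tab0 <- simulate_traits(simulate_yule(50, seed = 3), spec0, seed = 3)
  expect_false(anyNA(tab0))
})

test_that("response simulation matches its generative covariance", {
  tr <- simulate_yule(10, seed = 11)
  V <- vcv_from_tree(tr)
  X <- cbind(1, rnorm(10))
  # zero total variance: y = X beta exactly
  y0 <- simulate_response(X, V, c(2, 1), lambda_true = 0.5, s2_total = 0,
                          seed = 1)
  expect_equal(y0, drop(X %*% c(2, 1)))

  # Monte-Carlo covariance oracle over replicate draws
  reps <- sapply(1:5000, function(s)
    simulate_response(X * 0, V, c(0, 0), lambda_true = 0, s2_total = 2,
                      seed = s))
  emp0 <- cov(t(reps))
  expect_lt(max(abs(emp0 - 2 * diag(10))), 0.1 * 2)

  reps1 <- sapply(1:5000, function(s)
    simulate_response(X * 0, V, c(0, 0), lambda_true = 1, s2_total = 2,
                      seed = s))
  emp1 <- cov(t(reps1))
  expect_lt(max(abs(emp1 - 2 * V)), 0.1 * 2)
})

test_that("wing images carry the 5%-of-patches contrast rule as truth label", {
  two <- generate_wing_image(grid = 8, second_fraction = 0.5, seed = 1)
  expect_true(two$contrasting)
  one <- generate_wing_image(grid = 8, second_fraction = 0, seed = 1)
  expect_false(one$contrasting)
  # exactly 4% of patches in the second colour: below the >5% rule
  four <- generate_wing_image(grid = 10, second_fraction = 0.04, seed = 1)
  expect_equal(four$patch_counts[2], 4)
  expect_false(four$contrasting)
  # 6% is above the rule
  six <- generate_wing_image(grid = 10, second_fraction = 0.06, seed = 1)
  expect_true(six$contrasting)

  # contrast separation: contrasting images have higher RMS in every batch
  for (s in 1:3) {
    rms_of <- function(frac, seed) {
      w <- generate_wing_image(size = 32, second_fraction = frac, seed = seed)
      mask <- remove_background(w$image, c(255, 0, 255))
      suppressWarnings(rms_contrast(to_grayscale(w$image), mask)$rms)
    }
    con <- sapply(1:5, function(i) rms_of(0.5, s * 100 + i))
    non <- sapply(1:5, function(i) rms_of(0, s * 200 + i))
    expect_gt(mean(con), mean(non))
  }
})

test_that("scorer panel has the binomial error structure and is seed-pure", {
  truth <- rep(c(TRUE, FALSE), 50)
  v0 <- simulate_scorer_panel(truth, n_scorers = 30, flip_rate = 0, seed = 1)
  expect_true(all(score_image(v0) %in% c(0, 30)))
  expect_equal(unname(score_image(v0)), 30 * as.integer(truth))

  vh <- simulate_scorer_panel(rep(TRUE, 400), n_scorers = 30,
                              flip_rate = 0.5, seed = 2)
  expect_lt(abs(mean(score_image(vh)) - 15) / 15, 0.05)

  expect_identical(simulate_scorer_panel(truth, 30, 0.1, seed = 3),
                   simulate_scorer_panel(truth, 30, 0.1, seed = 3))
  expect_error(simulate_scorer_panel(truth, 30, flip_rate = 0.7), "flip_rate")
})

test_that("full dataset generation is consistent and seed-reproducible", {
  spec <- simulation_spec(n_species = 80, n_missing = 8, n_museum = 30,
                          n_museum_missing = 2, n_trees = 2, image_size = 24)
  ds <- simulate_dataset(spec, seed = 5)
  expect_equal(length(ds$trees), 2)
  expect_true(all(ds$traits$species_id %in% ds$trees[[1]]$tip.label))
  expect_equal(nrow(ds$votes), 30)
  expect_equal(length(ds$images), 30)
  expect_equal(names(ds$ground_truth$latent_score), ds$traits$species_id)
  ds2 <- simulate_dataset(spec, seed = 5)
  expect_identical(ds$traits, ds2$traits)
  expect_identical(unclass(ds$votes), unclass(ds2$votes))

  # disk round trip preserves the vote matrix and tree count
  td <- withr::local_tempdir()
  write_dataset(ds, td)
  trees <- read_newick(file.path(td, "trees.nwk"))
  expect_equal(length(trees), 2)
  votes <- read_votes(file.path(td, "votes.csv"))
  expect_equal(sort(rownames(votes)), sort(rownames(ds$votes)))
})

test_that("generated datasets allow end-to-end recovery of the coefficients", {
  # 50 replicate datasets at reduced scale; the 95% intervals should cover
  # the simulation truths in >= 90% of (run, coefficient) cases (pooled:
  # per-coefficient rates at 50 replicates carry +-4% binomial noise)
  spec <- simulation_spec(n_species = 200, n_missing = 10, n_museum = 60,
                          n_museum_missing = 3, n_trees = 1,
                          lambda_true = 0.5, s2_total = 9)
  covered <- matrix(NA, 50, 7)
  for (r in 1:50) {
    ds <- simulate_dataset(spec, seed = 3000 + r, images = FALSE)
    flt <- filter_missing(ds$traits)
    des <- build_design(flt$table, response = "manual")
    tr <- match_tree_species(ds$trees[[1]], des$species_id, prune = TRUE)
    V <- vcv_from_tree(tr)
    f <- fit_mcmc(des$y, des$X, V, schedule = mcmc_schedule(6000, 600, 6,
                                                            seed = r),
                  species_id = des$species_id)
    truth <- spec$beta_true[f$summary$coef]
    covered[r, ] <- f$summary$ci_lower <= truth & truth <= f$summary$ci_upper
  }
  expect_gte(mean(covered), 0.90)
  # and no coefficient collapses outright
  expect_true(all(colMeans(covered) >= 0.80))
})
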