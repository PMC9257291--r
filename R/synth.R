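## Synthetic-data generator: every input the pipeline consumes — trees,
## traits, responses, wing images and scorer panels — with stored ground
## truth, so each analysis stage can be verified end to end.

#' Simulation specification
#'
#' Defaults mirror the scale of the empirical study: 1980 species, 200 of
#' them with at least one missing trait, 682 with museum images of which 17
#' are among the incomplete records (so the museum subset retains 665 after
#' filtering), a 30-scorer panel, and a response generated with the model's
#' own structure — fixed effects plus a phylogenetic random effect carrying a
#' fraction `lambda_true` of the total variance.
#'
#' Coefficients are ordered as in the design matrix: intercept, nocturnal,
#' colonial, centred log mass, centred log flock size, centred sqrt predator
#' count, coloniality x log mass.
#'
#' @param n_species total species count.
#' @param n_missing species carrying at least one missing trait.
#' @param n_museum species with museum images.
#' @param n_museum_missing incomplete records within the museum subset.
#' @param beta_true length-7 named coefficient vector.
#' @param lambda_true phylogenetic variance fraction in `[0, 1]`.
#' @param s2_total total (phylo + residual) variance of the response.
#' @param n_trees candidate trees in the simulated tree set (a base Yule
#'   tree plus age-jittered variants of it, emulating a posterior set of
#'   dated estimates of one phylogeny).
#' @param tree_jitter_sd lognormal node-age noise of the non-base trees.
#' @param birth_rate Yule speciation rate.
#' @param n_scorers panel size.
#' @param flip_rate per-vote scorer error probability in `[0, 0.5]`.
#' @param image_size wing image side length in pixels.
#' @param patch_grid patch grid dimension (grid x grid patches).
#' @param colonial_mass_slope logit-scale dependence of coloniality on
#'   centred log mass (0 = independent, the default, so recovery tests are
#'   unconfounded).
#' @param phylo_predictors evolve log mass by Brownian motion on the tree
#'   (default `TRUE`, matching the confounding real data carry); `FALSE`
#'   draws it iid for clean unit tests.
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(n_species = 1980, n_missing = 200,
                            n_museum = 682, n_museum_missing = 17,
                            beta_true = c(`(Intercept)` = 10.276,
                                          nocturnal = -7.241,
                                          colonial = 0.789,
                                          log_mass_c = 0.700,
                                          log_flock_c = 0.107,
                                          sqrt_pred_c = 0.138,
                                          `colonial:log_mass_c` = 0.973),
                            lambda_true = 0.77, s2_total = 25,
                            n_trees = 10, tree_jitter_sd = 0.1,
                            birth_rate = 1,
                            n_scorers = 30, flip_rate = 0.1,
                            image_size = 48, patch_grid = 8,
                            colonial_mass_slope = 0,
                            phylo_predictors = TRUE) {
  stopifnot(lambda_true >= 0, lambda_true <= 1, s2_total > 0,
            n_museum <= n_species, n_missing <= n_species,
            n_museum_missing <= min(n_missing, n_museum),
            flip_rate >= 0, flip_rate <= 0.5, patch_grid >= 2)
  structure(as.list(environment()), class = "simulation_spec")
}

## Draw a multivariate normal with covariance s2 * V via the eigenbasis.
rmvn_phylo <- function(V, s2) {
  eg <- eigen_vcv(V)
  drop(eg$vectors %*% (sqrt(eg$values * s2) * stats::rnorm(nrow(V))))
}

#' Simulate the species trait table (without response)
#'
#' Log body mass evolves by Brownian motion on the tree (predictors
#' themselves carry phylogenetic signal, as in real comparative data) unless
#' `spec$phylo_predictors` is `FALSE`; flock size is log-normal; coloniality
#' is Bernoulli with optional mass-dependent logit; predator count is
#' Poisson; activity time is Bernoulli with a small nocturnal probability.
#' Missingness is then imposed on exactly `n_missing` species (each losing
#' at least one of the five traits), split between the museum and non-museum
#' strata as the spec dictates.
#'
#' @param tree an `ape::phylo` with `n_species` tips.
#' @param spec a [simulation_spec()].
#' @param seed integer seed.
#' @return data frame: `species_id`, the five traits, `has_museum_image`.
#' @export
simulate_traits <- function(tree, spec, seed = 1L) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- spec$n_species
  if (length(tree$tip.label) != n)
    stop("tree has ", length(tree$tip.label), " tips but spec$n_species = ", n)
  set.seed(seed)
  V <- vcv_from_tree(tree, scale = TRUE)
  mu_lm <- log(100); s_lm <- 1.5   # geometric-mean mass 100 g, sd 1.5 on log scale
  log_mass <- if (spec$phylo_predictors) mu_lm + rmvn_phylo(V, s_lm^2)
              else stats::rnorm(n, mu_lm, s_lm)
  tab <- data.frame(
    species_id = tree$tip.label,
    mass_g = exp(log_mass),
    flock_size = stats::rlnorm(n, meanlog = 1.5, sdlog = 1),
    colonial = stats::rbinom(n, 1, stats::plogis(
      stats::qlogis(0.25) + spec$colonial_mass_slope * (log_mass - mu_lm))),
    n_predators = stats::rpois(n, 30),
    activity = stats::rbinom(n, 1, 0.05),
    stringsAsFactors = FALSE
  )
  museum <- sample.int(n, spec$n_museum)
  tab$has_museum_image <- seq_len(n) %in% museum
  miss_museum <- sample(museum, spec$n_museum_missing)
  miss_other <- sample(setdiff(seq_len(n), museum),
                       spec$n_missing - spec$n_museum_missing)
  for (i in c(miss_museum, miss_other)) {
    j <- sample(TRAIT_COLS, 1)
    tab[i, j] <- NA
  }
  tab
}

#' Simulate a Gaussian response with phylogenetic structure
#'
#' The generative model the inference assumes:
#' `y = X beta + u + e` with `u ~ N(0, s2_p V)` and `e ~ N(0, s2_e I)`,
#' `s2_p = lambda_true * s2_total`, `s2_e = (1 - lambda_true) * s2_total`.
#'
#' @param X model matrix (rows in tree tip order).
#' @param V scaled phylogenetic covariance, same order.
#' @param beta_true coefficient vector matching `ncol(X)`.
#' @param lambda_true phylogenetic variance fraction.
#' @param s2_total total variance.
#' @param seed integer seed.
#' @return numeric response vector.
#' @export
simulate_response <- function(X, V, beta_true, lambda_true, s2_total,
                              seed = 1L) {
  X <- as.matrix(X)
  if (ncol(X) != length(beta_true)) stop("beta_true length must match ncol(X)")
  if (nrow(X) != nrow(V)) stop("dimension mismatch between X and V")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X)
  u <- if (lambda_true > 0) rmvn_phylo(V, lambda_true * s2_total) else 0
  e <- stats::rnorm(n, 0, sqrt((1 - lambda_true) * s2_total))
  drop(X %*% beta_true) + u + e
}

#' Generate a synthetic museum-style wing image
#'
#' An elliptical "wing" on a uniform key-colour background, tiled with a
#' grid of colour patches drawn from a two-colour palette. The truth label
#' is contrasting exactly when each of (at least) two colours covers more
#' than 5% of the patches.
#'
#' @param size image side length in pixels.
#' @param grid patch grid dimension (`grid x grid` patches over the wing's
#'   bounding box).
#' @param colours 2 x 3 matrix of RGB rows on 0--255 (default black & white).
#' @param second_fraction fraction of patches given the second colour.
#' @param key_colour background RGB (default magenta, easy to key out).
#' @param seed integer seed (placement of second-colour patches).
#' @return list: `image` (an [rgb_image()]), `contrasting` (truth label),
#'   `patch_counts` (patches per colour).
#' @export
generate_wing_image <- function(size = 48, grid = 8,
                                colours = rbind(c(20, 20, 20),
                                                c(235, 235, 235)),
                                second_fraction = 0.5,
                                key_colour = c(255, 0, 255), seed = 1L) {
  stopifnot(grid >= 2, nrow(colours) == 2)
  set.seed(seed)
  n2 <- round(second_fraction * grid^2)
  patch_col <- rep(1L, grid^2)
  if (n2 > 0) patch_col[sample.int(grid^2, n2)] <- 2L
  counts <- tabulate(patch_col, 2L)
  contrasting <- sum(counts > 0.05 * grid^2) >= 2

  arr <- array(0, c(size, size, 3))
  for (ch in 1:3) arr[, , ch] <- key_colour[ch]
  cx <- cy <- (size + 1) / 2
  rx <- 0.45 * size; ry <- 0.3 * size
  xs <- matrix(rep(seq_len(size), each = size), size)   # column index
  ys <- matrix(rep(seq_len(size), size), size)          # row index
  wing <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
  ## map each wing pixel to its patch in the ellipse bounding box
  px <- pmin(grid, pmax(1, ceiling((xs - (cx - rx)) / (2 * rx) * grid)))
  py <- pmin(grid, pmax(1, ceiling((ys - (cy - ry)) / (2 * ry) * grid)))
  pid <- (py - 1L) * grid + px
  for (ch in 1:3) {
    plane <- arr[, , ch]
    plane[wing] <- colours[patch_col[pid[wing]], ch]
    arr[, , ch] <- plane
  }
  list(image = rgb_image(arr), contrasting = contrasting,
       patch_counts = counts)
}

#' Simulate a multi-scorer vote panel
#'
#' Each scorer's vote equals the truth label flipped independently with
#' probability `flip_rate`.
#'
#' @param truth logical (or 0/1) vector of per-image truth labels.
#' @param n_scorers panel size S.
#' @param flip_rate error probability in `[0, 0.5]`.
#' @param seed integer seed.
#' @return a [vote_matrix()], images x scorers.
#' @export
simulate_scorer_panel <- function(truth, n_scorers = 30, flip_rate = 0.1,
                                  seed = 1L) {
  stopifnot(flip_rate >= 0, flip_rate <= 0.5, n_scorers >= 1)
  set.seed(seed)
  truth <- as.integer(as.logical(truth))
  flips <- matrix(stats::rbinom(length(truth) * n_scorers, 1, flip_rate),
                  length(truth), n_scorers)
  votes <- abs(sweep(flips, 1, truth, `-`))   # truth XOR flip
  rownames(votes) <- names(truth) %||% paste0("img", seq_along(truth))
  colnames(votes) <- paste0("scorer", seq_len(n_scorers))
  vote_matrix(votes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a complete synthetic dataset
#'
#' Orchestrates the generator: a set of Yule trees, traits on the first
#' tree, the Gaussian response (stored as `manual_score`), image truth
#' labels for the museum subset (contrasting when the species' latent score
#' exceeds the median), wing images, and the scorer panel. Ground truth is
#' stored losslessly for recovery tests.
#'
#' @param spec a [simulation_spec()].
#' @param seed master seed; all stage seeds derive from it.
#' @param images generate the wing-image list (default `TRUE`); disable for
#'   model-only studies at large n.
#' @return a `synthetic_dataset` list: `trees`, `traits`, `votes`,
#'   `images` (named list of `rgb_image` or `NULL`), `manifest`, and
#'   `ground_truth` (`beta_true`, `lambda_true`, `s2_total`, latent scores,
#'   image truth labels, seeds).
#' @export
simulate_dataset <- function(spec = simulation_spec(), seed = 1L,
                             images = TRUE) {
  stopifnot(inherits(spec, "simulation_spec"))
  seeds <- derive_seeds(seed, 6)
  ## tree set = one base tree + age-jittered variants: alternative dated
  ## estimates of the same phylogeny, as a posterior tree sample would be
  tree <- simulate_yule(spec$n_species, spec$birth_rate, seed = seeds[1])
  trees <- c(list(tree),
             lapply(seq_len(spec$n_trees - 1L), function(i)
               jitter_tree(tree, sd = spec$tree_jitter_sd,
                           seed = seeds[1] + i)))
  traits <- simulate_traits(tree, spec, seed = seeds[2])

  ## response is generated from the COMPLETE traits, before missingness
  complete <- traits
  for (cl in TRAIT_COLS) {
    nas <- is.na(complete[[cl]])
    if (any(nas)) complete[[cl]][nas] <-
      stats::median(complete[[cl]], na.rm = TRUE)
  }
  complete$manual_score <- 0
  des <- build_design(complete, response = "manual")
  V <- vcv_from_tree(tree, scale = TRUE)
  y <- simulate_response(des$X, V, spec$beta_true[colnames(des$X)],
                         spec$lambda_true, spec$s2_total, seed = seeds[3])
  traits$manual_score <- y

  museum_ids <- traits$species_id[traits$has_museum_image]
  latent <- y[match(museum_ids, traits$species_id)]
  truth <- latent > stats::median(latent)
  names(truth) <- museum_ids

  img_list <- NULL
  manifest <- data.frame(species_id = museum_ids,
                         image_id = paste0(museum_ids, "_img1"),
                         path = NA_character_, source = "museum",
                         stringsAsFactors = FALSE)
  if (images) {
    img_seeds <- seeds[4] + seq_along(museum_ids) - 1L
    img_list <- lapply(seq_along(museum_ids), function(i) {
      frac <- if (truth[i]) 0.5 else 0
      generate_wing_image(spec$image_size, spec$patch_grid,
                          second_fraction = frac, seed = img_seeds[i])$image
    })
    names(img_list) <- manifest$image_id
  }
  votes <- simulate_scorer_panel(truth, spec$n_scorers, spec$flip_rate,
                                 seed = seeds[5])
  rownames(votes) <- manifest$image_id

  structure(list(
    trees = trees, traits = traits, votes = votes, images = img_list,
    manifest = manifest,
    ground_truth = list(beta_true = spec$beta_true,
                        lambda_true = spec$lambda_true,
                        s2_total = spec$s2_total,
                        latent_score = stats::setNames(y, traits$species_id),
                        image_truth = truth, master_seed = seed,
                        stage_seeds = seeds)
  ), class = "synthetic_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Emits the same artifact layout a real study would use: `trees.nwk` (one
#' Newick per line), `traits.csv`, `votes.csv` (long format),
#' `images/*.png` with `manifest.csv`, and `ground_truth.json`.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(vapply(ds$trees, ape::write.tree, character(1)),
             file.path(dir, "trees.nwk"))
  utils::write.csv(ds$traits, file.path(dir, "traits.csv"), row.names = FALSE)
  long <- data.frame(
    image_id = rep(rownames(ds$votes), ncol(ds$votes)),
    scorer_id = rep(colnames(ds$votes), each = nrow(ds$votes)),
    vote = as.vector(unclass(ds$votes)))
  utils::write.csv(long, file.path(dir, "votes.csv"), row.names = FALSE)
  manifest <- ds$manifest
  if (!is.null(ds$images)) {
    img_dir <- file.path(dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    manifest$path <- file.path(img_dir, paste0(manifest$image_id, ".png"))
    for (i in seq_len(nrow(manifest)))
      write_wing_image(ds$images[[manifest$image_id[i]]], manifest$path[i])
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  gt <- ds$ground_truth
  gt$latent_score <- as.list(gt$latent_score)
  gt$image_truth <- as.list(gt$image_truth)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
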