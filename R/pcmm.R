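## Bayesian phylogenetic Gaussian mixed model:
##   y = X beta + u + e,  u ~ N(0, s2_phylo * V),  e ~ N(0, s2_resid * I)
## fitted by parameter-expanded Gibbs sampling (the standard animal-model
## scheme for a single phylogenetic random effect), plus a profiled-GLS maximum
## likelihood fit used as an independent oracle, posterior diagnostics, and
## model averaging across a set of candidate trees.

#' Prior specification
#'
#' Residual variance: inverse-Wishart `(V, nu)`, i.e. scaled inverse
#' chi-squared. Phylogenetic variance: parameter-expanded — the random effect
#' is `u = alpha * g` with `g ~ N(0, s2_g V)` and a working scale
#' `alpha ~ N(alpha_mu, alpha_V)`; the reported variance component is
#' `alpha^2 s2_g`. Defaults are the weakly informative choice standard for
#' phylogenetic animal models: `R = (V = 1, nu = 0.002)`,
#' `G = (V = 1, nu = 1, alpha_mu = 0, alpha_V = 1000)`.
#'
#' @param resid_V,resid_nu residual inverse-Wishart scale and df.
#' @param g_V,g_nu phylo-variance inverse-Wishart scale and df.
#' @param alpha_mu,alpha_V working-parameter Gaussian prior.
#' @param beta_V prior variance of fixed effects (near-flat Gaussian).
#' @return a `prior_spec` list.
#' @export
prior_spec <- function(resid_V = 1, resid_nu = 0.002,
                       g_V = 1, g_nu = 1, alpha_mu = 0, alpha_V = 1000,
                       beta_V = 1e10) {
  stopifnot(resid_V > 0, resid_nu > 0, g_V > 0, g_nu > 0, alpha_V > 0,
            beta_V > 0)
  structure(list(resid_V = resid_V, resid_nu = resid_nu, g_V = g_V,
                 g_nu = g_nu, alpha_mu = alpha_mu, alpha_V = alpha_V,
                 beta_V = beta_V), class = "prior_spec")
}

#' MCMC schedule
#'
#' Defaults follow the standard long-chain protocol: 75 000 iterations,
#' 7500 burn-in, thinning every 40, retaining
#' `floor((n_iter - burn_in)/thin)` = 1687 draws.
#'
#' @param n_iter total iterations.
#' @param burn_in discarded initial iterations (`< n_iter`).
#' @param thin keep every `thin`-th post-burn-in draw (`>= 1`).
#' @param seed integer RNG seed.
#' @return an `mcmc_schedule` list with the retained-draw count `n_keep`.
#' @export
mcmc_schedule <- function(n_iter = 75000, burn_in = 7500, thin = 40,
                          seed = 1L) {
  stopifnot(burn_in < n_iter, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 n_keep = floor((n_iter - burn_in) / thin)),
            class = "mcmc_schedule")
}

## Align V to the row order of the data when both carry names.
align_vcv <- function(V, species_id) {
  if (is.null(species_id) || is.null(rownames(V))) return(V)
  missing_sp <- setdiff(species_id, rownames(V))
  if (length(missing_sp))
    stop("species absent from covariance matrix: ",
         paste(missing_sp, collapse = ", "))
  V[species_id, species_id]
}

## Eigendecomposition of V with a PSD check; the sampler works in the
## eigenbasis, where the full conditional of the phylogenetic effect has a
## diagonal precision.
eigen_vcv <- function(V, jitter = 1e-10) {
  eg <- eigen(V, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(eg$values))
    stop("phylogenetic covariance matrix is not positive semi-definite")
  eg$values <- pmax(eg$values, jitter)
  eg
}

#' Fit the phylogenetic mixed model by Gibbs sampling
#'
#' Parameter-expanded Gibbs sampler. All full conditionals are conjugate:
#' fixed effects and the (eigenbasis) phylogenetic effects are Gaussian, the
#' working scale `alpha` is Gaussian, and both variance components are
#' inverse-gamma. Working in the eigenbasis of `V` makes the phylogenetic
#' block a set of independent scalar updates, so no per-iteration matrix
#' factorization is needed.
#'
#' @param y numeric response vector (one record per species).
#' @param X model matrix with intercept, rows aligned with `y`.
#' @param V phylogenetic covariance matrix (unit diagonal after scaling);
#'   when it has dimnames and `species_id` is supplied, rows are aligned
#'   automatically.
#' @param prior a [prior_spec()].
#' @param schedule an [mcmc_schedule()].
#' @param species_id optional species ids for `V` alignment.
#' @return a `pcmm_fit`: retained draws (`beta`, `s2_phylo`, `s2_resid`,
#'   `lambda`), a per-coefficient summary table (posterior mean, 95% HPD
#'   interval, posterior sd, pMCMC, ESS), variance-component means, and
#'   `lambda_mean`, the posterior mean of
#'   `s2_phylo / (s2_phylo + s2_resid)` — the phylogenetic-heritability
#'   reading of Pagel's lambda.
#' @export
fit_mcmc <- function(y, X, V, prior = prior_spec(),
                     schedule = mcmc_schedule(), species_id = NULL) {
  stopifnot(inherits(prior, "prior_spec"), inherits(schedule, "mcmc_schedule"))
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  if (nrow(X) != n) stop("dimension mismatch between y and X")
  if (nrow(V) != n) stop("dimension mismatch between y and V")
  V <- align_vcv(V, species_id)
  eg <- eigen_vcv(V)
  Q <- eg$vectors; ev <- eg$values

  set.seed(schedule$seed)
  Xt <- t(X); XtX <- Xt %*% X
  Qty <- drop(crossprod(Q, y)); QtX <- crossprod(Q, X)
  Bprec <- diag(1 / prior$beta_V, p)

  beta <- qr.solve(X, y)
  s2g <- prior$g_V
  s2e <- max(stats::var(y - X %*% beta) / 2, 1e-8)
  alpha <- 1

  n_keep <- schedule$n_keep
  out_beta <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, colnames(X)))
  out_s2u <- out_s2e <- numeric(n_keep)
  k <- 0L
  for (it in seq_len(schedule$n_iter)) {
    ## phylogenetic effects (eigenbasis): diagonal Gaussian conditional
    r1 <- Qty - drop(QtX %*% beta)
    vv <- 1 / (alpha^2 / s2e + 1 / (ev * s2g))
    gt <- stats::rnorm(n, vv * alpha * r1 / s2e, sqrt(vv))
    u <- drop(Q %*% gt)
    ## working scale alpha: scalar Gaussian conditional
    ry <- y - drop(X %*% beta)
    pa <- sum(u^2) / s2e + 1 / prior$alpha_V
    ma <- (sum(u * ry) / s2e + prior$alpha_mu / prior$alpha_V) / pa
    alpha <- stats::rnorm(1, ma, sqrt(1 / pa))
    ## fixed effects: Gaussian conditional
    rb <- y - alpha * u
    ch <- chol(XtX / s2e + Bprec)
    mb <- backsolve(ch, forwardsolve(t(ch), Xt %*% rb / s2e))
    beta <- drop(mb + backsolve(ch, stats::rnorm(p)))
    ## variance components: inverse-gamma conditionals
    s2g <- 1 / stats::rgamma(1, (prior$g_nu + n) / 2,
                             (prior$g_nu * prior$g_V + sum(gt^2 / ev)) / 2)
    ee <- y - drop(X %*% beta) - alpha * u
    s2e <- 1 / stats::rgamma(1, (prior$resid_nu + n) / 2,
                             (prior$resid_nu * prior$resid_V + sum(ee^2)) / 2)
    if (!is.finite(s2e) || !is.finite(s2g))
      stop("divergent variance draw at iteration ", it)
    if (it > schedule$burn_in && (it - schedule$burn_in) %% schedule$thin == 0) {
      k <- k + 1L
      out_beta[k, ] <- beta
      out_s2u[k] <- alpha^2 * s2g
      out_s2e[k] <- s2e
    }
  }

  lambda_draws <- out_s2u / (out_s2u + out_s2e)
  summ <- data.frame(
    coef = colnames(X),
    post_mean = colMeans(out_beta),
    ci_lower = apply(out_beta, 2, function(x) hpd_interval(x)[1]),
    ci_upper = apply(out_beta, 2, function(x) hpd_interval(x)[2]),
    post_sd = apply(out_beta, 2, stats::sd),
    pMCMC = apply(out_beta, 2, pmcmc),
    ess = apply(out_beta, 2, effective_sample_size),
    row.names = NULL
  )
  structure(list(
    draws = list(beta = out_beta, s2_phylo = out_s2u, s2_resid = out_s2e,
                 lambda = lambda_draws),
    summary = summ,
    vc = c(s2_phylo = mean(out_s2u), s2_resid = mean(out_s2e)),
    lambda_mean = mean(lambda_draws),
    schedule = schedule, prior = prior
  ), class = "pcmm_fit")
}

#' @export
print.pcmm_fit <- function(x, ...) {
  cat("Phylogenetic mixed model (Gibbs),", x$schedule$n_keep, "retained draws\n")
  print(x$summary, digits = 4)
  cat(sprintf("s2_phylo = %.4g, s2_resid = %.4g, lambda = %.3f\n",
              x$vc["s2_phylo"], x$vc["s2_resid"], x$lambda_mean))
  invisible(x)
}

#' Profiled-GLS maximum-likelihood fit (oracle)
#'
#' Independent check on the sampler: for each lambda on a grid the error
#' covariance is `lambda * V + (1 - lambda) * I` (unit-diagonal `V`), the
#' total variance is profiled out analytically, and the lambda maximizing the
#' profile log-likelihood is returned together with the GLS coefficients at
#' that lambda.
#'
#' @param y,X,V as in [fit_mcmc()].
#' @param lam_grid lambda grid (default 0 to 1 by 0.01).
#' @param species_id optional ids for `V` alignment.
#' @return list with `beta` (named), `beta_se`, `lambda`, `sigma2` (ML total
#'   variance), `loglik`, and the full `profile` table.
#' @export
fit_gls <- function(y, X, V, lam_grid = seq(0, 1, by = 0.01),
                    species_id = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  V <- align_vcv(V, species_id)
  eg <- eigen_vcv(V)
  Q <- eg$vectors; ev <- eg$values
  yt <- drop(crossprod(Q, y)); Xt <- crossprod(Q, X)

  eval_lam <- function(h) {
    d <- h * ev + (1 - h)            # eigenvalues of h*V + (1-h)I
    if (min(d) <= 0) return(NULL)
    w <- 1 / d
    XtWX <- crossprod(Xt, Xt * w)
    XtWy <- crossprod(Xt, yt * w)
    b <- tryCatch(solve(XtWX, XtWy), error = function(e)
      stop("singular X'WX in GLS fit"))
    r <- yt - Xt %*% b
    rss <- sum(w * r^2)
    s2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * s2) + sum(log(d)) + n)
    list(beta = drop(b), s2 = s2, ll = ll, XtWX = XtWX)
  }
  prof <- lapply(lam_grid, eval_lam)
  ok <- !vapply(prof, is.null, logical(1))
  lls <- vapply(prof[ok], `[[`, numeric(1), "ll")
  best <- which.max(lls)
  fit <- prof[ok][[best]]
  beta <- fit$beta; names(beta) <- colnames(X)
  cov_b <- fit$s2 * solve(fit$XtWX) * n / (n - ncol(X))
  list(beta = beta, beta_se = sqrt(diag(cov_b)),
       lambda = lam_grid[ok][best], sigma2 = fit$s2, loglik = fit$ll,
       profile = data.frame(lambda = lam_grid[ok], loglik = lls))
}

#' MCMC sign probability (pMCMC)
#'
#' Twice the smaller of the posterior shares above and below zero, floored at
#' `1/n` per tail and capped at 1 — the Bayesian analogue of a two-sided
#' p-value reported for animal-model coefficients.
#'
#' @param samples numeric vector of retained draws.
#' @return a value in `(0, 1]`.
#' @export
pmcmc <- function(samples) {
  n <- length(samples)
  if (n < 2L) stop("pMCMC needs at least 2 samples")
  tail_min <- max(min(mean(samples > 0), mean(samples < 0)), 1 / n)
  min(2 * tail_min, 1)
}

#' Effective sample size of an MCMC chain
#'
#' `n / (1 + 2 * sum(rho_k))` with the initial-positive-sequence rule:
#' autocorrelations are summed in consecutive pairs and truncated at the
#' first pair with a negative sum. A constant chain has ESS 0 (with a
#' warning).
#'
#' @param samples numeric chain (length >= 10).
#' @param max_lag autocorrelation lags examined (default `length - 1`,
#'   capped at 10 000).
#' @return effective sample size.
#' @export
effective_sample_size <- function(samples, max_lag = NULL) {
  n <- length(samples)
  if (n < 10L) stop("ESS needs at least 10 samples")
  if (stats::var(samples) == 0) {
    warning("constant chain; ESS reported as 0")
    return(0)
  }
  if (is.null(max_lag)) max_lag <- min(n - 1L, 10000L)
  rho <- drop(stats::acf(samples, lag.max = max_lag, plot = FALSE)$acf)[-1]
  s <- 0; k <- 1L
  while (k + 1L <= length(rho)) {
    g <- rho[k] + rho[k + 1L]
    if (g < 0) break
    s <- s + g
    k <- k + 2L
  }
  n / (1 + 2 * s)
}

#' Highest-posterior-density interval
#'
#' Shortest interval containing a `prob` share of the draws; set
#' `method = "quantile"` for the central quantile interval instead.
#'
#' @param samples numeric draws.
#' @param prob coverage (default 0.95).
#' @param method `"hpd"` (default) or `"quantile"`.
#' @return length-2 vector `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, prob = 0.95, method = c("hpd", "quantile")) {
  method <- match.arg(method)
  if (method == "quantile")
    return(unname(stats::quantile(samples, c((1 - prob) / 2, (1 + prob) / 2))))
  x <- sort(samples)
  n <- length(x)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(x[1], x[n]))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(x[i], x[i + m])
}

## Deterministic per-tree seeds from a master seed.
derive_seeds <- function(master, k) {
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, k)
}

#' Fit the model across a set of candidate trees and average
#'
#' Absorbs phylogenetic uncertainty the standard way: sample `k` trees
#' without replacement, fit the identical model on each, and average the
#' posterior means, pMCMC values and lambda arithmetically across models.
#' The reported `se` is the mean of the per-model posterior standard
#' deviations. Per-tree seeds are derived deterministically from `seed`.
#'
#' @param y,X,prior,schedule as in [fit_mcmc()].
#' @param trees list (or `multiPhylo`) of candidate phylogenies.
#' @param k number of trees to sample (`<= length(trees)`).
#' @param seed master seed for tree sampling and per-tree chains.
#' @param species_id species ids ordering `y`/`X`; used to align each tree.
#' @return an `averaged_result`: coefficient table (`post_mean`, `se`,
#'   `pMCMC`, `ess` averaged over trees), `lambda_mean`, `tree_count`, and
#'   the per-tree fits.
#' @export
fit_tree_set <- function(y, X, trees, k = length(trees),
                         prior = prior_spec(), schedule = mcmc_schedule(),
                         seed = schedule$seed, species_id = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (k > length(trees)) stop("k exceeds the number of trees supplied")
  set.seed(seed)
  idx <- sample.int(length(trees), k)
  seeds <- derive_seeds(seed, k)
  fits <- vector("list", k)
  for (i in seq_len(k)) {
    tr <- trees[[idx[i]]]
    V <- vcv_from_tree(tr, scale = TRUE)
    sch <- schedule; sch$seed <- seeds[i]
    fits[[i]] <- tryCatch(
      fit_mcmc(y, X, V, prior, sch, species_id = species_id),
      error = function(e) stop("model fit failed on tree ", idx[i], ": ",
                               conditionMessage(e)))
  }
  tab <- Reduce(`+`, lapply(fits, function(f)
    as.matrix(f$summary[, c("post_mean", "post_sd", "pMCMC", "ess")]))) / k
  coef_tab <- data.frame(coef = fits[[1]]$summary$coef,
                         post_mean = tab[, "post_mean"], se = tab[, "post_sd"],
                         pMCMC = tab[, "pMCMC"], ess = tab[, "ess"],
                         row.names = NULL)
  structure(list(coefficients = coef_tab,
                 lambda_mean = mean(vapply(fits, `[[`, numeric(1), "lambda_mean")),
                 tree_count = k, tree_index = idx, fits = fits),
            class = "averaged_result")
}

#' @export
print.averaged_result <- function(x, ...) {
  cat("Model averaging over", x$tree_count, "trees\n")
  print(x$coefficients, digits = 4)
  cat(sprintf("mean lambda = %.3f\n", x$lambda_mean))
  invisible(x)
}

#' Validation regression of manual scores on RMS contrast
#'
#' Phylogenetic single-predictor model of the species manual contrast score
#' on the standardized log-RMS contrast score, used to check that the
#' human-scored and image-derived measures agree. Reports the slope summary
#' and a Bayesian marginal R-squared: per retained draw,
#' `Var(X beta) / (Var(X beta) + s2_phylo + s2_resid)`, averaged over draws.
#'
#' @param manual_scores numeric species manual scores.
#' @param log_rms_scores numeric species log-RMS scores (standardized
#'   internally).
#' @param V phylogenetic covariance from one tree, aligned or nameable.
#' @param prior,schedule,species_id as in [fit_mcmc()].
#' @return list with `slope` (posterior mean), `slope_ci`, `pMCMC`,
#'   `r_squared` (posterior mean), and the underlying `fit`.
#' @export
validation_regression <- function(manual_scores, log_rms_scores, V,
                                  prior = prior_spec(),
                                  schedule = mcmc_schedule(),
                                  species_id = NULL) {
  x <- as.numeric(scale(log_rms_scores))
  X <- cbind(`(Intercept)` = 1, log_rms_std = x)
  fit <- fit_mcmc(manual_scores, X, V, prior, schedule, species_id = species_id)
  fitted_var <- apply(fit$draws$beta %*% t(X), 1, stats::var)
  r2 <- fitted_var / (fitted_var + fit$draws$s2_phylo + fit$draws$s2_resid)
  list(slope = fit$summary$post_mean[2],
       slope_ci = c(fit$summary$ci_lower[2], fit$summary$ci_upper[2]),
       pMCMC = fit$summary$pMCMC[2],
       r_squared = mean(r2),
       fit = fit)
}
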