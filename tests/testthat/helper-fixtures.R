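# Fixtures are built in code at test time; nothing is read from disk.

# The 3-tip worked tree ((A:1,B:1):1,C:2) whose shared-path matrix is
# known by hand: [[2,1,0],[1,2,0],[0,0,2]].
tiny_tree <- function() read_newick("((A:1,B:1):1,C:2);")

# A small complete trait table with known values.
tiny_traits <- function(n = 12, seed = 1) {
  set.seed(seed)
  data.frame(
    species_id = paste0("sp", seq_len(n)),
    mass_g = exp(rnorm(n, log(100), 1)),
    flock_size = rlnorm(n, 1, 0.5),
    colonial = rbinom(n, 1, 0.4),
    n_predators = rpois(n, 16),
    activity = rbinom(n, 1, 0.2),
    manual_score = runif(n, 0, 30),
    stringsAsFactors = FALSE
  )
}

# Simulated regression problem on a Yule tree with known (beta, lambda):
# the generative model the sampler assumes.
sim_phylo_data <- function(n = 200, lambda = 0.6, s2 = 4,
                           beta = c(2, 1, -0.5), seed = 1) {
  # one seeded stream per dataset: tree, predictors and response draws all
  # advance the same RNG state, so different seeds give unrelated datasets
  set.seed(seed)
  tree <- simulate_yule(n, seed = NULL)
  V <- vcv_from_tree(tree)
  X <- cbind(1, matrix(rnorm(n * (length(beta) - 1)), n))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(length(beta) - 1)))
  y <- simulate_response(X, V, beta, lambda, s2, seed = NULL)
  list(y = y, X = X, V = V, tree = tree, beta = beta, lambda = lambda)
}

short_schedule <- function(n_iter = 4000, burn_in = 400, thin = 5, seed = 1)
  mcmc_schedule(n_iter, burn_in, thin, seed)
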