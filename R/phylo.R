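## Phylogeny plumbing: Newick I/O, the phylogenetic covariance matrix,
## Pagel's lambda transform, and Yule tree simulation for tests.

#' Read a rooted phylogeny from a Newick string or file
#'
#' @param text a Newick string (containing `(`) or a file path; files may
#'   hold one tree per line (a tree set), in which case a list is returned.
#' @return an `ape::phylo` object, or a `multiPhylo` list for tree sets.
#' @export
read_newick <- function(text) {
  tr <- if (grepl("(", text, fixed = TRUE)) ape::read.tree(text = text)
        else ape::read.tree(file = text)
  if (is.null(tr)) stop("malformed Newick input")
  check1 <- function(t) {
    if (anyDuplicated(t$tip.label)) stop("duplicate tip labels")
    if (is.null(t$edge.length)) stop("Newick tree lacks branch lengths")
    t
  }
  if (inherits(tr, "multiPhylo")) { lapply(tr, check1); tr } else check1(tr)
}

#' Write a phylogeny to Newick
#'
#' @param tree an `ape::phylo`.
#' @param path optional file path; when `NULL` the Newick string is returned.
#' @return the Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Phylogenetic covariance matrix of a tree
#'
#' Entry (i, j) is the shared root-to-tip path length of tips i and j — the
#' covariance structure Brownian evolution induces. For an ultrametric tree,
#' scaling by the tree height gives unit diagonal, which makes variance
#' components comparable across trees of different depths.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param scale divide by the maximum tip depth (default `TRUE`).
#' @return symmetric PSD matrix with tip labels as dimnames.
#' @export
vcv_from_tree <- function(tree, scale = TRUE) {
  if (any(tree$edge.length < 0)) stop("negative branch length")
  V <- ape::vcv(tree)
  if (scale) V <- V / max(diag(V))
  V
}

#' Pagel's lambda transform of a scaled covariance matrix
#'
#' Multiplies the off-diagonal entries by `lam`, leaving the diagonal
#' unchanged: `lam = 1` is the untransformed Brownian structure, `lam = 0`
#' the star phylogeny (independence). Composing transforms multiplies the
#' lambdas.
#'
#' @param V scaled phylogenetic covariance matrix.
#' @param lam signal strength in `[0, 1]`.
#' @return transformed matrix.
#' @export
lambda_transform <- function(V, lam) {
  if (lam < 0 || lam > 1) stop("lambda must lie in [0, 1]")
  W <- V * lam
  diag(W) <- diag(V)
  W
}

#' Simulate an ultrametric Yule (pure-birth) tree
#'
#' Stand-in for posterior tree sets: reproducible under `seed`, with tips
#' labelled `sp1..spN`.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate (> 0).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return an `ape::phylo`, ultrametric with exactly `n_tips` tips.
#' @export
simulate_yule <- function(n_tips, birth_rate = 1, seed = NULL) {
  stopifnot(n_tips >= 2, birth_rate > 0)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  tr$tip.label <- paste0("sp", seq_len(n_tips))
  tr
}

#' Perturb the node ages of an ultrametric tree
#'
#' Emulates the phylogenetic uncertainty of a posterior tree set: internal
#' node ages are multiplied by independent lognormal noise, parent-older-
#' than-child constraints are re-imposed by a postorder sweep, and edge
#' lengths are rebuilt from the new ages. Topology and ultrametricity are
#' preserved, so a jittered set behaves like alternative dated estimates of
#' the same phylogeny rather than unrelated trees.
#'
#' @param tree a rooted ultrametric `ape::phylo`.
#' @param sd standard deviation of the log-normal age noise (default 0.1).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return an `ape::phylo` with the same topology and perturbed ages.
#' @export
jitter_tree <- function(tree, sd = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is_ultrametric(tree, tol = 1e-6)) stop("tree must be ultrametric")
  n_tip <- length(tree$tip.label)
  ages <- numeric(n_tip + tree$Nnode)
  bt <- ape::branching.times(tree)
  ages[as.integer(names(bt))] <- bt * exp(stats::rnorm(length(bt), 0, sd))
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edge))) {   # children are final before parents
    p <- edge[k, 1]; ch <- edge[k, 2]
    ages[p] <- max(ages[p], ages[ch] + 1e-8)
  }
  out <- tree
  out$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  out
}

#' Check species/tree label agreement, optionally pruning
#'
#' Tip labels must match `species_id` exactly (case-sensitive). With
#' `prune = TRUE` the tree is pruned to the species present; otherwise any
#' mismatch is an error reporting the offending labels.
#'
#' @param tree an `ape::phylo`.
#' @param species_id character vector of species present in the data.
#' @param prune drop tree tips absent from `species_id` (default `FALSE`).
#' @return the (possibly pruned) tree.
#' @export
match_tree_species <- function(tree, species_id, prune = FALSE) {
  missing_in_tree <- setdiff(species_id, tree$tip.label)
  if (length(missing_in_tree))
    stop("species absent from tree: ", paste(missing_in_tree, collapse = ", "))
  extra <- setdiff(tree$tip.label, species_id)
  if (length(extra)) {
    if (!prune)
      stop("tree tips absent from data: ", paste(extra, collapse = ", "))
    tree <- ape::drop.tip(tree, extra)
  }
  tree
}

#' Is a tree ultrametric?
#'
#' @param tree an `ape::phylo`.
#' @param tol relative spread of tip depths tolerated (default 1e-6).
#' @return logical.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  d <- diag(ape::vcv(tree))
  (max(d) - min(d)) <= tol * max(d)
}
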