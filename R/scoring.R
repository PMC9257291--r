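## Multi-scorer manual contrast scores: aggregate a panel of binary
## contrasting / non-contrasting votes into image and species scores.

#' Validate and construct a vote matrix
#'
#' Every scorer classifies every image (a complete panel design); ragged
#' panels are rejected rather than imputed. Votes are 1 = "contrasting",
#' 0 = "non-contrasting".
#'
#' @param votes numeric matrix, images in rows and scorers in columns, all
#'   entries 0 or 1, with image ids as rownames.
#' @return the validated matrix, classed `vote_matrix`.
#' @export
vote_matrix <- function(votes) {
  votes <- as.matrix(votes)
  if (anyNA(votes))
    stop("vote matrix has missing votes; every scorer must score every image")
  if (!all(votes %in% c(0, 1)))
    stop("votes must be binary (0 = non-contrasting, 1 = contrasting)")
  if (ncol(votes) < 1L) stop("at least one scorer is required")
  if (is.null(rownames(votes)))
    rownames(votes) <- paste0("img", seq_len(nrow(votes)))
  class(votes) <- c("vote_matrix", class(votes))
  votes
}

#' Read votes from a long-format CSV
#'
#' Expects columns `image_id`, `scorer_id`, `vote`; pivots to the wide
#' image x scorer matrix and checks completeness.
#'
#' @param path CSV file path.
#' @return a `vote_matrix`.
#' @export
read_votes <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image_id", "scorer_id", "vote") %in% names(long)))
    stop("votes CSV must have columns image_id, scorer_id, vote")
  wide <- stats::xtabs(vote ~ image_id + scorer_id, data = long)
  counts <- stats::xtabs(~ image_id + scorer_id, data = long)
  if (any(counts != 1))
    stop("votes CSV is not a complete image x scorer design")
  m <- matrix(as.numeric(wide), nrow(wide), ncol(wide),
              dimnames = dimnames(wide))
  vote_matrix(m)
}

#' Manual contrast score of each image
#'
#' The manual score of an image is the number of scorers who classified it
#' as contrasting: with S scorers it ranges over 0..S (0..30 in the standard
#' 30-scorer protocol). The equivalent proportion scale is available via
#' `scale = "proportion"`.
#'
#' @param votes a `vote_matrix` (or coercible matrix).
#' @param scale `"count"` (default) or `"proportion"`.
#' @return named numeric vector of per-image scores.
#' @export
score_image <- function(votes, scale = c("count", "proportion")) {
  scale <- match.arg(scale)
  if (!inherits(votes, "vote_matrix")) votes <- vote_matrix(votes)
  s <- rowSums(unclass(votes))
  if (scale == "proportion") s <- s / ncol(votes)
  s
}

#' Species-level manual contrast score
#'
#' Averages the image scores of each species arithmetically; a species score
#' is therefore bounded by the minimum and maximum of its image scores.
#'
#' @param image_scores numeric vector of per-image scores.
#' @param species_ids character vector mapping each image to its species.
#' @return data frame with `species_id`, `n_images`, `manual_score`.
#' @export
score_species <- function(image_scores, species_ids) {
  if (length(image_scores) == 0L) stop("no image scores supplied")
  if (length(image_scores) != length(species_ids))
    stop("image_scores and species_ids lengths differ")
  m <- tapply(image_scores, species_ids, mean)
  out <- data.frame(species_id = names(m),
                    n_images = as.integer(table(species_ids)[names(m)]),
                    manual_score = as.numeric(m),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
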