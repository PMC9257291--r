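## Species trait table: missing-data filter, predictor transforms, design
## matrix assembly and collinearity diagnostics.

TRAIT_COLS <- c("mass_g", "flock_size", "colonial", "n_predators", "activity")

#' Drop species with incomplete trait data
#'
#' A species is removed when any of the five ecological traits (body mass,
#' flock size, coloniality, number of sympatric avian predators, activity
#' time) is missing, or when the response named in `response` is missing.
#' The filter is idempotent.
#'
#' @param table data frame with a unique `species_id` column and the five
#'   trait columns.
#' @param response optional response column name also required complete
#'   (e.g. `"manual_score"`).
#' @return list with `table` (retained rows) and `removed_count`.
#' @export
filter_missing <- function(table, response = NULL) {
  stopifnot(is.data.frame(table))
  if (anyDuplicated(table$species_id))
    stop("species_id must be unique")
  cols <- c(TRAIT_COLS, response)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols))
    stop("trait table lacks columns: ", paste(missing_cols, collapse = ", "))
  ok <- stats::complete.cases(table[, cols, drop = FALSE])
  list(table = table[ok, , drop = FALSE], removed_count = sum(!ok))
}

#' Build the model design matrix
#'
#' Applies the standard transforms — natural log of body mass and flock size,
#' square root of predator count — centres every continuous predictor at its
#' post-filter mean, and adds the coloniality x (centred log mass)
#' interaction. Baselines are non-colonial and diurnal. Centring offsets are
#' recorded so raw values can be reconstructed exactly.
#'
#' @param table a complete (filtered) trait table.
#' @param response `"manual"` (manual contrast score) or `"log_rms"`.
#' @param drop character vector of predictors to exclude, any of
#'   `"activity"`, `"flock_size"`, `"n_predators"`, `"colonial"`, `"mass"`
#'   (dropping `"colonial"` or `"mass"` also drops the interaction).
#' @return object of class `wing_design`: list with response vector `y`,
#'   model matrix `X` (intercept first), `species_id`, `offsets`
#'   (centring means), and `meta` (transforms and baselines).
#' @export
build_design <- function(table, response = c("manual", "log_rms"),
                         drop = character()) {
  response <- match.arg(response)
  resp_col <- switch(response, manual = "manual_score", log_rms = "log_rms")
  flt <- filter_missing(table, response = resp_col)
  table <- flt$table
  if (nrow(table) < 2L)
    stop("design needs at least 2 complete species; got ", nrow(table))
  bad <- table$species_id[table$mass_g <= 0]
  if (length(bad))
    stop("nonpositive body mass for species: ", paste(bad, collapse = ", "))
  if ("flock_size" %in% names(table)) {
    badf <- table$species_id[!is.na(table$flock_size) & table$flock_size <= 0]
    if (length(badf))
      stop("nonpositive flock size for species: ", paste(badf, collapse = ", "))
  }

  log_mass <- log(table$mass_g)
  log_flock <- log(table$flock_size)
  sqrt_pred <- sqrt(table$n_predators)
  offsets <- c(log_mass = mean(log_mass), log_flock = mean(log_flock),
               sqrt_pred = mean(sqrt_pred))
  cols <- list(
    nocturnal   = as.numeric(table$activity),
    colonial    = as.numeric(table$colonial),
    log_mass_c  = log_mass - offsets["log_mass"],
    log_flock_c = log_flock - offsets["log_flock"],
    sqrt_pred_c = sqrt_pred - offsets["sqrt_pred"]
  )
  if ("activity" %in% drop) cols$nocturnal <- NULL
  if ("flock_size" %in% drop) cols$log_flock_c <- NULL
  if ("n_predators" %in% drop) cols$sqrt_pred_c <- NULL
  if ("colonial" %in% drop) cols$colonial <- NULL
  if ("mass" %in% drop) cols$log_mass_c <- NULL
  X <- cbind(`(Intercept)` = 1, do.call(cbind, cols))
  if (all(c("colonial", "log_mass_c") %in% colnames(X)))
    X <- cbind(X, `colonial:log_mass_c` = X[, "colonial"] * X[, "log_mass_c"])

  structure(list(
    y = table[[resp_col]],
    X = X,
    species_id = table$species_id,
    offsets = offsets,
    meta = list(response = response, log_base = "natural",
                baselines = c(activity = "diurnal", colonial = "non-colonial"),
                dropped = drop)
  ), class = "wing_design")
}

#' Variance inflation factors of the main-effect predictors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing predictor j on
#' the remaining main effects. The interaction column is excluded: an
#' interaction built from centred components inflates VIF mechanically
#' without indicating real collinearity. A perfectly collinear column is
#' reported as `Inf` with a warning.
#'
#' @param design a `wing_design`, or a numeric predictor matrix without
#'   intercept.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(design) {
  X <- if (inherits(design, "wing_design")) design$X else as.matrix(design)
  keep <- setdiff(colnames(X), c("(Intercept)", "colonial:log_mass_c"))
  X <- X[, keep, drop = FALSE]
  if (ncol(X) < 2L) stop("VIF needs at least 2 predictors")
  if (nrow(X) <= ncol(X)) stop("VIF needs more rows than predictors")
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r <- fit$residuals
    tot <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - sum(r^2) / tot
    if (r2 >= 1 - 1e-12) {
      warning("predictor ", colnames(X)[j], " is perfectly collinear")
      Inf
    } else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  out
}
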