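#' Great-circle distance matrix (haversine, km)
#'
#' @param latitude,longitude decimal degrees (`[-90, 90]`, `[-180, 180]`).
#' @param ids optional identifiers for the dimnames.
#' @return symmetric matrix of distances in km (Earth radius 6371 km).
#' @export
haversine_matrix <- function(latitude, longitude, ids = NULL) {
  if (length(latitude) != length(longitude))
    stop("latitude and longitude lengths differ")
  if (any(latitude < -90 | latitude > 90)) stop("latitude out of range")
  if (any(longitude < -180 | longitude > 180)) stop("longitude out of range")
  d <- geosphere::distm(cbind(longitude, latitude),
                        fun = function(a, b)
                          geosphere::distHaversine(a, b, r = 6371))
  dimnames(d) <- list(ids, ids)
  d
}

#' Environmental distance between samples
#'
#' Euclidean distance on z-score standardized covariates (heterogeneous
#' units make standardization necessary); zero-variance variables are
#' dropped with a warning.
#'
#' @param meta metadata `data.frame` with a `sample_id` column.
#' @param variables covariate column names; defaults to every numeric
#'   column that is not an identifier/coordinate.
#' @return symmetric distance matrix with sample ids as dimnames.
#' @export
env_distance <- function(meta, variables = env_variables(meta)) {
  if (length(variables) == 0) stop("no environmental variables")
  miss <- setdiff(variables, names(meta))
  if (length(miss)) stop("unknown variable(s): ", paste(miss, collapse = ", "))
  x <- as.matrix(meta[, variables, drop = FALSE])
  if (anyNA(x)) stop("missing values in the chosen variables")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance variable(s): ",
            paste(variables[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
    if (ncol(x) == 0) stop("no variable with positive variance")
  }
  z <- scale(x)
  d <- as.matrix(dist(z))
  dimnames(d) <- list(meta$sample_id, meta$sample_id)
  d
}

check_mantel_ids <- function(...) {
  mats <- list(...)
  ids <- dimnames(mats[[1]])[[1]]
  for (m in mats[-1]) {
    if (!is.null(ids) && !is.null(rownames(m)) &&
        !identical(rownames(m), ids))
      stop("distance matrices have mismatching ids")
    if (nrow(m) != nrow(mats[[1]]))
      stop("distance matrices have mismatching sizes")
  }
  invisible(TRUE)
}

mantel_result <- function(r, p, n_perm, controlled = NULL) {
  structure(list(r = unname(r), p_value = unname(p), n_perm = n_perm,
                 controlled = controlled), class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel%s: r = %.4f, p = %.4g (%d permutations)\n",
              if (is.null(x$controlled)) "" else
                paste0(" (controlling ", x$controlled, ")"),
              x$r, x$p_value, x$n_perm))
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper-triangle entries, with a one-sided
#' (greater) permutation p-value obtained by permuting the row/column
#' order of the first matrix (via [vegan::mantel()]);
#' `p >= 1 / (n_perm + 1)`.
#'
#' @param A,B symmetric distance matrices over the same samples.
#' @param n_perm number of permutations.
#' @param seed optional RNG seed.
#' @return a `mantel_result` list: `r`, `p_value`, `n_perm`.
#' @export
mantel_test <- function(A, B, n_perm = 999, seed = NULL) {
  A <- as.matrix(A); B <- as.matrix(B)
  check_mantel_ids(A, B)
  fit <- with_seed(seed, vegan::mantel(stats::as.dist(A), stats::as.dist(B),
                                       method = "pearson",
                                       permutations = n_perm))
  mantel_result(fit$statistic, fit$signif, n_perm)
}

#' Partial Mantel test controlling a third distance matrix
#'
#' Partial Pearson correlation of upper triangles `r(A, B | C)` with a
#' one-sided permutation p-value, `A` permuted and the partial statistic
#' recomputed each time (via [vegan::mantel.partial()]). The standard use
#' is community dissimilarity vs environmental distance controlling for
#' geographic distance ("distance-corrected dissimilarities").
#'
#' @param A,B,C symmetric distance matrices over the same samples; `C` is
#'   partialled out.
#' @inheritParams mantel_test
#' @param controlled label for the controlled matrix (reporting only).
#' @return a `mantel_result` list.
#' @export
partial_mantel_test <- function(A, B, C, n_perm = 999, seed = NULL,
                                controlled = "C") {
  A <- as.matrix(A); B <- as.matrix(B); C <- as.matrix(C)
  check_mantel_ids(A, B, C)
  if (sd(C[upper.tri(C)]) == 0) {
    # a constant control matrix shares no variance with A or B
    simple <- mantel_test(A, B, n_perm = n_perm, seed = seed)
    return(mantel_result(simple$r, simple$p_value, n_perm,
                         controlled = controlled))
  }
  fit <- with_seed(seed, vegan::mantel.partial(
    stats::as.dist(A), stats::as.dist(B), stats::as.dist(C),
    method = "pearson", permutations = n_perm))
  mantel_result(fit$statistic, fit$signif, n_perm, controlled = controlled)
}
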