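#' Alpha diversity indices per sample
#'
#' Computes observed richness, Chao1, ACE and the Shannon index (natural
#' log) from raw integer counts. Chao1 uses the bias-corrected form
#' `S + F1 (F1 - 1) / (2 (F2 + 1))` by default (`F1`, `F2` = singleton and
#' doubleton counts), which stays finite when doubletons are absent; the
#' classic `S + F1^2 / (2 F2)` form is available. ACE follows the standard
#' Chao-Lee estimator with a rare/abundant cutoff of 10.
#'
#' @param table an [otu_table()] of raw integer counts.
#' @param chao1_bias_corrected use the bias-corrected Chao1 form (default).
#' @param ace_rare_cutoff abundance cutoff separating rare from abundant
#'   taxa in ACE.
#' @return data.frame with columns `sample_id`, `observed`, `chao1`, `ace`,
#'   `shannon`.
#' @export
alpha_indices <- function(table, chao1_bias_corrected = TRUE,
                          ace_rare_cutoff = 10) {
  m <- otu_counts(table)
  if (any(colSums(m) == 0)) stop("zero-total sample")
  res <- lapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    x <- x[x > 0]
    s_obs <- length(x)
    f1 <- sum(x == 1)
    f2 <- sum(x == 2)
    chao1 <- if (chao1_bias_corrected) {
      s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
    } else if (f2 > 0) {
      s_obs + f1^2 / (2 * f2)
    } else {
      s_obs + f1 * (f1 - 1) / 2
    }
    rare <- x[x <= ace_rare_cutoff]
    s_abund <- sum(x > ace_rare_cutoff)
    s_rare <- length(rare)
    n_rare <- sum(rare)
    ace <- if (s_rare == 0) {
      s_obs
    } else {
      c_ace <- 1 - f1 / n_rare
      if (c_ace <= 0) {
        NA_real_   # all rare taxa are singletons; ACE undefined
      } else {
        fi <- tabulate(rare, nbins = ace_rare_cutoff)
        g2 <- max(s_rare / c_ace *
                    sum(seq_len(ace_rare_cutoff) *
                          (seq_len(ace_rare_cutoff) - 1) * fi) /
                    (n_rare * (n_rare - 1)) - 1, 0)
        s_abund + s_rare / c_ace + f1 / c_ace * g2
      }
    }
    p <- x / sum(x)
    data.frame(sample_id = colnames(m)[j], observed = s_obs,
               chao1 = chao1, ace = ace, shannon = -sum(p * log(p)))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(x, y) = sum |x - y| / sum (x + y)` over taxa, for every sample pair.
#'
#' @param table an [otu_table()].
#' @param use_relative compute on within-sample relative abundances
#'   (default) rather than raw counts.
#' @return symmetric matrix with zero diagonal, entries in `[0, 1]`.
#' @export
bray_curtis <- function(table, use_relative = TRUE) {
  m <- otu_counts(table)
  if (ncol(m) < 2) stop("need at least 2 samples")
  if (any(colSums(m) == 0)) stop("zero-total sample")
  x <- if (use_relative) to_relative_abundance(m) else m
  as.matrix(vegan::vegdist(t(x), method = "bray"))
}

perm_result <- function(statistic, p_value, n_perm) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 n_perm = n_perm), class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("permutation test: statistic = %.4f, p = %.4g (%d permutations)\n",
              x$statistic, x$p_value, x$n_perm))
  invisible(x)
}

check_perm_groups <- function(d, groups, n_perm) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  groups <- as.factor(groups)
  if (length(groups) != nrow(d)) stop("groups length must match samples")
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 members")
  droplevels(groups)
}

#' PERMANOVA on a distance matrix
#'
#' Anderson's pseudo-F from the among/within decomposition of a distance
#' matrix (via [vegan::adonis2()]) with a label-permutation p-value
#' `p = (1 + #permuted F >= observed F) / (1 + n_perm)`.
#'
#' @param d symmetric distance matrix with sample ids as dimnames.
#' @param groups group label per sample (>= 2 groups of >= 2 members).
#' @param n_perm number of permutations.
#' @param seed optional RNG seed for the permutation stream.
#' @return a `perm_test` list: `statistic` (pseudo-F), `p_value`, `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  d <- as.matrix(d)
  groups <- check_perm_groups(d, groups, n_perm)
  fit <- with_seed(seed, vegan::adonis2(stats::as.dist(d) ~ g,
                                        data = data.frame(g = groups),
                                        permutations = n_perm))
  perm_result(fit$F[1], fit$`Pr(>F)`[1], n_perm)
}

#' ANOSIM on a distance matrix
#'
#' `R = (mean between-group rank - mean within-group rank) / (n(n-1)/4)`
#' with a label-permutation p-value (via [vegan::anosim()]).
#'
#' @inheritParams permanova
#' @return a `perm_test` list: `statistic` (R in `[-1, 1]`), `p_value`,
#'   `n_perm`.
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = NULL) {
  d <- as.matrix(d)
  groups <- check_perm_groups(d, groups, n_perm)
  fit <- with_seed(seed, vegan::anosim(stats::as.dist(d), groups,
                                       permutations = n_perm))
  perm_result(fit$statistic, fit$signif, n_perm)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-squared (k - 1 df) p-value.
#'
#' @param values numeric response per sample.
#' @param groups group label per sample.
#' @return list with `statistic` (H) and `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  if (length(unique(values)) == 1)     # all tied: H = 0 by convention
    return(list(statistic = 0, p_value = 1))
  fit <- kruskal.test(values, droplevels(groups))
  list(statistic = unname(fit$statistic), p_value = fit$p.value)
}

#' Within-group beta-dispersion
#'
#' Returns, per group, either the multiset of within-group pairwise
#' distances (the "beta diversity index" compared across habitats) or the
#' distances to the group spatial median ([vegan::betadisper()]).
#'
#' @param d symmetric distance matrix.
#' @param groups group label per sample; every group needs >= 2 members.
#' @param type `"pairwise"` (default) or `"centroid"`.
#' @return named list of numeric vectors, one per group.
#' @export
beta_dispersion <- function(d, groups, type = c("pairwise", "centroid")) {
  type <- match.arg(type)
  d <- as.matrix(d)
  groups <- as.factor(groups)
  if (length(groups) != nrow(d)) stop("groups length must match samples")
  if (any(table(droplevels(groups)) < 2))
    stop("every group needs at least 2 members")
  if (type == "pairwise") {
    lapply(split(seq_along(groups), droplevels(groups)), function(idx) {
      sub <- d[idx, idx, drop = FALSE]
      sub[lower.tri(sub)]
    })
  } else {
    bd <- vegan::betadisper(stats::as.dist(d), droplevels(groups))
    split(unname(bd$distances), droplevels(groups))
  }
}
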