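#' @title Phylogenetic and taxonomic null models of community assembly
#' @description
#' The workhorses of the assembly analysis: beta mean nearest taxon
#' distance (betaMNTD), its null-model z-score (betaNTI), the Bray-Curtis
#' Raup-Crick metric (RC_bray), and the five-way classification of
#' assembly processes. betaNTI beyond +/-2 indicates deterministic
#' selection (negative: homogeneous, positive: heterogeneous); within
#' +/-2, RC_bray beyond +/-0.95 separates dispersal processes from drift.
#' @name assembly
NULL

#' Process labels of the five-way assembly classification
#' @return character vector of the five process names.
#' @export
assembly_process_levels <- function() {
  c("homogeneous_selection", "heterogeneous_selection",
    "homogenizing_dispersal", "dispersal_limitation", "drift")
}

# build the taxa x samples weight matrix used by betaMNTD
bmntd_weights <- function(m, weighted) {
  if (weighted) {
    to_relative_abundance(m)
  } else {
    pres <- m > 0
    sweep(pres, 2, colSums(pres), "/")
  }
}

check_phylo_dist <- function(m, phylo_dist) {
  ids <- rownames(phylo_dist)
  if (is.null(ids) || !identical(ids, colnames(phylo_dist)))
    stop("phylo_dist needs matching row/column ids")
  missing <- setdiff(rownames(m), ids)
  if (length(missing))
    stop(sprintf("%d taxa absent from phylo_dist (e.g. %s)", length(missing),
                 missing[1]))
  phylo_dist[rownames(m), rownames(m), drop = FALSE]
}

#' Beta mean nearest taxon distance for all sample pairs
#'
#' `betaMNTD(k, m) = 0.5 * (sum_i f_ik min_j d(i, j) + sum_j f_jm min_i
#' d(j, i))`, the minima taken over taxa present in the other community;
#' `f` is the within-sample relative abundance when `weighted` (default)
#' or `1 / richness` otherwise. Shared taxa contribute distance zero, so
#' identical communities score 0. Note that the unweighted form averages
#' the two per-community means (some implementations instead pool all
#' nearest-taxon distances into one mean, which differs when the two
#' richnesses differ); the weighted form is the usual convention and is
#' numerically identical to picante's abundance-weighted comdistnt.
#'
#' @param table an [otu_table()]; all taxa must appear in `phylo_dist`.
#' @param phylo_dist cophenetic distance matrix
#'   ([cophenetic_distances()]).
#' @param weighted abundance-weight the nearest-taxon distances.
#' @return symmetric samples x samples matrix.
#' @export
beta_mntd_matrix <- function(table, phylo_dist, weighted = TRUE) {
  m <- otu_counts(table)
  if (any(colSums(m) == 0)) stop("empty community")
  pd <- check_phylo_dist(m, phylo_dist)
  W <- bmntd_weights(m, weighted)
  out <- cpp_beta_mntd(pd, W)
  dimnames(out) <- list(colnames(m), colnames(m))
  out
}

#' Beta mean nearest taxon distance for one community pair
#'
#' @param x,y abundance vectors named by (or aligned with) the taxa of
#'   `phylo_dist`.
#' @inheritParams beta_mntd_matrix
#' @return a single non-negative number.
#' @export
beta_mntd <- function(x, y, phylo_dist, weighted = TRUE) {
  m <- pair_matrix(x, y, phylo_dist)
  beta_mntd_matrix(otu_table(m), phylo_dist, weighted)[1, 2]
}

pair_matrix <- function(x, y, phylo_dist) {
  ids <- rownames(phylo_dist)
  if (!is.null(names(x))) x <- x[ids]
  if (!is.null(names(y))) y <- y[ids]
  if (length(x) != length(ids) || length(y) != length(ids) ||
      anyNA(x) || anyNA(y))
    stop("x and y must cover the taxa of phylo_dist")
  if (sum(x) == 0 || sum(y) == 0) stop("empty community")
  matrix(c(x, y), ncol = 2, dimnames = list(ids, c("x", "y")))
}

#' betaNTI: null-model z-score of betaMNTD
#'
#' The null distribution comes from shuffling taxon labels on the
#' phylogenetic distance matrix (`n_null` joint row/column permutations,
#' shared across pairs within one randomization);
#' `betaNTI = (obs - mean_null) / sd_null` per sample pair. The shuffle
#' pool is every taxon of `table` found in `phylo_dist`, including taxa
#' with all-zero counts: the null asks where the observed communities
#' could sit on the whole available tree, so restricting the pool to
#' observed taxa would absorb any selection signal into the null itself.
#' Pairs whose null standard deviation is zero (e.g. on a star phylogeny)
#' are flagged degenerate and get `NA`.
#'
#' @inheritParams beta_mntd_matrix
#' @param n_null number of label permutations (999 by convention).
#' @param seed optional RNG seed; fixed seed reproduces the null exactly.
#' @return data.frame with one row per unordered sample pair: `sample_i`,
#'   `sample_j`, `beta_mntd_obs`, `null_mean`, `null_sd`, `bnti`,
#'   `degenerate`.
#' @export
bnti <- function(table, phylo_dist, n_null = 999, weighted = TRUE,
                 seed = NULL) {
  m <- otu_counts(table)
  if (any(colSums(m) == 0)) stop("empty community")
  pd <- check_phylo_dist(m, phylo_dist)
  W <- bmntd_weights(m, weighted)
  n <- nrow(m)
  perms <- with_seed(seed, {
    t(vapply(seq_len(n_null), function(i) sample.int(n) - 1L, integer(n)))
  })
  res <- cpp_bnti_null(pd, W, perms)
  idx <- which(upper.tri(res$obs), arr.ind = TRUE)
  null_sd <- res$null_sd[idx]
  degenerate <- null_sd <= 1e-12
  out <- data.frame(
    sample_i = colnames(m)[idx[, 1]], sample_j = colnames(m)[idx[, 2]],
    beta_mntd_obs = res$obs[idx], null_mean = res$null_mean[idx],
    null_sd = null_sd,
    bnti = ifelse(degenerate, NA_real_,
                  (res$obs[idx] - res$null_mean[idx]) / null_sd),
    degenerate = degenerate)
  if (any(degenerate))
    warning(sprintf("%d pair(s) have a degenerate (zero-variance) null",
                    sum(degenerate)))
  out
}

#' betaNTI for one community pair
#'
#' @inheritParams beta_mntd
#' @inheritParams bnti
#' @return one-row data.frame as in [bnti()].
#' @export
bnti_pair <- function(x, y, phylo_dist, n_null = 999, weighted = TRUE,
                      seed = NULL) {
  m <- pair_matrix(x, y, phylo_dist)
  keep <- rowSums(m) > 0
  bnti(otu_table(m[keep, , drop = FALSE]),
       phylo_dist[keep, keep, drop = FALSE],
       n_null = n_null, weighted = weighted, seed = seed)
}

# one probabilistic reassembly of a community: keep richness and total,
# draw taxa by occurrence frequency, then fill individuals by mean
# relative abundance among the drawn taxa (each drawn taxon starts with
# one individual).
assemble_null <- function(richness, total, occ, relab) {
  n_pool <- length(occ)
  idx <- sample.int(n_pool, richness, prob = occ)
  cnt <- integer(n_pool)
  cnt[idx] <- 1L
  if (total > richness)
    cnt[idx] <- cnt[idx] + as.integer(rmultinom(1, total - richness,
                                                relab[idx]))
  cnt
}

bray_pairs <- function(m) {
  # Bray-Curtis on count columns, returned as upper-triangle matrix index
  as.matrix(vegan::vegdist(t(m), method = "bray"))
}

#' Bray-Curtis Raup-Crick metric (RC_bray) for all sample pairs
#'
#' Each of `n_null` replicates probabilistically reassembles every sample,
#' preserving its observed richness and total count: taxa are drawn with
#' probability proportional to their occurrence frequency across the
#' metacommunity table, then individuals are allotted with probability
#' proportional to metacommunity mean relative abundance among the drawn
#' taxa. `RC = 2 ((#null < obs) + 0.5 (#null = obs)) / n_null - 1`, where
#' null and observed Bray-Curtis are compared with tolerance `1e-10`.
#' RC_bray near -1 means communities are far more similar than chance;
#' near +1 far more different.
#'
#' @param table an [otu_table()] whose columns are the communities to
#'   compare.
#' @param metacommunity OTU table defining the species pool (defaults to
#'   `table` itself).
#' @param n_null number of reassembly replicates.
#' @param seed optional RNG seed.
#' @return data.frame with one row per unordered pair: `sample_i`,
#'   `sample_j`, `bc_obs`, `rc`.
#' @export
rc_bray <- function(table, metacommunity = table, n_null = 999,
                    seed = NULL) {
  m <- otu_counts(table)
  meta <- otu_counts(metacommunity)
  if (!identical(rownames(m), rownames(meta)))
    stop("table and metacommunity must share the same taxa")
  pool <- rowSums(meta) > 0
  if (any(m[!pool, , drop = FALSE] > 0))
    stop("sample richness exceeds metacommunity richness: ",
         "counts on taxa absent from the pool")
  m <- m[pool, , drop = FALSE]
  meta <- meta[pool, , drop = FALSE]
  occ <- rowMeans(meta > 0)
  relab <- rowMeans(to_relative_abundance(meta))
  richness <- colSums(m > 0)
  totals <- colSums(m)
  if (any(richness > sum(pool)))
    stop("sample richness exceeds metacommunity richness")
  if (any(richness == 0)) stop("empty community")
  S <- ncol(m)
  obs <- bray_pairs(m)
  below <- matrix(0, S, S)
  equal <- matrix(0, S, S)
  with_seed(seed, {
    for (r in seq_len(n_null)) {
      null_m <- vapply(seq_len(S),
                       function(s) assemble_null(richness[s], totals[s],
                                                 occ, relab),
                       integer(nrow(m)))
      bc_null <- bray_pairs(null_m)
      below <- below + (bc_null < obs - 1e-10)
      equal <- equal + (abs(bc_null - obs) <= 1e-10)
    }
  })
  rc <- 2 * ((below + 0.5 * equal) / n_null) - 1
  idx <- which(upper.tri(obs), arr.ind = TRUE)
  data.frame(sample_i = colnames(m)[idx[, 1]],
             sample_j = colnames(m)[idx[, 2]],
             bc_obs = obs[idx], rc = rc[idx])
}

#' RC_bray for one community pair
#'
#' @param x,y count vectors named by (or aligned with) the metacommunity
#'   taxa.
#' @inheritParams rc_bray
#' @return one-row data.frame as in [rc_bray()].
#' @export
rc_bray_pair <- function(x, y, metacommunity, n_null = 999, seed = NULL) {
  meta <- otu_counts(metacommunity)
  ids <- rownames(meta)
  if (!is.null(names(x))) x <- x[ids]
  if (!is.null(names(y))) y <- y[ids]
  m <- matrix(as.integer(c(x, y)), ncol = 2,
              dimnames = list(ids, c("x", "y")))
  rc_bray(otu_table(m), metacommunity, n_null = n_null, seed = seed)
}

#' Classify a sample pair into one of five assembly processes
#'
#' `betaNTI < -2`: homogeneous selection; `betaNTI > 2`: heterogeneous
#' selection; otherwise `RC < -0.95`: homogenizing dispersal, `RC > 0.95`:
#' dispersal limitation, else drift. Boundary values (|betaNTI| = 2,
#' |RC| = 0.95 exactly) fall on the stochastic/drift side.
#'
#' @param bnti,rc numeric vectors (recycled to common length).
#' @param bnti_threshold,rc_threshold classification thresholds.
#' @return character vector of process names.
#' @export
classify_pair <- function(bnti, rc, bnti_threshold = 2,
                          rc_threshold = 0.95) {
  n <- max(length(bnti), length(rc))
  bnti <- rep_len(bnti, n)
  rc <- rep_len(rc, n)
  if (any(!is.finite(bnti)) || any(!is.finite(rc)))
    stop("bnti and rc must be finite")
  ifelse(bnti < -bnti_threshold, "homogeneous_selection",
  ifelse(bnti > bnti_threshold, "heterogeneous_selection",
  ifelse(rc < -rc_threshold, "homogenizing_dispersal",
  ifelse(rc > rc_threshold, "dispersal_limitation", "drift"))))
}

#' Fractions of assembly processes among classified pairs
#'
#' @param processes character vector of process names (one per classified
#'   pair); `NA` entries (degenerate pairs) are dropped.
#' @return named numeric vector over the five processes, summing to 1.
#' @export
partition_processes <- function(processes) {
  processes <- processes[!is.na(processes)]
  if (length(processes) == 0) stop("no classifiable pairs")
  bad <- setdiff(unique(processes), assembly_process_levels())
  if (length(bad)) stop("unknown process label(s): ",
                        paste(bad, collapse = ", "))
  tab <- table(factor(processes, levels = assembly_process_levels()))
  setNames(as.numeric(tab) / length(processes), names(tab))
}

#' Per-group null-model partitioning of assembly processes
#'
#' Runs betaNTI and RC_bray on all within-group sample pairs of each
#' group, classifies every pair, and tallies the five process fractions.
#' The species pool for each group's null models is the set of taxa
#' occurring in that group (consistent with within-group pairing);
#' cross-group pairing over the full pool is available via
#' `pairs = "all"`.
#'
#' @param table an [otu_table()].
#' @param tree rooted `phylo` covering the table's taxa (extra tips are
#'   pruned, missing taxa dropped, with messages).
#' @param groups group label per sample.
#' @param n_null null-model randomizations for both betaNTI and RC_bray.
#' @param weighted abundance-weighted betaMNTD (default).
#' @param pairs `"within"` (default) or `"all"` (one pool, all pairs).
#' @param bnti_threshold,rc_threshold classification thresholds passed to
#'   [classify_pair()].
#' @param seed optional RNG seed.
#' @return list with `pairs` (per-pair data.frame incl. `group`,
#'   `bnti`, `rc`, `process`) and `partition` (data.frame of per-group
#'   process fractions).
#' @export
assembly_processes <- function(table, tree, groups, n_null = 999,
                               weighted = TRUE, pairs = c("within", "all"),
                               bnti_threshold = 2, rc_threshold = 0.95,
                               seed = NULL) {
  pairs <- match.arg(pairs)
  aligned <- align_community(table, tree = tree)
  m <- otu_counts(aligned$table)
  groups <- setNames(as.character(groups), colnames(table))[colnames(m)]
  pd_full <- cophenetic_distances(aligned$tree)
  group_sets <- if (pairs == "within") split(colnames(m), groups)
                else list(all = colnames(m))
  run_one <- function(samples) {
    # betaNTI: full taxon universe as shuffle pool; RC_bray: the group's
    # own occurrence frequencies define the reassembly pool.
    tab <- otu_table(m[, samples, drop = FALSE])
    b <- bnti(tab, pd_full, n_null = n_null, weighted = weighted)
    r <- rc_bray(tab, n_null = n_null)
    stopifnot(identical(b$sample_i, r$sample_i))
    b$rc <- r$rc
    b$bc_obs <- r$bc_obs
    b$process <- NA_character_
    ok <- !b$degenerate
    b$process[ok] <- classify_pair(b$bnti[ok], b$rc[ok],
                                   bnti_threshold = bnti_threshold,
                                   rc_threshold = rc_threshold)
    b
  }
  res <- with_seed(seed, lapply(group_sets, run_one))
  pair_df <- do.call(rbind, Map(function(g, df) cbind(group = g, df),
                                names(res), res))
  rownames(pair_df) <- NULL
  part <- do.call(rbind, lapply(res, function(df)
    partition_processes(df$process)))
  partition <- data.frame(group = rownames(part), part,
                          row.names = NULL, check.names = FALSE)
  list(pairs = pair_df, partition = partition)
}
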