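#' Levins niche breadth per taxon
#'
#' `B_j = 1 / sum_i P_ij^2` where `P_ij` is the proportion of taxon j's
#' total abundance found in sample i. `B` ranges from 1 (taxon confined to
#' one sample) to the number of samples (taxon spread evenly), and is
#' invariant to rescaling a taxon's abundances by a positive constant.
#' All-zero taxa are excluded with a warning.
#'
#' @param table an [otu_table()] or count matrix (taxa x samples).
#' @return named numeric vector of niche breadths, one per non-empty taxon.
#' @export
levins_breadth <- function(table) {
  m <- otu_counts(table)
  totals <- rowSums(m)
  if (any(totals == 0)) {
    warning(sprintf("excluding %d all-zero taxa from niche breadth",
                    sum(totals == 0)))
    m <- m[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  P <- m / totals
  setNames(1 / rowSums(P^2), rownames(m))
}

#' Community-level niche breadth per sample
#'
#' The community-level value for a sample is the mean Levins breadth of the
#' taxa present (count > 0) in it; habitat generalist-rich communities
#' score high. An abundance-weighted mean is available.
#'
#' @param table an [otu_table()].
#' @param B per-taxon breadths; computed with [levins_breadth()] if omitted.
#' @param weighted weight the mean by within-sample relative abundance.
#' @return named numeric vector, one value per sample.
#' @export
community_breadth <- function(table, B = NULL, weighted = FALSE) {
  m <- otu_counts(table)
  if (any(colSums(m) == 0)) stop("empty sample")
  if (is.null(B)) B <- levins_breadth(m)
  m <- m[names(B), , drop = FALSE]
  vapply(seq_len(ncol(m)), function(j) {
    present <- m[, j] > 0
    if (!any(present)) stop(sprintf("sample '%s' has no taxa with breadth",
                                    colnames(m)[j]))
    if (weighted) {
      w <- m[present, j] / sum(m[present, j])
      sum(w * B[present])
    } else {
      mean(B[present])
    }
  }, numeric(1)) |> setNames(colnames(m))
}
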