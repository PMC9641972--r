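#' Construct an OTU count table
#'
#' An OTU table is a taxa x samples matrix of non-negative integer counts
#' with unique taxon and sample identifiers. Taxa that are absent from every
#' sample are permitted (they are reported via a message) but every sample
#' must contain at least one count.
#'
#' @param counts numeric matrix of non-negative integers, taxa in rows.
#' @param taxa_ids,sample_ids character identifiers; defaults to the
#'   dimnames of `counts`.
#' @return an integer matrix of class `otu_table` with taxa as rows.
#' @export
otu_table <- function(counts, taxa_ids = rownames(counts),
                      sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(taxa_ids) || is.null(sample_ids))
    stop("taxa and sample identifiers are required")
  taxa_ids <- as.character(taxa_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(taxa_ids)) stop("duplicate taxon identifiers")
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers")
  if (length(taxa_ids) != nrow(counts) || length(sample_ids) != ncol(counts))
    stop("identifier lengths do not match the count matrix")
  if (any(!is.finite(counts))) stop("counts must be finite numbers")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at taxon '%s', sample '%s'",
                 taxa_ids[bad[1]], sample_ids[bad[2]]))
  }
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(taxa_ids, sample_ids)
  totals <- colSums(counts)
  if (any(totals == 0))
    stop(sprintf("sample(s) with zero total count: %s",
                 paste(sample_ids[totals == 0], collapse = ", ")))
  zero <- rowSums(counts) == 0
  if (any(zero))
    log_msg("otu_table: %d taxa have all-zero counts", sum(zero))
  structure(counts, class = c("otu_table", "matrix", "array"))
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d taxa x %d samples, %s total counts\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

# strip class for matrix maths
otu_counts <- function(x) {
  m <- unclass(x)
  attr(m, "class") <- NULL
  m
}

#' Read an OTU table from a tab-separated file
#'
#' The expected layout has an identifier column (`#OTU_ID` for taxa-in-rows
#' files) followed by one column per sample (or per taxon when
#' `orientation = "samples_rows"`).
#'
#' @param path file path.
#' @param orientation `"taxa_rows"` (default) or `"samples_rows"`.
#' @return an [otu_table()], always oriented taxa x samples.
#' @export
read_otu_table <- function(path, orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   comment.char = "")
  if (ncol(df) < 2) stop("OTU table needs an id column plus data columns")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                 dimnames = dimnames(m)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric count at row '%s', column '%s'",
                 ids[bad[1]], colnames(m)[bad[2]]))
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at row '%s', column '%s'",
                 ids[bad[1]], colnames(m)[bad[2]]))
  }
  rownames(num) <- ids
  if (orientation == "samples_rows") num <- t(num)
  otu_table(num)
}

#' Write an OTU table as tab-separated text
#'
#' @param x an [otu_table()].
#' @param path output file path.
#' @export
write_otu_table <- function(x, path) {
  df <- data.frame(`#OTU_ID` = rownames(x), otu_counts(x),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny in newick format
#'
#' @param path file path to a newick file with branch lengths.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("newick parse error: could not read a tree")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  tree
}

#' Write a phylogeny in newick format
#' @param tree a `phylo` object.
#' @param path output file path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Cophenetic (tip-to-tip) phylogenetic distances
#'
#' Each entry is the sum of branch lengths along the path between two tips.
#'
#' @param tree a `phylo` object with at least two tips.
#' @return symmetric numeric matrix with zero diagonal, ordered as
#'   `tree$tip.label`.
#' @export
cophenetic_distances <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (length(tree$tip.label) < 2) stop("tree must have at least 2 tips")
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Read sample metadata
#'
#' CSV with required columns `sample_id`, `group`, `latitude`, `longitude`;
#' any additional numeric columns are treated as environmental covariates.
#'
#' @param path CSV file path.
#' @param groups allowed group labels; defaults to the five habitat groups.
#' @return a `data.frame` with one row per sample.
#' @export
read_sample_metadata <- function(path, groups = study_groups()) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_metadata(df, groups)
}

#' Write sample metadata as CSV
#' @param meta metadata `data.frame`.
#' @param path output file path.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The five habitat group labels of the study layout
#' @return character vector of group labels.
#' @export
study_groups <- function() c("Sur_FL", "Sur_PA", "Bot_FL", "Bot_PA", "Sed")

validate_metadata <- function(df, groups = study_groups()) {
  req <- c("sample_id", "group", "latitude", "longitude")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  if (!all(df$group %in% groups))
    stop("unknown group label(s): ",
         paste(setdiff(unique(df$group), groups), collapse = ", "))
  if (any(df$latitude < -90 | df$latitude > 90, na.rm = TRUE) ||
      any(df$longitude < -180 | df$longitude > 180, na.rm = TRUE))
    stop("coordinates out of range")
  df
}

# names of metadata columns holding environmental covariates
env_variables <- function(meta) {
  cand <- setdiff(names(meta), c("sample_id", "group", "latitude", "longitude",
                                 "site"))
  cand[vapply(meta[cand], is.numeric, logical(1))]
}

#' Align an OTU table with a phylogeny and sample metadata
#'
#' Restricts all inputs to the shared taxon universe (table taxa that are
#' tree tips) and shared sample universe (table samples present in the
#' metadata). Dropped taxa and samples are reported via messages.
#'
#' @param table an [otu_table()].
#' @param tree optional `phylo`; taxa absent from the tree are dropped.
#' @param meta optional metadata `data.frame`; samples absent from it are
#'   dropped.
#' @return list with elements `table`, `tree`, `meta`.
#' @export
align_community <- function(table, tree = NULL, meta = NULL) {
  taxa <- rownames(table)
  samples <- colnames(table)
  if (!is.null(tree)) {
    keep_taxa <- intersect(taxa, tree$tip.label)
    if (length(keep_taxa) == 0) stop("no taxa shared between table and tree")
    if (length(keep_taxa) < length(taxa))
      log_msg("align_community: dropped %d taxa absent from the tree (%s%s)",
              length(taxa) - length(keep_taxa),
              paste(head(setdiff(taxa, keep_taxa), 5), collapse = ", "),
              if (length(setdiff(taxa, keep_taxa)) > 5) ", ..." else "")
    drop_tips <- setdiff(tree$tip.label, keep_taxa)
    if (length(drop_tips)) {
      log_msg("align_community: pruned %d tree tips absent from the table",
              length(drop_tips))
      tree <- ape::drop.tip(tree, drop_tips)
    }
    taxa <- keep_taxa
  }
  if (!is.null(meta)) {
    keep_samples <- intersect(samples, meta$sample_id)
    if (length(keep_samples) == 0)
      stop("no samples shared between table and metadata")
    if (length(keep_samples) < length(samples))
      log_msg("align_community: dropped %d samples absent from metadata",
              length(samples) - length(keep_samples))
    meta <- meta[match(keep_samples, meta$sample_id), , drop = FALSE]
    rownames(meta) <- NULL
    samples <- keep_samples
  }
  tab <- otu_counts(table)[taxa, samples, drop = FALSE]
  list(table = otu_table(tab), tree = tree, meta = meta)
}

#' Convert counts to within-sample relative abundances
#'
#' @param table an [otu_table()] or count matrix (taxa x samples).
#' @return numeric matrix whose columns each sum to 1.
#' @export
to_relative_abundance <- function(table) {
  m <- otu_counts(table)
  totals <- colSums(m)
  if (any(totals == 0))
    stop(sprintf("sample(s) with zero total count: %s",
                 paste(colnames(m)[totals == 0], collapse = ", ")))
  sweep(m, 2, totals, "/")
}

#' Rarefy an OTU table to even depth
#'
#' Thin wrapper around [vegan::rrarefy()]. Rarefaction is off by default in
#' every analysis; use this explicitly when even depth is wanted.
#'
#' @param table an [otu_table()].
#' @param depth target depth; defaults to the minimum sample total.
#' @param seed optional RNG seed.
#' @return an [otu_table()] with every sample total equal to `depth`.
#' @export
rarefy_table <- function(table, depth = min(colSums(table)), seed = NULL) {
  m <- otu_counts(table)
  if (depth > min(colSums(m))) stop("depth exceeds the shallowest sample")
  # rrarefy heuristically warns when the smallest nonzero count exceeds 1;
  # counts are validated upstream, so silence it
  out <- with_seed(seed, t(suppressWarnings(vegan::rrarefy(t(m), depth))))
  otu_table(out)
}
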