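#' Keep the k most abundant taxa
#'
#' Ranks taxa by summed relative abundance across all samples (ties broken
#' by lexicographically smaller identifier) and keeps the top `k`.
#'
#' @param table an [otu_table()].
#' @param k number of taxa to keep (>= 2); if `k` exceeds the available
#'   taxa, all are kept with a warning.
#' @return an [otu_table()] restricted to the selected taxa.
#' @export
select_top_taxa <- function(table, k = 500) {
  if (k < 2) stop("k must be at least 2")
  m <- otu_counts(table)
  if (k > nrow(m)) {
    warning(sprintf("k = %d exceeds the %d available taxa; keeping all",
                    k, nrow(m)))
    k <- nrow(m)
  }
  score <- rowSums(to_relative_abundance(m))
  ord <- order(-score, rownames(m))
  otu_table(m[sort(ord[seq_len(k)]), , drop = FALSE])
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH adjustment with monotonicity enforcement (via
#' [stats::p.adjust()]).
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in `[0, 1]`.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Build a Spearman co-occurrence network
#'
#' Computes Spearman rank correlations (midranks for ties) between all
#' unordered taxon pairs across samples, two-sided p-values from the
#' t-approximation with `n - 2` degrees of freedom, and a single
#' Benjamini-Hochberg adjustment over all tested pairs. Pairs with
#' `|r| > r_threshold` and adjusted `p < q_threshold` become edges of an
#' undirected simple graph; taxa with constant abundance are skipped with
#' a warning (their correlation is undefined), and taxa left without any
#' edge do not appear as nodes.
#'
#' @param table an [otu_table()] (typically after [select_top_taxa()]);
#'   needs at least 4 samples.
#' @param r_threshold minimum absolute correlation (default 0.7).
#' @param q_threshold maximum FDR-adjusted p-value (default 0.01).
#' @param use_relative correlate relative abundances (default) rather than
#'   raw counts.
#' @return an [igraph::graph] with edge attributes `r`, `q`, `sign`
#'   (`"positive"`/`"negative"`) and `weight = |r|`, plus graph attributes
#'   `r_threshold`, `q_threshold`, `n_tested`.
#' @export
spearman_edges <- function(table, r_threshold = 0.7, q_threshold = 0.01,
                           use_relative = TRUE) {
  m <- otu_counts(table)
  if (ncol(m) < 4) stop("need at least 4 samples for rank correlation")
  x <- if (use_relative) to_relative_abundance(m) else m
  constant <- apply(x, 1, function(v) max(v) == min(v))
  if (any(constant)) {
    warning(sprintf("skipping %d constant taxa (undefined correlation)",
                    sum(constant)))
    x <- x[!constant, , drop = FALSE]
  }
  if (nrow(x) < 2) stop("fewer than 2 variable taxa")
  n <- ncol(x)
  ranks <- t(apply(x, 1, rank))        # midranks for ties
  R <- cor(t(ranks))                   # Pearson of ranks = Spearman
  idx <- which(upper.tri(R), arr.ind = TRUE)
  r <- R[idx]
  r_cl <- pmin(pmax(r, -1), 1)
  tstat <- r_cl * sqrt((n - 2) / pmax(1 - r_cl^2, .Machine$double.eps))
  pval <- 2 * pt(-abs(tstat), df = n - 2)
  pval[abs(r_cl) >= 1 - 1e-12] <- 0
  q <- bh_fdr(pval)
  keep <- abs(r) > r_threshold & q < q_threshold
  edges <- data.frame(from = rownames(x)[idx[keep, 1]],
                      to = rownames(x)[idx[keep, 2]],
                      r = r[keep], q = q[keep],
                      sign = ifelse(r[keep] > 0, "positive", "negative"),
                      weight = abs(r[keep]))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  g <- igraph::set_graph_attr(g, "r_threshold", r_threshold)
  g <- igraph::set_graph_attr(g, "q_threshold", q_threshold)
  igraph::set_graph_attr(g, "n_tested", length(pval))
}

#' Network-level topology summary
#'
#' Average degree `2E/N`, graph density, clustering coefficient (mean
#' local transitivity over nodes of degree >= 2), average path length and
#' diameter on the largest connected component, modularity of the
#' greedy-modularity partition, Freeman degree and betweenness
#' centralization, node/edge counts and the fraction of positive edges.
#' An empty graph yields `NA` metrics.
#'
#' @param net an igraph network from [spearman_edges()].
#' @param seed seed forwarded to [detect_modules()].
#' @return named list of metrics.
#' @export
network_topology <- function(net, seed = NULL) {
  nv <- igraph::vcount(net)
  ne <- igraph::ecount(net)
  if (nv == 0)
    return(list(n_nodes = 0, n_edges = 0, average_degree = NA_real_,
                clustering_coefficient = NA_real_,
                average_path_length = NA_real_, modularity = NA_real_,
                graph_density = NA_real_, network_diameter = NA_real_,
                betweenness_centralization = NA_real_,
                degree_centralization = NA_real_,
                positive_edge_fraction = NA_real_))
  deg <- igraph::degree(net)
  loc <- igraph::transitivity(net, type = "local", isolates = "NaN")
  cc <- if (any(deg >= 2)) mean(loc[deg >= 2], na.rm = TRUE) else NA_real_
  comp <- igraph::components(net)
  giant <- igraph::induced_subgraph(
    net, which(comp$membership == which.max(comp$csize)))
  apl <- if (igraph::vcount(giant) > 1)
    igraph::mean_distance(giant, weights = NA) else NA_real_
  diam <- if (igraph::vcount(giant) > 1)
    igraph::diameter(giant, weights = NA) else NA_real_
  mods <- if (ne > 0) detect_modules(net, seed = seed)$modularity else 0
  signs <- igraph::edge_attr(net, "sign")
  pos <- if (ne > 0 && !is.null(signs)) mean(signs == "positive")
         else NA_real_
  list(n_nodes = nv, n_edges = ne,
       average_degree = 2 * ne / nv,
       clustering_coefficient = cc,
       average_path_length = apl,
       modularity = mods,
       graph_density = igraph::edge_density(net),
       network_diameter = diam,
       betweenness_centralization =
         igraph::centr_betw(net, directed = FALSE)$centralization,
       degree_centralization =
         igraph::centr_degree(net, mode = "all", loops = FALSE)$centralization,
       positive_edge_fraction = pos)
}

#' Detect modules by greedy modularity maximization
#'
#' Multi-level (Louvain) greedy modularity optimization on the unsigned
#' graph; modules are labelled `1..k` by decreasing size. An edgeless
#' graph yields one singleton module per node and `Q = 0`.
#'
#' @param net an igraph network.
#' @param seed RNG seed; a fixed internal default keeps the partition
#'   reproducible when no seed is given.
#' @return list with `membership` (named integer vector) and `modularity`.
#' @export
detect_modules <- function(net, seed = NULL) {
  if (igraph::ecount(net) == 0) {
    memb <- setNames(seq_len(igraph::vcount(net)),
                     igraph::V(net)$name)
    return(list(membership = memb, modularity = 0))
  }
  if (is.null(seed)) seed <- 0
  cl <- with_seed(seed, igraph::cluster_louvain(
    net, weights = rep(1, igraph::ecount(net))))
  memb <- igraph::membership(cl)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  memb <- setNames(as.integer(relabel[as.character(memb)]),
                   igraph::V(net)$name)
  list(membership = memb,
       modularity = igraph::modularity(net, memb))
}

#' Node-level topology
#'
#' Degree, local transitivity (`NA` below degree 2), normalized
#' betweenness, and closeness centrality computed within each node's
#' connected component (isolated nodes get closeness 0 by convention).
#'
#' @param net an igraph network with >= 2 nodes.
#' @return data.frame with columns `node`, `degree`, `transitivity`,
#'   `betweenness`, `closeness`.
#' @export
node_topology <- function(net) {
  nv <- igraph::vcount(net)
  if (nv < 2) stop("need at least 2 nodes")
  deg <- igraph::degree(net)
  trans <- igraph::transitivity(net, type = "local", isolates = "NaN")
  trans[deg < 2] <- NA_real_
  btw <- igraph::betweenness(net, directed = FALSE, normalized = TRUE,
                             weights = NA)
  comp <- igraph::components(net)
  clo <- numeric(nv)
  for (cid in seq_len(comp$no)) {
    members <- which(comp$membership == cid)
    if (length(members) == 1) {
      clo[members] <- 0
    } else {
      sub <- igraph::induced_subgraph(net, members)
      clo[members] <- igraph::closeness(sub, normalized = TRUE, weights = NA)
    }
  }
  data.frame(node = igraph::V(net)$name, degree = unname(deg),
             transitivity = unname(trans), betweenness = unname(btw),
             closeness = clo, row.names = NULL)
}

#' Extract a habitat subnetwork from the meta-community network
#'
#' Induces the subgraph on nodes whose total abundance over the group's
#' samples is positive; edges are inherited, correlations are not
#' recomputed.
#'
#' @param net the meta-community network from [spearman_edges()].
#' @param table the [otu_table()] used to build `net`.
#' @param group_samples sample ids belonging to the group (>= 1).
#' @return an igraph subnetwork (possibly empty, with a warning).
#' @export
extract_subnetwork <- function(net, table, group_samples) {
  if (length(group_samples) < 1) stop("group needs at least 1 sample")
  m <- otu_counts(table)
  missing <- setdiff(group_samples, colnames(m))
  if (length(missing)) stop("unknown sample(s): ",
                            paste(missing, collapse = ", "))
  present <- rownames(m)[rowSums(m[, group_samples, drop = FALSE]) > 0]
  keep <- intersect(igraph::V(net)$name, present)
  if (length(keep) == 0)
    warning("no group taxa present in the network; returning empty graph")
  igraph::induced_subgraph(net, keep)
}
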