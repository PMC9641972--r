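# small fixtures and independent brute-force oracles

tree4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

star_tree <- function(n = 4) {
  ape::read.tree(text = paste0(
    "(", paste(sprintf("%s:1", LETTERS[seq_len(n)]), collapse = ","), ");"))
}

toy_table <- function(counts, taxa = NULL, samples = NULL) {
  m <- as.matrix(counts)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(m)))
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(m)))
  otu_table(m, taxa_ids = taxa, sample_ids = samples)
}

# independent cophenetic oracle: shortest paths on the weighted edge graph
brute_cophenetic <- function(tree) {
  n_tip <- length(tree$tip.label)
  g <- igraph::graph_from_data_frame(
    data.frame(from = tree$edge[, 1], to = tree$edge[, 2],
               weight = tree$edge.length),
    directed = FALSE)
  ids <- as.integer(igraph::V(g)$name)
  d <- igraph::distances(g)
  tip_idx <- match(seq_len(n_tip), ids)
  out <- d[tip_idx, tip_idx]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

# literal double-loop betaMNTD oracle
brute_beta_mntd <- function(x, y, pd, weighted = TRUE) {
  ids <- rownames(pd)
  x <- x[ids]; y <- y[ids]
  px <- which(x > 0); py <- which(y > 0)
  fx <- if (weighted) x[px] / sum(x) else rep(1 / length(px), length(px))
  fy <- if (weighted) y[py] / sum(y) else rep(1 / length(py), length(py))
  s1 <- sum(vapply(seq_along(px), function(i)
    fx[i] * min(pd[px[i], py]), numeric(1)))
  s2 <- sum(vapply(seq_along(py), function(j)
    fy[j] * min(pd[py[j], px]), numeric(1)))
  0.5 * (s1 + s2)
}

# exhaustive-permutation betaNTI oracle for small pools
brute_bnti_exhaustive <- function(x, y, pd, weighted = TRUE) {
  n <- nrow(pd)
  perms <- all_permutations(n)
  obs <- brute_beta_mntd(x, y, pd, weighted)
  nulls <- apply(perms, 1, function(p) {
    pdp <- pd[p, p]
    dimnames(pdp) <- dimnames(pd)
    brute_beta_mntd(x, y, pdp, weighted)
  })
  (obs - mean(nulls)) / sd(nulls)
}

# all permutations of 1..n without extra packages
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# step-up BH oracle by definition
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
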