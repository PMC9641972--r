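test_that("top-taxa selection ranks by summed relative abundance", {
  m <- matrix(c(5, 9, 1, 0, 0, 0), 3, 2,
              dimnames = list(c("x", "y", "z"), c("s1", "s2")))
  m[, 2] <- c(0, 1, 0)
  tab <- suppressMessages(otu_table(m))
  expect_setequal(rownames(select_top_taxa(tab, k = 2)), c("x", "y"))
  expect_identical(unclass(select_top_taxa(tab, k = 3)), unclass(tab))
  expect_warning(select_top_taxa(tab, k = 10), "keeping all")
  expect_error(select_top_taxa(tab, k = 1), "at least 2")

  # tie at the cutoff: lexicographically smaller id kept
  m2 <- matrix(c(4, 2, 2), 3, 1, dimnames = list(c("c", "b", "a"), "s1"))
  expect_setequal(rownames(select_top_taxa(otu_table(m2), k = 2)),
                  c("c", "a"))
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  for (s in 1:5) {
    set.seed(s)
    p <- runif(10)
    adj <- bh_fdr(p)
    expect_equal(adj, brute_bh(p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Spearman edges capture monotone pairs and skip constant taxa", {
  m <- rbind(up = c(1, 2, 3, 4, 5, 6),
             up2 = c(2, 4, 9, 16, 25, 36),
             down = c(60, 50, 40, 30, 20, 10),
             flat = c(5, 5, 5, 5, 5, 5),
             noise = c(3, 1, 4, 1, 5, 9))
  colnames(m) <- paste0("s", 1:6)
  tab <- otu_table(m)
  expect_warning(net <- spearman_edges(tab, r_threshold = 0.7,
                                       q_threshold = 0.05,
                                       use_relative = FALSE),
                 "constant")
  ed <- igraph::as_data_frame(net)
  key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
  expect_true("up up2" %in% key)
  expect_equal(ed$r[key == "up up2"], 1)
  expect_true(all(ed$r[ed$sign == "negative"] < 0))
  expect_false("flat" %in% igraph::V(net)$name)
  expect_true(all(abs(ed$r) > 0.7 & ed$q < 0.05))
  expect_error(spearman_edges(toy_table(matrix(1:6, 2, 3))), "4 samples")
})

test_that("Spearman midranks match the Pearson-of-ranks oracle under ties", {
  x <- c(1, 2, 2, 3, 3, 3)
  y <- c(2, 1, 4, 4, 6, 5)
  m <- rbind(a = x, b = y)
  colnames(m) <- paste0("s", 1:6)
  net <- spearman_edges(otu_table(m), r_threshold = 0.1, q_threshold = 1,
                        use_relative = FALSE)
  r_pkg <- igraph::as_data_frame(net)$r
  expect_equal(r_pkg, cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_equal(r_pkg, suppressWarnings(
    cor.test(x, y, method = "spearman")$estimate[[1]]), tolerance = 1e-12)
})

test_that("network topology matches hand values on canonical graphs", {
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  topo <- network_topology(k5)
  expect_equal(topo$graph_density, 1)
  expect_equal(topo$clustering_coefficient, 1)
  expect_equal(topo$average_path_length, 1)
  expect_equal(topo$network_diameter, 1)
  expect_equal(topo$average_degree, 4)
  expect_equal(topo$degree_centralization, 0)

  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- letters[1:5]
  tst <- network_topology(star)
  expect_equal(tst$degree_centralization, 1)
  expect_equal(tst$betweenness_centralization, 1)

  path <- igraph::graph_from_literal(A - B, B - C)
  tp <- network_topology(path)
  expect_equal(tp$average_path_length, 4 / 3)
  expect_equal(tp$network_diameter, 2)

  cyc <- igraph::make_ring(6)
  igraph::V(cyc)$name <- letters[1:6]
  expect_equal(network_topology(cyc)$degree_centralization, 0)

  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_true(is.na(network_topology(empty)$average_degree))
})

test_that("module detection finds planted cliques with Q = 0.5", {
  g <- igraph::disjoint_union(igraph::make_full_graph(4),
                              igraph::make_full_graph(4))
  igraph::V(g)$name <- letters[1:8]
  mod <- detect_modules(g, seed = 1)
  expect_equal(mod$modularity, 0.5)
  expect_equal(length(unique(mod$membership)), 2)
  expect_equal(length(unique(mod$membership[1:4])), 1)

  single <- igraph::make_full_graph(5)
  igraph::V(single)$name <- letters[1:5]
  expect_equal(length(unique(detect_modules(single)$membership)), 1)

  edgeless <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(edgeless)$name <- c("a", "b", "c")
  m0 <- detect_modules(edgeless)
  expect_equal(m0$modularity, 0)
  expect_equal(length(unique(m0$membership)), 3)

  expect_identical(detect_modules(g, seed = 4), detect_modules(g, seed = 4))
})

test_that("node topology matches hand values", {
  star <- igraph::make_star(5, center = 1, mode = "undirected")
  igraph::V(star)$name <- c("hub", "a", "b", "c", "d")
  nt <- node_topology(star)
  hub <- nt[nt$node == "hub", ]
  expect_equal(hub$degree, 4)
  expect_equal(hub$betweenness, 1)

  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  expect_true(all(node_topology(k5)$transitivity == 1))

  path <- igraph::graph_from_literal(A - B, B - C)
  expect_equal(node_topology(path)$betweenness[2], 1)

  iso <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(iso)$name <- c("a", "b")
  expect_equal(node_topology(iso)$closeness, c(0, 0))
  expect_true(all(is.na(node_topology(iso)$transitivity)))
})

test_that("subnetwork extraction induces on group-present taxa", {
  set.seed(11)
  m <- matrix(rpois(40, 4) + 1, 4, 10,
              dimnames = list(c("a", "b", "c", "d"), paste0("s", 1:10)))
  m[c("c", "d"), 1:5] <- 0L
  tab <- otu_table(m)
  net <- igraph::graph_from_literal(a - b, b - c, c - d)
  full <- extract_subnetwork(net, tab, paste0("s", 1:10))
  expect_equal(igraph::vcount(full), 4)
  sub <- extract_subnetwork(net, tab, paste0("s", 1:5))
  expect_setequal(igraph::V(sub)$name, c("a", "b"))
  expect_equal(igraph::ecount(sub), 1)
  expect_lte(igraph::vcount(sub), igraph::vcount(net))
  expect_error(extract_subnetwork(net, tab, "nope"), "unknown sample")
})
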