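test_that("betaMNTD matches hand values and is symmetric", {
  pd <- cophenetic_distances(tree4())
  A <- c(A = 1, B = 0, C = 0, D = 0)
  C_ <- c(A = 0, B = 0, C = 1, D = 0)
  expect_equal(beta_mntd(A, C_, pd), 4)
  expect_equal(beta_mntd(C_, A, pd), 4)

  # identical taxon sets: every nearest-taxon distance is 0
  x <- c(A = 3, B = 1, C = 0, D = 0)
  y <- c(A = 9, B = 2, C = 0, D = 0)
  expect_equal(beta_mntd(x, y, pd), 0)
  expect_error(beta_mntd(c(A = 0, B = 0, C = 0, D = 0), y, pd), "empty")
})

test_that("betaMNTD equals the brute-force double loop on random fixtures", {
  for (seed in 1:6) {
    set.seed(seed)
    tr <- simulate_phylogeny(10)
    pd <- cophenetic_distances(tr)
    x <- setNames(rpois(10, 2), tr$tip.label)
    y <- setNames(rpois(10, 2), tr$tip.label)
    if (sum(x) == 0) x[1] <- 1
    if (sum(y) == 0) y[2] <- 1
    for (w in c(TRUE, FALSE)) {
      expect_equal(beta_mntd(x, y, pd, weighted = w),
                   brute_beta_mntd(x, y, pd, weighted = w),
                   tolerance = 1e-10)
    }
  }
})

test_that("abundance-weighted betaMNTD matches picante's comdistnt", {
  skip_if_not_installed("picante")
  for (s in 1:3) {
    set.seed(s)
    tr <- simulate_phylogeny(15)
    pd <- cophenetic_distances(tr)
    m <- matrix(rpois(60, 2) * rbinom(60, 1, 0.7), 15, 4,
                dimnames = list(tr$tip.label, paste0("S", 1:4)))
    m[1, colSums(m) == 0] <- 1
    tab <- suppressMessages(otu_table(m))
    mine <- beta_mntd_matrix(tab, pd, weighted = TRUE)
    ref <- as.matrix(picante::comdistnt(t(m), pd, abundance.weighted = TRUE))
    expect_equal(mine, ref[rownames(mine), colnames(mine)],
                 tolerance = 1e-10)
  }
})

test_that("betaNTI flags degenerate nulls on a star phylogeny", {
  pd <- cophenetic_distances(star_tree(6))
  x <- setNames(c(1, 1, 1, 0, 0, 0), rownames(pd))
  y <- setNames(c(0, 0, 0, 1, 1, 1), rownames(pd))
  expect_warning(res <- bnti_pair(x, y, pd, n_null = 49, seed = 1),
                 "degenerate")
  expect_true(res$degenerate)
  expect_true(is.na(res$bnti))
})

test_that("identical taxon sets give zero betaMNTD and a degenerate null", {
  # shared taxa keep distance zero under every joint relabelling, so a
  # pair with identical taxon sets has an all-zero null distribution
  tr <- simulate_phylogeny(20, seed = 30)
  pd <- cophenetic_distances(tr)
  set.seed(30)
  x <- setNames(rpois(20, 3) + (seq_len(20) <= 8), tr$tip.label)
  expect_warning(res <- bnti_pair(x, x, pd, n_null = 99, seed = 2),
                 "degenerate")
  expect_equal(res$beta_mntd_obs, 0)
  expect_true(res$degenerate)
})

test_that("betaNTI is invariant to branch-length scale", {
  tr <- simulate_phylogeny(15, seed = 31)
  pd <- cophenetic_distances(tr)
  set.seed(32)
  m <- matrix(rpois(45, 2) * rbinom(45, 1, 0.6), 15, 3)
  m[1, colSums(m) == 0] <- 1
  tab <- suppressMessages(toy_table(m, taxa = tr$tip.label))
  a <- bnti(tab, pd, n_null = 199, seed = 3)
  b <- bnti(tab, pd * 10, n_null = 199, seed = 3)
  expect_false(any(a$degenerate))
  expect_equal(a$bnti, b$bnti, tolerance = 1e-8)
})

test_that("fixed seed reproduces betaNTI and RC matrices exactly", {
  tr <- simulate_phylogeny(12, seed = 33)
  pd <- cophenetic_distances(tr)
  set.seed(34)
  m <- matrix(rpois(48, 3) * rbinom(48, 1, 0.7), 12, 4)
  m[1, colSums(m) == 0] <- 1
  tab <- suppressMessages(toy_table(m, taxa = tr$tip.label))
  expect_identical(bnti(tab, pd, n_null = 99, seed = 5),
                   bnti(tab, pd, n_null = 99, seed = 5))
  expect_identical(rc_bray(tab, n_null = 99, seed = 6),
                   rc_bray(tab, n_null = 99, seed = 6))
})

test_that("RC_bray hits its limits: identical pairs near -1, disjoint near +1", {
  set.seed(35)
  pool <- 60
  # heterogeneous occupancy: 15 core taxa, 45 sparse satellites
  lam <- rep(c(6, 0.3), c(15, 45))
  meta_m <- matrix(rpois(pool * 20, lam), pool, 20,
                   dimnames = list(paste0("t", 1:pool), paste0("s", 1:20)))
  meta_m[, colSums(meta_m) == 0] <- 1
  meta <- suppressMessages(otu_table(meta_m))

  # two identical rich samples against the pool metacommunity
  rcs <- vapply(1:5, function(s) {
    x <- unclass(meta)[, 1]
    m2 <- cbind(x, x)
    dimnames(m2) <- list(rownames(meta), c("a", "b"))
    suppressMessages(rc_bray(otu_table(m2), metacommunity = meta,
                             n_null = 199, seed = s)$rc)
  }, numeric(1))
  expect_lt(mean(rcs), -0.9)

  # samples on disjoint satellite taxa, richness well below the pool's
  rcd <- vapply(1:5, function(s) {
    m2 <- matrix(0L, pool, 2, dimnames = list(rownames(meta), c("a", "b")))
    m2[16:25, 1] <- 5L
    m2[26:35, 2] <- 5L
    suppressMessages(rc_bray(otu_table(m2), metacommunity = meta,
                             n_null = 199, seed = s)$rc)
  }, numeric(1))
  expect_gt(mean(rcd), 0.9)

  expect_true(all(abs(c(rcs, rcd)) <= 1))
})

test_that("RC_bray validates richness against the pool", {
  meta <- toy_table(matrix(c(1, 0, 2, 0, 3, 0), 2, 3))
  bad <- matrix(c(1L, 1L, 1L, 0L), 2, 2,
                dimnames = list(rownames(meta), c("a", "b")))
  expect_error(rc_bray(otu_table(bad), metacommunity = meta),
               "exceeds")
})

test_that("pair classification follows the betaNTI/RC thresholds", {
  expect_equal(classify_pair(-3, 0.2), "homogeneous_selection")
  expect_equal(classify_pair(3, -0.2), "heterogeneous_selection")
  expect_equal(classify_pair(0.5, 0.99), "dispersal_limitation")
  expect_equal(classify_pair(0.5, -0.99), "homogenizing_dispersal")
  expect_equal(classify_pair(0, 0), "drift")
  # boundary values fall to the stochastic / drift side
  expect_equal(classify_pair(c(-2, 2), c(0, 0)), rep("drift", 2))
  expect_equal(classify_pair(c(0, 0), c(-0.95, 0.95)), rep("drift", 2))
  expect_error(classify_pair(NaN, 0), "finite")
  expect_error(classify_pair(0, NA), "finite")
})

test_that("process partitioning tallies classified pairs", {
  expect_equal(unname(partition_processes(rep("drift", 10))),
               c(0, 0, 0, 0, 1))
  mixed <- c(rep("homogeneous_selection", 3), rep("drift", 2),
             rep("dispersal_limitation", 2), "heterogeneous_selection")
  part <- partition_processes(mixed)
  expect_equal(sum(part), 1)
  expect_equal(unname(part["homogeneous_selection"]), 3 / 8)
  expect_equal(unname(part["dispersal_limitation"]), 2 / 8)
  expect_error(partition_processes(c(NA_character_, NA)), "no classifiable")
  expect_error(partition_processes("selection"), "unknown process")
})

test_that("assembly_processes combines the pieces per group", {
  reg <- simulate_regime("neutral", seed = 40, n_taxa = 60, N = 400,
                         n_samples = 6)
  res <- suppressMessages(suppressWarnings(assembly_processes(
    reg$table, reg$tree, rep(c("g1", "g2"), each = 3), n_null = 99,
    seed = 41)))
  expect_equal(nrow(res$pairs), 2 * choose(3, 2))
  expect_setequal(res$partition$group, c("g1", "g2"))
  expect_equal(rowSums(res$partition[, -1]), c(1, 1), ignore_attr = TRUE)
})
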