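test_that("Yule phylogenies are valid and reproducible", {
  tr <- simulate_phylogeny(2, seed = 1)
  expect_equal(length(tr$tip.label), 2)
  expect_equal(tr$Nnode, 1)

  a <- ape::write.tree(simulate_phylogeny(40, seed = 9))
  b <- ape::write.tree(simulate_phylogeny(40, seed = 9))
  expect_identical(a, b)

  d <- cophenetic_distances(simulate_phylogeny(100, seed = 2))
  expect_equal(dim(d), c(100, 100))
  expect_equal(d, t(d))
  expect_true(all(d[upper.tri(d)] > 0))

  expect_error(simulate_phylogeny(1), "at least 2")
})

test_that("lognormal metacommunities are normalized and strongly dominated", {
  expect_equal(unname(simulate_metacommunity(1, seed = 1)), 1)
  p <- simulate_metacommunity(500, seed = 3)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_error(simulate_metacommunity(10, sdlog = 0), "positive")

  # with sdlog = 1.5 the top decile of taxa holds over half the mass
  top_mass <- vapply(1:20, function(s) {
    p <- simulate_metacommunity(200, sdlog = 1.5, seed = s)
    sum(sort(p, decreasing = TRUE)[1:20])
  }, numeric(1))
  expect_gt(median(top_mass), 0.5)
  expect_true(all(top_mass > 0.4))
})

test_that("neutral communities conserve N and are seed-reproducible", {
  p <- simulate_metacommunity(60, seed = 4)
  tab <- simulate_neutral_samples(p, N = 500, m = 0.2, n_samples = 8,
                                  seed = 5)
  expect_true(all(colSums(tab) == 500))
  tab2 <- simulate_neutral_samples(p, N = 500, m = 0.2, n_samples = 8,
                                   seed = 5)
  expect_identical(unclass(tab), unclass(tab2))
  expect_warning(simulate_neutral_samples(p, N = 500, m = 0.5,
                                          n_samples = 1, burn_in = 100,
                                          seed = 1),
                 "burn_in")
  expect_error(simulate_neutral_samples(p, N = 5, m = 0.5, n_samples = 1),
               "at least 10")
  expect_error(simulate_neutral_samples(p, N = 100, m = 0, n_samples = 1),
               "m must")
})

test_that("at m = 1 per-taxon means match the metacommunity", {
  p <- simulate_metacommunity(40, seed = 6)
  tab <- simulate_neutral_samples(p, N = 1000, m = 1, n_samples = 100,
                                  seed = 7)
  rel <- to_relative_abundance(tab)
  mu <- rowMeans(rel)
  se <- apply(rel, 1, sd) / sqrt(ncol(rel))
  frac_in <- mean(abs(mu - p) <= 3 * pmax(se, 1e-6))
  expect_gt(frac_in, 0.9)
})

test_that("smaller migration gives a shallower occurrence-frequency curve", {
  p <- simulate_metacommunity(150, seed = 8)
  lo <- simulate_neutral_samples(p, N = 1000, m = 0.05, n_samples = 40,
                                 seed = 9)
  hi <- simulate_neutral_samples(p, N = 1000, m = 0.9, n_samples = 40,
                                 seed = 10)
  mid <- p > quantile(p, 0.4) & p < quantile(p, 0.9)
  expect_lt(mean(rowMeans(unclass(lo) > 0)[mid]),
            mean(rowMeans(unclass(hi) > 0)[mid]))
})

test_that("selection converges to neutral sampling as sigma grows", {
  tr <- simulate_phylogeny(80, seed = 11)
  p <- simulate_metacommunity(80, seed = 12)
  names(p) <- tr$tip.label
  tv <- vapply(c(0.5, 5, 50), function(sg) {
    tab <- simulate_selected_samples(tr, p, rep(0, 30), sigma = sg,
                                     N = 2000, seed = 13)
    mu <- rowMeans(to_relative_abundance(tab))
    0.5 * sum(abs(mu - p[rownames(tab)]))
  }, numeric(1))
  expect_true(tv[3] < tv[2] && tv[2] < tv[1])
})

test_that("homogeneous selection raises community overlap above neutral", {
  tr <- simulate_phylogeny(100, seed = 14)
  p <- simulate_metacommunity(100, seed = 15)
  names(p) <- tr$tip.label
  jac <- function(tab) {
    m <- unclass(tab) > 0
    pairs <- utils::combn(ncol(m), 2)
    mean(apply(pairs, 2, function(ij)
      sum(m[, ij[1]] & m[, ij[2]]) / sum(m[, ij[1]] | m[, ij[2]])))
  }
  sel <- simulate_selected_samples(tr, p, rep(1, 10), sigma = 0.4,
                                   N = 300, seed = 16)
  neu <- simulate_neutral_samples(p, N = 300, m = 1, n_samples = 10,
                                  seed = 16)
  expect_gt(jac(sel), jac(neu))
  expect_error(simulate_selected_samples(tr, p, 1:3, sigma = 1, N = 100,
                                         n_samples = 5),
               "env_values length")
})

test_that("Brownian trait divergence grows with phylogenetic distance", {
  # under Brownian motion E[(t_i - t_j)^2] equals the path length between
  # tips, so the regression of squared trait contrasts on cophenetic
  # distance has positive slope
  slopes <- vapply(1:10, function(s) {
    tr <- simulate_phylogeny(60, seed = 100 + s)
    tab <- simulate_selected_samples(tr, simulate_metacommunity(60),
                                     rep(0, 2), sigma = 10, N = 100,
                                     seed = 200 + s)
    traits <- attr(tab, "traits")[tr$tip.label]
    pd <- cophenetic_distances(tr)
    ut <- upper.tri(pd)
    dd <- outer(traits, traits, "-")^2
    coef(lm(dd[ut] ~ pd[ut]))[[2]]
  }, numeric(1))
  expect_gt(mean(slopes > 0), 0.7)
})

test_that("dispersal limitation produces distance decay that vanishes with scale", {
  p <- simulate_metacommunity(120, seed = 17)
  set.seed(18)
  coords <- data.frame(latitude = runif(12, 37, 40),
                       longitude = runif(12, 118, 122))
  geo <- haversine_matrix(coords$latitude, coords$longitude,
                          ids = sprintf("S%02d", 1:12))

  fits <- lapply(1:3, function(s) {
    tab <- simulate_dispersal_limited(p, coords, decay_scale = 100,
                                      N = 2000, seed = s)
    mantel_test(bray_curtis(tab), geo, n_perm = 199, seed = s)
  })
  expect_true(all(vapply(fits, `[[`, numeric(1), "r") > 0))
  expect_true(all(vapply(fits, `[[`, numeric(1), "p_value") <= 0.05))

  far <- simulate_dispersal_limited(p, coords, decay_scale = 1e6,
                                    N = 2000, seed = 1)
  r_far <- mantel_test(bray_curtis(far), geo, n_perm = 199, seed = 1)$r
  expect_lt(abs(r_far), 0.3)
  expect_true(all(colSums(far) == 2000))
  expect_error(simulate_dispersal_limited(p, coords[1, ], 10, 100),
               "at least 2")
})

test_that("the study layout has 75 samples in the five groups, reproducibly", {
  lay <- generate_study_layout(seed = 3, n_taxa = 120, N = 600)
  expect_equal(ncol(lay$table), 75)
  expect_equal(unname(table(lay$meta$group)[study_groups()]),
               rep(15L, 5), ignore_attr = TRUE)
  expect_setequal(unique(lay$meta$group), study_groups())
  lay2 <- generate_study_layout(seed = 3, n_taxa = 120, N = 600)
  expect_identical(unclass(lay$table), unclass(lay2$table))
  expect_identical(ape::write.tree(lay$tree), ape::write.tree(lay2$tree))
  expect_identical(lay$meta, lay2$meta)
})

test_that("canonical regimes are reproducible and labelled", {
  r1 <- simulate_regime("neutral", seed = 5, n_taxa = 40, N = 200,
                        n_samples = 5)
  r2 <- simulate_regime("neutral", seed = 5, n_taxa = 40, N = 200,
                        n_samples = 5)
  expect_identical(unclass(r1$table), unclass(r2$table))
  expect_equal(r1$kind, "neutral")
  clade <- specialist_clade(simulate_phylogeny(100, seed = 1), size = 20)
  expect_true(length(clade) >= 10 && length(clade) <= 40)
})
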