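#' Simulate a pure-birth (Yule) phylogeny
#'
#' @param n_tips number of tips (>= 2); labels are `t1 ... tn`.
#' @param birth_rate speciation rate of the Yule process.
#' @param seed optional RNG seed; fixed seed gives an identical tree.
#' @return a rooted `phylo` object with strictly positive branch lengths.
#' @export
simulate_phylogeny <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (n_tips < 2) stop("n_tips must be at least 2")
  if (birth_rate <= 0) stop("birth_rate must be positive")
  with_seed(seed, ape::rphylo(n_tips, birth = birth_rate, death = 0))
}

#' Simulate lognormal metacommunity relative abundances
#'
#' Draws independent lognormal abundances and normalises them to sum to 1,
#' giving the heavy-tailed rank-abundance structure typical of 16S surveys.
#'
#' @param n_taxa number of taxa (>= 1).
#' @param meanlog,sdlog lognormal parameters on the log scale; `sdlog` must
#'   be positive (1.5 gives a realistically steep curve where the top decile
#'   of taxa holds most of the mass).
#' @param seed optional RNG seed.
#' @return numeric vector of proportions summing to 1, named `t1 ... tn`.
#' @export
simulate_metacommunity <- function(n_taxa, meanlog = 0, sdlog = 1.5,
                                   seed = NULL) {
  if (n_taxa < 1) stop("n_taxa must be at least 1")
  if (sdlog <= 0) stop("sdlog must be positive")
  x <- with_seed(seed, rlnorm(n_taxa, meanlog, sdlog))
  setNames(x / sum(x), paste0("t", seq_len(n_taxa)))
}

#' Simulate neutral local communities (Sloan death-replacement process)
#'
#' Each sample is an independent local community of `N` individuals evolved
#' by single-individual death-replacement: the replacement is an immigrant
#' drawn from the metacommunity or the offspring of a local individual. The
#' migration rate `m` is expressed on the Sloan neutral-model scale, i.e.
#' the chain's stationary distribution is Dirichlet-multinomial with
#' concentration `N * m * meta_p` (the distribution the neutral community
#' model assumes); the corresponding per-replacement immigration probability
#' is `m / (1 + m)`.
#'
#' @param meta_p metacommunity relative abundances (summing to 1).
#' @param N local community size (>= 10 individuals).
#' @param m migration rate in (0, 1], Sloan scale.
#' @param n_samples number of independent local communities.
#' @param burn_in death-replacement events before sampling; the default is
#'   five relaxation times (`5 * N / m_event`) of the chain. A value below
#'   `N` triggers a warning (insufficient mixing).
#' @param seed optional RNG seed.
#' @return an [otu_table()] with every column summing to `N`.
#' @export
simulate_neutral_samples <- function(meta_p, N, m, n_samples,
                                     burn_in = NULL, seed = NULL) {
  if (N < 10) stop("N must be at least 10")
  if (m <= 0 || m > 1) stop("m must be in (0, 1]")
  if (abs(sum(meta_p) - 1) > 1e-6) stop("meta_p must sum to 1")
  m_event <- m / (1 + m)
  if (is.null(burn_in)) burn_in <- ceiling(5 * N / m_event)
  if (burn_in < N)
    warning("burn_in below N: local communities may not be well mixed")
  taxa <- names(meta_p)
  if (is.null(taxa)) taxa <- paste0("t", seq_along(meta_p))
  counts <- with_seed(seed, vapply(
    seq_len(n_samples),
    function(i) cpp_neutral_community(as.numeric(meta_p), as.integer(N),
                                      m_event, as.integer(burn_in)),
    integer(length(meta_p))))
  dimnames(counts) <- list(taxa, sprintf("S%02d", seq_len(n_samples)))
  otu_table(counts)
}

#' Simulate communities under environmental selection
#'
#' Each taxon receives a trait optimum by Brownian motion along the tree
#' (root value 0, variance proportional to branch length); sample `k` with
#' environmental value `env_values[k]` draws `N` individuals with
#' probability proportional to
#' `meta_p * exp(-(env - optimum)^2 / (2 * sigma^2))`.
#' Identical `env_values` emulate homogeneous selection; strongly divergent
#' values emulate heterogeneous selection. As `sigma` grows the regime
#' converges to neutral multinomial sampling.
#'
#' Two optional layers add realism for stronger regimes: `suitability`
#' restricts the candidate pool to taxa carrying a (perfectly conserved)
#' habitat-suitability trait, and `dropout` / `sample_noise_sd` add
#' demographic drift around the deterministic filter — per-sample
#' stochastic colonization failure and lognormal abundance noise. Both
#' are off by default.
#'
#' @param tree `phylo` whose tips are the taxa.
#' @param meta_p metacommunity relative abundances in `tree$tip.label`
#'   order (or named by tip label).
#' @param env_values per-sample environmental values.
#' @param sigma selection width (> 0), in trait units.
#' @param N individuals per sample.
#' @param n_samples number of samples; must equal `length(env_values)`.
#' @param trait_sigma Brownian-motion rate (trait SD per unit branch length).
#' @param suitability optional 0/1 (or logical) vector over tips: taxa with
#'   0 cannot establish regardless of their continuous trait.
#' @param dropout per-sample probability that an otherwise suitable taxon
#'   fails to colonize (demographic drift), in `[0, 1)`.
#' @param sample_noise_sd SD of per-sample lognormal abundance noise.
#' @param traits optional precomputed trait optima (named by tip); when
#'   supplied no Brownian simulation is run.
#' @param seed optional RNG seed.
#' @return an [otu_table()]; the trait optima are attached as attribute
#'   `"traits"`.
#' @export
simulate_selected_samples <- function(tree, meta_p, env_values, sigma, N,
                                      n_samples = length(env_values),
                                      trait_sigma = 1, suitability = NULL,
                                      dropout = 0, sample_noise_sd = 0,
                                      traits = NULL, seed = NULL) {
  if (sigma <= 0) stop("sigma must be positive")
  if (length(env_values) != n_samples)
    stop("env_values length must equal n_samples")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  tips <- tree$tip.label
  if (!is.null(names(meta_p))) meta_p <- meta_p[tips]
  if (length(meta_p) != length(tips) || anyNA(meta_p))
    stop("meta_p must cover every tree tip")
  if (is.null(suitability)) suitability <- rep(1, length(tips))
  if (!is.null(names(suitability))) suitability <- suitability[tips]
  suitability <- as.numeric(suitability)
  with_seed(seed, {
    if (is.null(traits))
      traits <- ape::rTraitCont(tree, model = "BM", sigma = trait_sigma,
                                root.value = 0)
    else if (!is.null(names(traits))) traits <- traits[tips]
    base <- meta_p * suitability *
      exp(-outer(traits, env_values, function(t, e) (e - t)^2) /
            (2 * sigma^2))
    counts <- vapply(seq_len(n_samples), function(k) {
      w <- base[, k]
      if (dropout > 0) w <- w * rbinom(length(w), 1, 1 - dropout)
      if (sample_noise_sd > 0)
        w <- w * exp(rnorm(length(w), 0, sample_noise_sd))
      if (sum(w) <= 0) w <- base[, k]
      if (sum(w) <= 0) stop("selection weights vanished; increase sigma")
      as.integer(rmultinom(1, N, w))
    }, integer(length(tips)))
    dimnames(counts) <- list(tips, sprintf("S%02d", seq_len(n_samples)))
    tab <- otu_table(counts)
    attr(tab, "traits") <- traits
    tab
  })
}

#' Locate a specialist clade of approximately a given size
#'
#' Returns the tip labels of the monophyletic group whose size is closest
#' to `size` (earliest such node on ties). Used by the
#' homogeneous-selection regime as a perfectly conserved habitat
#' suitability trait: only members of this clade can establish in the
#' habitat.
#'
#' @param tree a `phylo` object.
#' @param size target clade size.
#' @return character vector of tip labels.
#' @export
specialist_clade <- function(tree, size = 30) {
  subtrees <- ape::subtrees(tree)
  sizes <- vapply(subtrees, function(s) length(s$tip.label), integer(1))
  subtrees[[which.min(abs(sizes - size))]]$tip.label
}

#' Generate one canonical assembly regime
#'
#' Produces a 15-sample community table with a known dominant assembly
#' process, together with the phylogeny and metacommunity used. The four
#' regimes:
#' \describe{
#'   \item{neutral}{independent Sloan death-replacement communities,
#'     migration rate `m = 0.3`.}
#'   \item{homogeneous_selection}{an identical environment across samples
#'     admits only a ~30-taxon specialist clade (conserved suitability
#'     trait) filtered by a Gaussian kernel on the within-clade Brownian
#'     trait, with colonization dropout 0.5 and lognormal abundance noise
#'     (SD 1) supplying drift around the filter.}
#'   \item{heterogeneous_selection}{environments spread over `[-4, 4]`
#'     across samples with a narrow selection width (`sigma = 0.5`) on a
#'     Brownian trait.}
#'   \item{dispersal_limited}{site-specific pools on 15 coastal sites with
#'     a 50 km correlation length.}
#' }
#'
#' @param kind one of the four regime names.
#' @param seed RNG seed.
#' @param n_taxa metacommunity size.
#' @param N individuals per sample.
#' @param n_samples samples per regime.
#' @return list with `table`, `tree`, `meta_p`, `kind`.
#' @export
simulate_regime <- function(kind = c("neutral", "homogeneous_selection",
                                     "heterogeneous_selection",
                                     "dispersal_limited"),
                            seed = 1, n_taxa = 300, N = 5000,
                            n_samples = 15) {
  kind <- match.arg(kind)
  with_seed(seed, {
    tree <- simulate_phylogeny(n_taxa, birth_rate = 1)
    meta_p <- simulate_metacommunity(n_taxa)
    names(meta_p) <- tree$tip.label
    table <- switch(
      kind,
      neutral = simulate_neutral_samples(meta_p, N = N, m = 0.3,
                                         n_samples = n_samples),
      homogeneous_selection = {
        clade <- specialist_clade(tree, size = 30)
        traits <- ape::rTraitCont(tree, model = "BM", sigma = 1,
                                  root.value = 0)
        simulate_selected_samples(
          tree, meta_p,
          env_values = rep(mean(traits[clade]), n_samples),
          sigma = sd(traits[clade]), N = N,
          suitability = tree$tip.label %in% clade,
          dropout = 0.5, sample_noise_sd = 1, traits = traits)
      },
      heterogeneous_selection = simulate_selected_samples(
        tree, meta_p, env_values = seq(-4, 4, length.out = n_samples),
        sigma = 0.5, N = N),
      dispersal_limited = {
        sites <- data.frame(latitude = runif(n_samples, 37.5, 40.5),
                            longitude = runif(n_samples, 118, 122))
        simulate_dispersal_limited(meta_p, sites, decay_scale = 50, N = N)
      })
    list(table = table, tree = tree, meta_p = meta_p, kind = kind)
  })
}

#' Simulate dispersal-limited communities over a set of sites
#'
#' Every site draws `N` individuals from a site-specific species pool built
#' by re-weighting the metacommunity with spatially autocorrelated
#' log-Gaussian noise (correlation `exp(-d / decay_scale)` on haversine
#' distances between sites). Nearby sites share pools, producing a positive
#' distance-decay of community similarity; as `decay_scale` grows all sites
#' converge on a single shared pool.
#'
#' @param meta_p metacommunity relative abundances.
#' @param site_coords data.frame with columns `latitude`, `longitude`
#'   (decimal degrees), one row per site (>= 2 sites).
#' @param decay_scale correlation length in km (> 0).
#' @param N individuals per site sample.
#' @param noise_sd standard deviation of the log-scale pool noise; larger
#'   values differentiate site pools more strongly.
#' @param seed optional RNG seed.
#' @return an [otu_table()] with one sample per site.
#' @export
simulate_dispersal_limited <- function(meta_p, site_coords, decay_scale, N,
                                       noise_sd = 2, seed = NULL) {
  if (decay_scale <= 0) stop("decay_scale must be positive")
  n_sites <- nrow(site_coords)
  if (is.null(n_sites) || n_sites < 2) stop("need at least 2 sites")
  D <- haversine_matrix(site_coords$latitude, site_coords$longitude)
  Sigma <- exp(-D / decay_scale)
  L <- t(chol(Sigma + diag(1e-8, n_sites)))
  taxa <- names(meta_p)
  if (is.null(taxa)) taxa <- paste0("t", seq_along(meta_p))
  with_seed(seed, {
    z <- matrix(rnorm(n_sites * length(meta_p)), n_sites)
    eps <- L %*% z   # sites x taxa, correlated across sites
    counts <- vapply(seq_len(n_sites), function(s) {
      w <- meta_p * exp(noise_sd * eps[s, ])
      as.integer(rmultinom(1, N, w))
    }, integer(length(meta_p)))
    dimnames(counts) <- list(taxa, sprintf("S%02d", seq_len(n_sites)))
    otu_table(counts)
  })
}

#' Generate the 75-sample five-group synthetic study layout
#'
#' Emulates a coastal survey: 15 sites sampled in five habitat groups
#' (`Sur_FL`, `Sur_PA`, `Bot_FL`, `Bot_PA`, `Sed`), one shared species pool
#' and phylogeny. The planktonic groups are generated under
#' stochastic-heavy regimes (dispersal limitation for `Sur_FL`, `Sur_PA`,
#' `Bot_PA`; neutral drift for `Bot_FL`) and the sediment group under a
#' homogeneous-selection regime (identical environment, narrow selection
#' width). Metadata carries group labels, site coordinates, and synthetic
#' environmental covariates (absent for sediment).
#'
#' @param seed RNG seed; the whole layout is reproducible from it.
#' @param n_taxa species-pool size.
#' @param N individuals per sample.
#' @return list with elements `table` ([otu_table()]), `tree` (`phylo`),
#'   `meta` (metadata `data.frame`), and `regimes` (the generating process
#'   per group).
#' @export
generate_study_layout <- function(seed = 1, n_taxa = 400, N = 5000) {
  regimes <- c(Sur_FL = "dispersal_limited", Sur_PA = "dispersal_limited",
               Bot_FL = "neutral", Bot_PA = "dispersal_limited",
               Sed = "homogeneous_selection")
  with_seed(seed, {
    tree <- simulate_phylogeny(n_taxa, birth_rate = 1)
    meta_p <- simulate_metacommunity(n_taxa)
    names(meta_p) <- tree$tip.label
    n_sites <- 15
    sites <- data.frame(
      site = sprintf("st%02d", seq_len(n_sites)),
      latitude = round(runif(n_sites, 37.5, 40.5), 4),
      longitude = round(runif(n_sites, 118, 122), 4))

    sim_group <- function(group) {
      tab <- switch(
        regimes[[group]],
        dispersal_limited = simulate_dispersal_limited(
          meta_p, sites, decay_scale = switch(group, Sur_FL = 75, Sur_PA = 50,
                                              Bot_PA = 50),
          N = N),
        neutral = simulate_neutral_samples(meta_p, N = N, m = 0.15,
                                           n_samples = n_sites),
        homogeneous_selection = {
          clade <- specialist_clade(tree, size = 30)
          traits <- ape::rTraitCont(tree, model = "BM", sigma = 1,
                                    root.value = 0)
          simulate_selected_samples(
            tree, meta_p,
            env_values = rep(mean(traits[clade]), n_sites),
            sigma = sd(traits[clade]), N = N,
            suitability = tree$tip.label %in% clade,
            dropout = 0.5, sample_noise_sd = 1, traits = traits)
        })
      m <- otu_counts(tab)
      colnames(m) <- paste(group, sites$site, sep = "_")
      m
    }
    counts <- do.call(cbind, lapply(names(regimes), sim_group))

    meta <- do.call(rbind, lapply(names(regimes), function(group) {
      surface <- grepl("^Sur", group)
      water <- group != "Sed"
      data.frame(
        sample_id = paste(group, sites$site, sep = "_"),
        group = group, site = sites$site,
        latitude = sites$latitude, longitude = sites$longitude,
        temperature = if (water)
          round((if (surface) 26 else 19) - 1.2 * (sites$latitude - 37.5) +
                  rnorm(n_sites, 0, 0.4), 2) else NA_real_,
        salinity = if (water)
          round(29 + 0.6 * (sites$longitude - 118) + rnorm(n_sites, 0, 0.3), 2)
          else NA_real_,
        nitrate = if (water)
          round(exp(rnorm(n_sites, if (surface) 0.5 else 1.2, 0.4)), 2)
          else NA_real_)
    }))
    rownames(meta) <- NULL
    list(table = otu_table(counts), tree = tree, meta = meta,
         regimes = regimes)
  })
}
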