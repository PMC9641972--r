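# assemblyscope

Statistical machinery for asking *how microbial communities are
assembled* — and for comparing the answer across habitats. Given an OTU
count table, a rooted phylogeny, and per-sample metadata, assemblyscope
partitions community turnover into five ecological processes
(homogeneous selection, heterogeneous selection, homogenizing dispersal,
dispersal limitation, ecological drift) with the betaNTI / Raup–Crick
null-model framework, fits the Sloan neutral community model, computes
Levins niche breadth, runs the standard diversity and permutation-test
toolkit (Chao1/ACE/Shannon, Bray–Curtis, PERMANOVA, ANOSIM,
Kruskal–Wallis), tests environment association with Mantel and partial
Mantel tests, and builds Spearman co-occurrence networks with full
network- and node-level topology.

It is aimed at microbial ecologists analysing multi-habitat 16S surveys
(e.g. free-living vs particle-associated fractions of surface and bottom
seawater against sediment), and ships a synthetic-community generator
with *known* assembly regimes so that every inference stage can be
validated against ground truth.

## The core statistics

For a pair of communities $k$, $m$ with phylogenetic distances $d_{ij}$
and relative abundances $f$:

$$
\beta\mathrm{MNTD}(k,m) = \tfrac12\Big[\textstyle\sum_i f_{ik}
\min_{j\in m} d_{ij} + \sum_j f_{jm} \min_{i\in k} d_{ij}\Big],
\qquad
\beta\mathrm{NTI} = \frac{\beta\mathrm{MNTD}_{obs} -
\bar\beta\mathrm{MNTD}_{null}}{\mathrm{sd}(\beta\mathrm{MNTD}_{null})}
$$

with the null from 999 joint row/column shuffles of tip labels on the
distance matrix. betaNTI < −2 ⇒ homogeneous selection; betaNTI > +2 ⇒
heterogeneous selection. For |betaNTI| ≤ 2, RC_bray (the Raup–Crick
rescaled rank of observed Bray–Curtis within 999 probabilistic
reassemblies preserving richness and depth) separates homogenizing
dispersal (RC < −0.95), dispersal limitation (RC > +0.95), and drift.
The Sloan neutral model relates a taxon's mean relative abundance $p$ to
its occurrence frequency through a beta-distributed local abundance with
parameters $Nmp$, $Nm(1-p)$; `ncm_fit()` estimates the migration rate
$m$ and the goodness-of-fit $R^2$. Levins niche breadth is
$B_j = 1/\sum_i P_{ij}^2$. Details, design decisions and caveats are in
the methods vignette (`vignettes/community-assembly.Rmd`).

## Worked example

Simulate a 15-sample community under a known homogeneous-selection
regime (a conserved specialist clade under an identical environment) and
recover the process from scratch:

```r
library(assemblyscope)

reg <- simulate_regime("homogeneous_selection", seed = 1)
res <- assembly_processes(reg$table, reg$tree, rep("Sed", 15),
                          n_null = 999, seed = 1)
res$partition
#>   group homogeneous_selection heterogeneous_selection homogenizing_dispersal
#> 1   Sed                 0.971                       0                      0
#>   dispersal_limitation drift
#>              0.00952 0.019

head(res$pairs[, c("sample_i", "sample_j", "beta_mntd_obs",
                   "bnti", "rc", "process")], 4)
#>   sample_i sample_j beta_mntd_obs  bnti    rc               process
#> 1      S01      S02         0.428 -3.68 0.894 homogeneous_selection
#> 2      S01      S03         0.220 -2.93 0.992 homogeneous_selection
#> 3      S02      S03         0.755 -3.01 0.856 homogeneous_selection
#> 4      S01      S04         0.219 -2.88 0.954 homogeneous_selection
```

97% of sample pairs are called homogeneous selection: every observed
betaMNTD sits far below its null (betaNTI ≈ −3), meaning the communities
are phylogenetically much more similar than tip-shuffled chance — the
signature of consistent environmental filtering. Contrast a neutral
regime, where the Sloan model fits well and recovers its migration rate:

```r
fit <- ncm_fit(simulate_regime("neutral", seed = 1)$table)
fit
#> Sloan neutral community model fit (betabinomial occupancy)
#>   m = 0.3173, Nm = 1586, R^2 = 0.944
#>   N = 5000.0, 15 samples, 296 taxa (64.9% within 95% band)
```

The generating migration rate was 0.3; the fit returns 0.317 with
$R^2 = 0.94$ — occurrence frequency is predictable from abundance alone,
as neutral assembly implies.

The whole analysis — diversity, niche breadth, assembly partition,
neutral fits, networks, Mantel tests — runs as one pipeline on either
your files or the built-in 75-sample synthetic survey:

```r
report <- run_pipeline(pipeline_config(seed = 1), out_dir = "out")
# out/report.json, out/alpha.tsv, out/assembly_pairs.tsv,
# out/network_edges.tsv, out/node_topology.tsv
```

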