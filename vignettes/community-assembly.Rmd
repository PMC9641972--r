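---
title: "Null models, neutral fits, and co-occurrence networks: the methods behind assemblyscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null models, neutral fits, and co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assemblyscope)
```

# The question the package answers

When microbial communities are sampled from several habitats — say
free-living and particle-associated fractions of surface and bottom
seawater, plus surface sediment — the compositional differences among
samples can arise from *deterministic* processes (environmental filtering
that consistently selects certain lineages) or *stochastic* ones
(dispersal, ecological drift). assemblyscope implements the community-level
machinery used to partition these processes from an OTU table, a rooted
phylogeny, and per-sample metadata: phylogenetic and taxonomic null models
(betaNTI and the Raup–Crick metric on Bray–Curtis), the Sloan neutral
community model, Levins niche breadth, the standard diversity and
permutation-test toolkit, Mantel association with environmental distances,
and Spearman co-occurrence networks. A synthetic-community generator with
known assembly regimes provides ground truth for every inference stage.

# The null-model partition of assembly processes

## betaMNTD and betaNTI

For a pair of communities $k$ and $m$, the beta mean nearest taxon
distance is

$$
\beta\mathrm{MNTD}(k,m) = \frac{1}{2}\left[
\sum_{i} f_{ik}\,\min_{j \in m} d_{ij} +
\sum_{j} f_{jm}\,\min_{i \in k} d_{ij}
\right],
$$

where $d_{ij}$ is the cophenetic (tip-to-tip) phylogenetic distance and
$f_{ik}$ is the relative abundance of taxon $i$ in community $k$
(abundance weighting is the default; presence weights $1/S_k$ are
available, in which case the two per-community means are averaged). Taxa
shared between the two communities contribute distance zero.

betaNTI is the z-score of the observed betaMNTD against a null
distribution obtained by shuffling taxon labels jointly on the rows and
columns of the phylogenetic distance matrix (999 randomizations by
default):

$$
\beta\mathrm{NTI} = \frac{\beta\mathrm{MNTD}_{\mathrm{obs}} -
\overline{\beta\mathrm{MNTD}}_{\mathrm{null}}}{\mathrm{sd}
(\beta\mathrm{MNTD}_{\mathrm{null}})}.
$$

Three design points matter:

* **The shuffle pool is the full taxon universe of the supplied table**,
  including taxa that happen to be absent from the analysed samples. The
  null asks where the observed communities *could* sit on the available
  tree; restricting the pool to the taxa actually observed in a group
  would absorb any selection signal into the null itself and drive
  betaNTI toward zero even under strong filtering. For the same reason,
  `assembly_processes()` uses the whole aligned table's taxa as the pool
  for each group even though pairs are formed within groups.
* **One permutation is shared by all pairs within a randomization**, the
  standard scheme: it preserves the dependence structure among pairs and
  makes 999 randomizations affordable for 100+ pairs at once (the inner
  loop is compiled C++).
* **Degenerate nulls are flagged, not fudged.** On a star phylogeny — or
  for a pair whose taxon sets are identical, where every null draw is
  exactly zero — the null standard deviation vanishes; such pairs get
  `bnti = NA`, a `degenerate` flag, and are excluded from classification
  with a warning.

betaNTI is invariant to rescaling all branch lengths (the z-score cancels
scale), which the test suite checks, and the sampled null is validated
against exhaustive enumeration of all tip-label permutations on trees of
up to 7 tips.

## RC_bray

For pairs whose betaNTI lies within the selection thresholds, the
Bray–Curtis Raup–Crick metric asks whether the pair's taxonomic
dissimilarity is larger or smaller than expected under random reassembly.
Each of 999 replicates rebuilds every sample with its observed richness
and total count: taxa are drawn without replacement with probability
proportional to their occurrence frequency across the metacommunity
table, each drawn taxon receives one individual, and the remaining
individuals are allotted multinomially with probability proportional to
metacommunity mean relative abundance among the drawn taxa. With
$B_{\mathrm{obs}}$ the observed Bray–Curtis value and $B^{(r)}$ the null
values,

$$
\mathrm{RC} = 2\,\frac{\#\{B^{(r)} < B_{\mathrm{obs}}\} +
\tfrac12 \#\{B^{(r)} = B_{\mathrm{obs}}\}}{n_{\mathrm{null}}} - 1
\in [-1, 1],
$$

with equality meaning $|B^{(r)} - B_{\mathrm{obs}}| \le 10^{-10}$. One
reassembly of every sample is drawn per replicate and the null
Bray–Curtis matrix is computed across all within-group pairs; each pair's
marginal null distribution is identical to independent per-pair
reassembly, and sharing the draws makes the 999 replicates cheap. The
metacommunity defining occurrence frequencies is the group's own table by
default, consistent with within-group pairing.

## Classification

Each pair falls into exactly one of five processes:

| condition | process |
|---|---|
| betaNTI < −2 | homogeneous selection |
| betaNTI > +2 | heterogeneous selection |
| \|betaNTI\| ≤ 2 and RC < −0.95 | homogenizing dispersal |
| \|betaNTI\| ≤ 2 and RC > +0.95 | dispersal limitation |
| \|betaNTI\| ≤ 2 and \|RC\| ≤ 0.95 | drift |

Boundary values (betaNTI of exactly ±2, RC of exactly ±0.95) fall on the
stochastic/drift side, matching the strict inequalities of the
classification rule. Per-group fractions over all $n(n-1)/2$ within-group
pairs form the process partition; all thresholds are configurable in
`pipeline_config()`.

# The Sloan neutral community model

Under neutral death–replacement dynamics, a local community of $N$
individuals receives immigrants from a metacommunity in which taxon $i$
has relative abundance $p_i$. The stationary local abundance follows a
beta distribution with parameters $N m p_i$ and $N m (1 - p_i)$, so a
taxon's occurrence frequency across samples is its detection
probability, an increasing function of $p_i$. `ncm_fit()` estimates the
migration rate $m$ by least squares on the
occurrence-frequency-vs-mean-abundance curve and reports
$R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$ (possibly negative on strongly
non-neutral data, which is informative in itself).

Two occupancy models are available:

* `method = "betabinomial"` (default): the exact probability of observing
  at least one individual under the beta-binomial,
  $1 - B(Nmp,\ Nm(1-p) + N)/B(Nmp,\ Nm(1-p))$. Detection means count ≥ 1.
* `method = "beta"`: the classic continuous approximation
  $1 - I_d(Nmp,\ Nm(1-p))$ with detection limit $d = 1/N$ by default.

The continuous form systematically overestimates $m$ at survey-scale
depths because $P(\text{count}=0)$ is smaller than $P(x < 1/N)$; on
simulated neutral data at $N = 1000$ the bias is roughly +25–40%,
which is why the exact form is the default. With the exact form the fit
recovers the generating $m$ within a few percent across
$m \in \{0.05, 0.1, 0.5\}$ (the acceptance suite checks ±30% at 200
samples). Optimization is a deterministic 50-point log-grid over
$m \in (10^{-5}, 1]$ followed by bounded 1-D refinement — there is no
random initialization to go wrong. A 95% Wilson band at the realized
sample count flags taxa outside the neutral expectation (reported, never
used for refitting).

**The migration-rate scale.** The simulator
`simulate_neutral_samples()` defines $m$ on this same Sloan scale: the
death–replacement chain is run with per-event immigration probability
$m/(1+m)$, which makes its exact stationary distribution the
Dirichlet-multinomial with concentration $N m$ — precisely the
distribution the fit assumes. (A chain with literal per-event immigration
probability $m$ has stationary concentration $N m/(1-m)$; the fit applied
to it recovers $m/(1-m)$, a 100% discrepancy at $m = 0.5$. Defining both
sides on one scale makes "parameter recovery" well posed.) The default
burn-in is five relaxation times of the chain, $5N/m_{\mathrm{event}}$
events, starting from a multinomial draw of the metacommunity.

# Levins niche breadth

For taxon $j$, $B_j = 1/\sum_i P_{ij}^2$ where $P_{ij}$ is the share of
taxon $j$'s total abundance found in sample $i$: $B_j$ runs from 1
(confined to one sample) to the number of samples (evenly spread), and is
invariant to rescaling a taxon's row. The community-level value of a
sample is the unweighted mean of $B_j$ over the taxa present (count > 0)
in it — the simplest defensible reading of a community average; an
abundance-weighted mean is available via `weighted = TRUE`. Breadths are
computed over all samples jointly, treating each sample as one resource
state.

# Diversity and permutation tests

Alpha diversity uses the estimators' textbook forms on raw integer
counts: observed richness; bias-corrected Chao1
$S + F_1(F_1-1)/(2(F_2+1))$ (the classic $S + F_1^2/(2F_2)$ via a flag);
ACE with the conventional rare/abundant cutoff of 10; Shannon with the
natural logarithm. Chao1 is implemented directly rather than through
`vegan::estimateR()` because the latter applies an additional
$(n-1)/n$ small-sample factor; the suite cross-checks Shannon against
vegan exactly. Whether to rarefy first is left to the user
(`rarefy_table()`); all analyses default to raw counts.

Bray–Curtis, PERMANOVA (Anderson's pseudo-F via `vegan::adonis2`), ANOSIM
and the Kruskal–Wallis test wrap the standard implementations, with
permutation p-values on the $(1 + \#\{ \mathrm{perm} \ge \mathrm{obs}\})
/(1 + n_{\mathrm{perm}})$ estimator so $p \ge 1/(n_{\mathrm{perm}}+1)$
always. The acceptance suite verifies type-I error within $[0.03, 0.07]$
at $\alpha = 0.05$ over 500 exchangeable replicates for PERMANOVA,
ANOSIM, Mantel, and partial Mantel. The "beta-diversity index" compared
across groups is the multiset of within-group pairwise Bray–Curtis
distances (a distance-to-centroid variant is available).

Mantel association uses Pearson correlation of distance-matrix upper
triangles with a one-sided (greater) permutation test — the direction in
which community–environment association is expected. "Distance-corrected"
community–environment association is a partial Mantel with the haversine
great-circle distance matrix (Earth radius 6371 km) partialled out;
environmental distance is Euclidean on z-standardized covariates (units
are heterogeneous — PSU, °C, mg/l — so standardization is not optional).
A constant control matrix shares no variance with anything and reduces
the partial test to the simple one.

# Co-occurrence networks

The meta-community network is built on the top-k taxa by summed relative
abundance (k = 500 by default; ties broken toward the lexicographically
smaller identifier). Spearman correlations use midranks; two-sided
p-values come from the t-approximation on $n-2$ degrees of freedom —
accurate at 75 samples and fast enough for the 124,750 pairs of a
500-taxon run — and a single Benjamini–Hochberg adjustment covers all
tested pairs (one network is built; subnetworks are extracted, not
re-tested). Edges require $|r| > 0.7$ and adjusted $p < 0.01$. Taxa with
constant abundance have undefined rank correlations and are skipped with
a warning; taxa left without edges do not become nodes.

Topology follows the field's conventions: average degree $2E/V$, density,
clustering coefficient as the mean local transitivity over nodes of
degree ≥ 2, average path length and diameter on the largest connected
component (the graph may be disconnected), Freeman degree and betweenness
centralization (1 on a star, 0 on vertex-transitive graphs), and the
modularity of a multi-level greedy (Louvain) partition computed on the
unsigned graph with a fixed internal seed for reproducibility. Edge signs
are kept as attributes and reported as the positive-edge fraction, but
topology is computed on the unsigned graph. Group subnetworks are the
induced subgraphs on taxa with nonzero abundance in the group's samples.

# The synthetic-community generator

The generator exists so that every inference stage can be tested against
data whose generating process is known. `generate_study_layout()` emits a
75-sample survey — 15 sites × 5 habitat groups (`Sur_FL`, `Sur_PA`,
`Bot_FL`, `Bot_PA`, `Sed`) — from one shared Yule phylogeny and one
lognormal metacommunity (meanlog 0, sdlog 1.5: the top decile of taxa
holds over half the mass, a realistic rank-abundance shape). Default
sizes (400 taxa, N = 5000 individuals per sample; 300 taxa in the
canonical single regimes) keep 999-randomization null models in the
minutes range on one CPU.

The four canonical regimes (`simulate_regime()`):

* **neutral** — independent Sloan chains, $m = 0.3$.
* **dispersal_limited** — each site draws from a site-specific pool made
  by re-weighting the metacommunity with spatially autocorrelated
  log-Gaussian noise (correlation $e^{-d/\text{scale}}$ on haversine
  distances; 50 km default against ~100–400 km site spacings), so nearby
  sites share pools and Bray–Curtis increases with distance.
* **heterogeneous_selection** — Gaussian environmental filtering,
  $w \propto p\,e^{-(E-t)^2/2\sigma^2}$, on a Brownian trait (root 0,
  variance = branch length), with sample environments spread over
  $[-4, 4]$ and $\sigma = 0.5$: different samples select different
  lineages, betaNTI goes strongly positive.
* **homogeneous_selection** — an identical environment across samples
  admitting only a ~30-taxon *specialist clade* (a perfectly conserved
  habitat-suitability trait) with Gaussian filtering on the within-clade
  trait, colonization dropout 0.5 and lognormal abundance noise (SD 1)
  supplying the drift that real filtered communities carry.

The clade-based suitability trait in the homogeneous regime deserves a
note, because the obvious simpler design does not work and the reason is
scientific, not numerical. A Gaussian band on a Brownian trait is *not*
phylogenetically clustered at a 300-taxon pool: independent deep lineages
converge onto any trait value (the mean within-band phylogenetic distance
stays near the pool mean), so communities filtered that way never become
clustered enough for betaNTI to call homogeneous selection, no matter how
strong the filter. Nearest-taxon clustering also needs community richness
well below the pool size and genuine taxon turnover between samples —
hence the dropout and abundance noise, which emulate establishment
stochasticity around a consistent filter. With the clade-level trait the
regime is recovered at a homogeneous-selection fraction of 0.85–0.97
across seeds; with identical environments the heterogeneous machinery,
run at face value, yields fractions near zero. Habitat specialism as a
clade-conserved trait is also the more realistic model: sediment
specialists in marine surveys are recognizable clades, not arbitrary
collections of convergent lineages.

In the study layout, the surface and bottom-PA groups are
dispersal-limited (decay 75 and 50 km), `Bot_FL` is neutral
($m = 0.15$, drift-heavy), and `Sed` is the homogeneous-selection regime.
Metadata carries coordinates and synthetic covariates (temperature with a
latitudinal trend, salinity with a longitudinal trend, lognormal
nitrate); sediment covariates are missing, as is typical when only water
casts are instrumented.

**What the generator does not emulate.** Sequencing noise (PCR bias,
chimeras, variable library depth), taxonomic mis-assignment, phylogenetic
uncertainty, temporal dynamics, and genuine species interactions are all
absent. Passing tests on these data therefore show that the *inference
machinery* is correct and recovers known regimes — not that any
particular field dataset satisfies the models' assumptions. In
particular, the co-occurrence networks of synthetic data are much sparser
than those of real surveys, because the generator induces correlation
only through shared pools and shared filters, not through interactions.
The layout also makes no attempt to reproduce observed alpha-diversity
orderings between habitats: its sediment group is a narrow specialist
community by design.

# Numerical choices and degenerate inputs

* Permutations for betaNTI are generated in R (so one seed reproduces
  every null exactly) and consumed by compiled code; the per-pair null
  mean and SD use the unbiased variance over the 999 draws.
* Null SDs below $10^{-12}$ are treated as zero (degenerate pair).
* RC equality tolerance is $10^{-10}$ on Bray–Curtis values.
* Relative-abundance columns must sum to 1 within $10^{-12}$.
* Identifier matching is exact and case-sensitive everywhere; taxa absent
  from the tree are dropped with a logged count before phylogenetic
  computation (betaMNTD is undefined for them).
* All-zero taxa are allowed in tables (they are reported, and they
  legitimately enlarge the betaNTI shuffle pool) but excluded from niche
  breadths with a warning; zero-total samples are rejected outright.
* ACE is undefined when every rare taxon is a singleton (sample coverage
  0); the estimator returns `NA` for such samples.
* Kruskal–Wallis on all-tied data returns $H = 0$, $p = 1$ by convention
  rather than 0/0.
* `ncm_fit()` refuses fewer than 10 samples, fewer than 20 non-empty
  taxa, and data where every taxon is at frequency 1 (the occupancy curve
  then carries no information).

# Problem sizes used by the test suite

The acceptance tests run the methods at the sizes the package targets:
regime recovery at 300 taxa, N = 5000, 15 samples per group, 999
randomizations, five seeds per regime; neutral-model recovery at 200
samples of N = 1000 over ten seeds for each $m \in \{0.05, 0.1, 0.5\}$;
permutation-test calibration over 500 replicates; and end-to-end
determinism on the 75-sample layout at 200 taxa with 199
randomizations. The full default pipeline (400 taxa, 999 randomizations,
999 permutations) completes in a few minutes on one CPU; `run_pipeline()`
writes a JSON report that is byte-identical across runs with the same
configuration.

# Known limitations

* The five-way classification is community-level; per-taxon (bin-based)
  partitioning is out of scope.
* The betaNTI null assumes exchangeable tips given the pool; strong
  phylogenetic signal in *abundances themselves* (not just presence)
  under neutrality would mildly inflate type-I selection calls.
* RC_bray inherits Bray–Curtis's sensitivity to sampling depth; the
  reassembly preserves each sample's total count, which compensates only
  partially when depths are very uneven. Rarefaction is available but off
  by default.
* The Sloan model assumes a single well-mixed metacommunity per fitted
  group; fitting across strongly structured habitats mixes migration
  scales and will depress $R^2$ (which is exactly how the fit is used
  diagnostically).
* Spearman-based networks on relative abundances carry compositional
  bias; compositionality-aware estimators are deliberately out of scope
  because rank correlation is the convention this package implements.
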