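---
title: "Partitioning community assembly into selection and stochasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning community assembly into selection and stochasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question and the model

Host-associated microbial communities assemble from an environmental
source pool through dispersal, selection, and ecological drift. For a 16S
ASV table with an accompanying phylogeny, the package quantifies the
balance between selection and stochasticity with two standardized
nearest-taxon statistics.

For one community, the mean nearest taxon distance

$$\mathrm{MNTD} = \sum_{t \in \text{present}} w_t \min_{u \neq t} d(t, u)$$

averages each taxon's cophenetic distance to its closest co-occurring
relative ($w_t = 1/S$ unweighted, or the relative abundance). For a pair
of communities, βMNTD replaces "closest co-occurring relative" with
"closest taxon of the *other* community" (a taxon shared by both sits at
distance zero) and averages the two directions.

Both observed values are standardized against a *taxa-labels* null: the
taxon labels of the cophenetic matrix — equivalently the tips of the tree
— are shuffled within a metacommunity pool, and the statistic is
recomputed under each of `runs` shuffles (999 by default; pools of at
most eight taxa can be enumerated exhaustively with `exhaustive = TRUE`).
Then

$$\mathrm{NTI} = -\frac{\mathrm{MNTD}_{obs} - \overline{\mathrm{MNTD}}_{null}}{\mathrm{sd}(\mathrm{MNTD}_{null})},
\qquad
\beta\mathrm{NTI} = \frac{\beta\mathrm{MNTD}_{obs} - \overline{\beta\mathrm{MNTD}}_{null}}{\mathrm{sd}(\beta\mathrm{MNTD}_{null})}.$$

Note the sign convention: NTI is the *negative* z-score, so clustered
communities (observed MNTD below the null) score positive; NTI > 2 is
read as selection, NTI < −2 as overdispersion. βNTI keeps the plain
z-score: per pair, βNTI > 2 means phylogenetic turnover exceeds the null
(heterogeneous selection), βNTI < −2 means turnover below the null
(homogeneous selection), and values in between — boundaries included,
since the decision rules are strict inequalities — are attributed to
stochastic processes. A degenerate null (zero variance, e.g. a community
containing the whole pool, or two identical communities whose βMNTD is
zero under every shuffle) is reported as `NA` with class `"undefined"`
rather than forced into a category.

The null-model machinery assumes niche-related traits carry phylogenetic
signal; `mantel_correlogram()` checks this by correlating niche distances
with cophenetic distance classes (equal-width classes, permutation
p-values, progressive Holm correction, via `vegan::mantel.correlog`).

## Null pools

Two pool conventions are in use in the field and both are supported. The
per-group convention restricts the pool to the taxa observed in the
samples being compared (`beta_nti()`'s default, matching per-group runs
of qpen-style tools). The one-metacommunity convention uses every taxon
in the analyzed table; since all samples in the emulated design are
colonized from one water source, `run_pipeline()` and
`process_recovery()` pass the whole filtered table as `null_pool` to both
`nti()` and `beta_nti()`. The choice matters: against a per-group pool,
group-level selection is partly absorbed into the pool itself and
within-group βNTI loses contrast, which is why the pipeline prefers the
whole-table pool. Both are explicit arguments.

## Abundance weighting

`nti()` is unweighted by default (the classical presence-based index);
`beta_nti()` is abundance-weighted by default (the common convention for
between-sample turnover). Both expose `weighted` flags.

# QC and normalization choices

* `filter_min_reads()` reads "fewer than 8 reads in all samples" as a
  *total* across samples (threshold 8, the usual denoiser
  recommendation); `mode = "per_sample_max"` offers the stricter
  per-sample reading.
* `subtract_control_asvs()` removes every taxon observed in a negative
  control unless its summed control reads stay below `control_read_cap`
  (4) *and* its mean relative abundance across biological samples reaches
  `abundance_floor` (0.1%) — the exception that keeps genuinely abundant
  taxa which leak into controls at trace level. The cap applies to reads
  summed over all controls.
* `normalize_scaling()` converts each sample to fractions, multiplies by
  the target depth (11 000) and rounds half-up (`"banker"` rounding
  available). Column sums are left within `ceiling(n_taxa/2)` of the
  target rather than repaired, so each taxon's relative abundance is
  preserved to within half a read.
* `drop_taxa()` covers curated exclusions (e.g. host-gene ASVs
  identified upstream), supplied by id.
* Rooting follows the longest-branch rule: the root is placed at the
  midpoint of the longest branch (ties broken by edge order, with a
  message). Rooting never changes cophenetic distances, which is tested.

# The synthetic-data generator

`generate_experiment()` emulates the study design the package targets: a
2 × 2 factorial (water treatment × host strain) with 4 replicate flasks
per cell, 4 individual gut samples and 1 rearing-water sample per flask
(64 + 16), repeated added-water samples (2 treatments × 4 days), and 2
negative controls carrying sparse contamination, all sequenced to 11 000
reads.

Its generative model, from the tree down:

1. **Phylogeny.** A Yule backbone of `n_species = 50` populations
   (`birth_rate = 1`), each expanded by `expand_microdiversity()` into a
   terminal cluster of near-identical ASVs (pendant edges of scale
   `cluster_depth = 0.02` against a backbone height of roughly 4–5).
   This two-scale structure mirrors real zOTU tables, where denoising
   resolves clusters of strain-level sequence variants; it is what
   separates the distance scale of within-population taxon replacement
   from the scale of random tip sets, and without it nearest-taxon
   z-scores cannot move far from zero at these community sizes.
2. **Niche traits.** Brownian motion with an early-burst rate decay
   (`bm_rate = 1`, `eb_rate = 1`): the trait rate declines as
   exp(−`eb_rate`·t) with time from the root, concentrating divergence
   in deep branches. This is the standard niche-conservatism model and
   makes clades, not scattered single tips, the units that a filter
   selects; with plain Brownian motion (`eb_rate = 0`) sister tips
   differ by more than any useful filter width and selection picks
   convergent tips all over the tree.
3. **Metacommunity.** Log-normal abundances at the cluster level
   (`meta_sdlog = 0.5`) times a flatter within-cluster strain profile
   (`strain_sdlog = 0.4`).
4. **Selection.** A Gaussian filter
   $w_t \propto m_t \exp(-(z_t - \mathrm{env})^2 / 2\sigma^2)$ with
   width `selection_width = 0.25` × the realized trait standard
   deviation. Optima are placed where the filter passes a target
   fraction of metacommunity mass (`target_band_mass = 0.2`), which
   keeps selectivity comparable across tree realizations: one shared
   optimum under homogeneous selection; one per water treatment, on
   opposite flanks of the trait median and at least
   `env_separation = 3` σ apart, under heterogeneous selection; no
   filter under `neutral`.
5. **Founder effects and drift.** Each flask draws a founder community
   by two-stage Dirichlet drift: cluster level (`flask_theta = 30`;
   which populations establish) and strain level (`strain_theta = 0.3`;
   which one or two variants of an established population dominate).
   Each gut sample then drifts again within its flask
   (`drift_theta = 60`) after receiving a trace immigrant tail
   (`dispersal_mix = 0.002` of the unfiltered metacommunity — mass
   effects), and reads are drawn multinomially. Strain-level founder
   turnover is what gives replicate communities the low ASV-level
   overlap seen in real individuals while populations coincide.
6. **Water samples.** Rearing water is sampled from a strain-rich
   mixture of the flask community and the full selection profile
   (`rw_strain_mix = 0.45`) under weak drift (`rw_theta = 300`) — water
   is far less bottlenecked than a gut and correspondingly denser and
   more clustered. Added water is a neutral draw from a mixture of the
   shared metacommunity and a treatment-specific second metacommunity
   (`aw_mix = 0.5`), which keeps the whole-table null pool
   phylogenetically broad.

All randomness derives from `master_seed`; identical configurations give
byte-identical outputs.

## What the generator does and does not emulate

It emulates: the factorial design and sample counts, sequencing depth,
microdiversity, phylogenetically conserved niches, founder effects at
flask and individual level, mass-effect immigrant tails, dense water
communities, and low-level control contamination. It does not emulate:
taxonomy, chimeras or other denoising artefacts, temporal dynamics of
the water exchanges, r/K growth kinetics, host feedback, or
compositional sequencing biases. Passing recovery tests therefore show
that the statistics detect the processes *as modelled*; on real data the
same statistics additionally face unmodelled noise sources.

## Choice of the validation conditions

`process_recovery()` runs the full chain (QC → normalization → rooting →
cophenetic → NTI/βNTI with the whole-table pool) on one generated
experiment. The package validates recovery over master seeds 1–10 at 199
null permutations — sizes at which the whole battery runs in a few
minutes while estimating classification fractions over 496 pairs per
group to a few percent. Under these conditions homogeneous-selection
scenarios give a plurality of homogeneous-selection pair classifications
in 10/10 seeds and mean NTI (gut + rearing water) above 2 in 8/10;
heterogeneous scenarios give a plurality of heterogeneous classifications
among cross-treatment pairs in 10/10; neutral scenarios give at least
60% stochastic pairs and |mean NTI| < 2 in 10/10. The NTI margin is the
tightest of these: individual gut communities sit near the NTI = 2 line
(their per-sample founder bottleneck genuinely erodes clustering), and
the threshold is cleared jointly by the gut and the denser rearing-water
samples, mirroring the empirical pattern that water communities show far
stronger clustering than individual guts.

# Numerical conventions

* Permutation p-values use (1 + exceedances) / (1 + permutations).
* PERMANOVA permutes labels freely (one-way, no strata); with tight,
  well-separated groups the attainable minimum p is limited by label
  permutations that recreate the same partition.
* SIMPER per-pair contributions are defined so they sum exactly to that
  pair's Bray–Curtis dissimilarity.
* Chao1 uses the bias-corrected form S + F1(F1−1)/(2(F2+1)) by default;
  the classic form is a flag.
* PCoA reports negative eigenvalues instead of silently dropping them;
  a Lingoes correction is optional. Axes are scaled by the square root
  of their (positive) eigenvalues.
* The tip-shuffle null applies *one* permutation per run to the whole
  table, so shared taxa remain shared under the null — identical
  communities are a degenerate case by design, not a strongly negative
  one.
* Exhaustive enumeration is limited to pools of ≤ 8 taxa (8! = 40 320
  permutations).

# Limitations

* βNTI classifications near the ±2 thresholds are sensitive to the
  number of null permutations; use ≥ 199 for classification and 999 for
  reported values.
* The stochastic fraction is not split further (e.g. into dispersal
  limitation vs homogenizing dispersal); doing so requires a
  taxonomic-turnover null (RC-Bray) outside this package's scope.
* With strongly clade-restricted tables and per-group pools, within-group
  βNTI loses power against homogeneous selection; prefer the whole-table
  pool when a one-metacommunity assumption is defensible.
* The generator's defaults describe one realistic operating point of a
  rearing experiment; they are not fitted to any particular data set.
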