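# asvassembly

Community-assembly analysis for 16S amplicon sequence variant (ASV / zOTU)
tables, built around the study design of gnotobiotic fish rearing
experiments: individual gut samples and rearing-water samples from
replicate flasks under a two-factor design (microbial water treatment x
host strain), plus repeated samples of the added source water and negative
controls.

The package asks the central question of microbial community ecology — how
much of a community's composition is shaped by deterministic selection and
how much by stochastic processes (drift, founder effects) — and answers it
with phylogenetic null models, surrounded by the standard QC and diversity
stages such studies need:

* **Table QC**: removal of low-support ASVs (fewer than 8 reads by
  default), negative-control contaminant subtraction with an abundance
  exception for genuine taxa that leak into controls at trace level, and
  total-count scaling normalization to a common depth (11 000 reads by
  default).
* **Diversity**: observed richness *S*, Chao1, the Hill number of order
  one (exponential Shannon diversity, e^H), evenness e^H/S; Bray–Curtis
  dissimilarity; principal coordinates analysis (PCoA); one-way PERMANOVA;
  SIMPER; data-driven two-group testing (Shapiro–Wilk → Wilcoxon, or
  F-test → Welch/Student *t*); shared-ASV fractions between sample sets.
* **Phylogenetics**: Newick I/O, rooting at the midpoint of the longest
  branch, cophenetic distances, and a Mantel correlogram verifying the
  phylogenetic signal that licenses nearest-taxon null models.
* **Null models (the core)**: the nearest taxon index and its
  between-sample analogue,

  NTI = −(MNTD_obs − mean MNTD_null) / sd MNTD_null,
  βNTI = (βMNTD_obs − mean βMNTD_null) / sd βMNTD_null,

  where MNTD is the (optionally abundance-weighted) mean distance from
  each taxon to its nearest co-occurring relative, βMNTD the two-community
  analogue, and the null shuffles taxon labels across the tips of the
  phylogeny restricted to a metacommunity pool ("taxa labels" null, 999
  permutations by default, with an exact enumeration mode for small
  pools). NTI > 2 indicates phylogenetic clustering (selection); per
  sample pair, βNTI > 2 indicates heterogeneous selection, βNTI < −2
  homogeneous selection, and |βNTI| ≤ 2 stochastic assembly.
* **Synthetic data**: a generator that assembles communities on a
  simulated phylogeny under *known* processes — homogeneous selection,
  heterogeneous selection, or neutral drift — so that every stage of the
  pipeline can be validated against ground truth. Communities are built
  from a Yule backbone tree expanded into microdiversity clusters of
  near-identical ASVs, early-burst (conserved) niche traits, a Gaussian
  environmental filter, hierarchical founder drift (flask level and
  sample level), and multinomial read sampling.

## Worked example

Generate a synthetic experiment assembled under homogeneous selection,
apply QC, and ask the null models which process shaped it:

```r
library(asvassembly)

cfg <- scenario_config(process = "homogeneous_selection", master_seed = 3)
ex  <- generate_experiment(cfg)
ex$table
#> count_table: 200 taxa x 90 samples; total reads 968,017

md       <- ex$metadata
controls <- md$sample_id[md$sample_type == "negative_control"]
tab <- normalize_scaling(filter_min_reads(
         subtract_control_asvs(ex$table, controls), 8))
tab
#> count_table: 193 taxa x 88 samples; total reads 967,963

tree <- root_longest_branch(ex$tree)
d    <- cophenetic_distances(tree)
gut  <- md$sample_id[md$sample_type == "gut"]
rw   <- md$sample_id[md$sample_type == "rearing_water"]

res <- nti(ct_subset(tab, samples = c(gut, rw)), d, runs = 199, seed = 3,
           null_pool = taxon_ids(tab))
mean(res$nti[res$sample_id %in% gut])  # 2.86
mean(res$nti[res$sample_id %in% rw])   # 3.78

trt <- setNames(md$water_treatment, md$sample_id)
bn  <- beta_nti(tab, d, runs = 199, seed = 3,
                samples = gut[trt[gut] == "Add-r"],
                null_pool = taxon_ids(tab))
summarize_processes(bn)
#>   group n_pairs frac_heterogeneous_selection frac_homogeneous_selection
#> 1   all     496                      0.00403                      0.841
#>   frac_stochastic frac_undefined
#> 1           0.155              0
```

Both readouts recover the generating process: mean NTI above 2 says the
communities are more phylogenetically clustered than chance (selection
acted), and 84% of the 496 within-group sample pairs classify as
homogeneous selection (shared environment, low phylogenetic turnover).
Under a `"neutral"` scenario the same pipeline classifies the large
majority of pairs as stochastic, and under `"heterogeneous_selection"`
the cross-treatment pairs classify as heterogeneous selection.

`run_pipeline(run_config(scenario = cfg, output_dir = "out"))` wraps all
of the above (plus alpha/beta diversity, PCoA, PERMANOVA, SIMPER,
shared-ASV fractions, and the Mantel correlogram) into a deterministic
tab-separated report bundle with a manifest of every effective parameter.
Real data enter through `read_count_table()`, `read_sample_metadata()`
and `read_newick_file()` in place of the scenario.

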