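#' Ground-truth recovery experiment for one assembly process
#'
#' Generates a full synthetic experiment under a known process, pushes it
#' through the standard analysis chain (negative-control subtraction,
#' low-abundance filter, depth normalization, longest-branch rooting,
#' cophenetic distances), and measures how well the null models recover the
#' generating process: NTI over gut and rearing-water samples against the
#' whole-table metacommunity pool, and betaNTI process classifications for
#' within-group gut pairs (plus cross-environment gut pairs under
#' heterogeneous selection), also against the whole-table pool.
#'
#' @param process assembly process handed to [scenario_config()].
#' @param master_seed master seed of the synthetic experiment; also seeds
#'   the null models.
#' @param runs null-model permutations (default 199).
#' @param ... further arguments to [scenario_config()].
#' @return a one-row data.frame: `process`, `master_seed`, `mean_nti`
#'   (gut + rearing water), `mean_nti_gut`, `mean_nti_rw`,
#'   `frac_homogeneous`, `frac_stochastic`, `frac_heterogeneous` (within
#'   one treatment's gut group), and for heterogeneous selection
#'   `frac_heterogeneous_cross` / `frac_stochastic_cross` over
#'   cross-treatment gut pairs (otherwise `NA`).
#' @export
process_recovery <- function(process, master_seed, runs = 199, ...) {
  cfg <- scenario_config(process = process, master_seed = master_seed, ...)
  ex <- generate_experiment(cfg)
  md <- ex$metadata
  controls <- md$sample_id[md$sample_type == "negative_control"]
  tab <- ex$table
  if (length(controls)) tab <- subtract_control_asvs(tab, controls)
  tab <- normalize_scaling(filter_min_reads(tab, 8), cfg$read_depth)
  d <- cophenetic_distances(root_longest_branch(ex$tree))
  md <- md[match(sample_ids(tab), md$sample_id), ]
  gut <- md$sample_id[md$sample_type == "gut"]
  rw <- md$sample_id[md$sample_type == "rearing_water"]
  trt <- stats::setNames(md$water_treatment, md$sample_id)
  pool <- taxon_ids(tab)

  nt <- nti(ct_subset(tab, samples = c(gut, rw)), d, runs = runs,
            seed = master_seed, null_pool = pool)
  g1 <- gut[trt[gut] == cfg$treatments[1]]
  bn <- beta_nti(tab, d, runs = runs, seed = master_seed, samples = g1,
                 null_pool = pool)
  out <- data.frame(
    process = process, master_seed = master_seed,
    mean_nti = mean(nt$nti, na.rm = TRUE),
    mean_nti_gut = mean(nt$nti[nt$sample_id %in% gut], na.rm = TRUE),
    mean_nti_rw = mean(nt$nti[nt$sample_id %in% rw], na.rm = TRUE),
    frac_homogeneous = mean(bn$process == "homogeneous_selection"),
    frac_stochastic = mean(bn$process == "stochastic"),
    frac_heterogeneous = mean(bn$process == "heterogeneous_selection"),
    frac_heterogeneous_cross = NA_real_,
    frac_stochastic_cross = NA_real_,
    stringsAsFactors = FALSE)
  if (process == "heterogeneous_selection") {
    bnx <- beta_nti(tab, d, runs = runs, seed = master_seed, samples = gut,
                    null_pool = pool)
    cross <- trt[bnx$sample_1] != trt[bnx$sample_2]
    out$frac_heterogeneous_cross <-
      mean(bnx$process[cross] == "heterogeneous_selection")
    out$frac_stochastic_cross <- mean(bnx$process[cross] == "stochastic")
  }
  out
}
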