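#' Remove low-abundance taxa
#'
#' Drops ASVs whose read support across the table falls below a threshold,
#' the standard guard against denoising artefacts. Two readings of "fewer
#' than `threshold` reads in all samples" are offered: `total` sums counts
#' over samples (the default, matching the total-abundance recommendation of
#' common denoising pipelines), `per_sample_max` requires at least one single
#' sample to reach the threshold.
#'
#' @param table a `count_table`.
#' @param threshold minimum read support (default 8).
#' @param mode `"total"` or `"per_sample_max"`.
#' @return a `count_table` with the same samples and the surviving taxa,
#'   counts unchanged.
#' @export
filter_min_reads <- function(table, threshold = 8,
                             mode = c("total", "per_sample_max")) {
  mode <- match.arg(mode)
  stopifnot(threshold >= 0)
  m <- ct_counts(table)
  support <- switch(mode,
                    total = rowSums(m),
                    per_sample_max = apply(m, 1, max))
  ct_replace(table, m[support >= threshold, , drop = FALSE])
}

#' Remove putative contaminants using negative controls
#'
#' Any taxon observed in a negative control is treated as a contaminant and
#' removed, with one exception: taxa that are genuinely abundant in the
#' biological samples but leaked into the controls at trace level (summed
#' control reads below `control_read_cap` and mean relative abundance across
#' non-control samples at least `abundance_floor`) are kept. Control samples
#' themselves are dropped from the output.
#'
#' @param table a `count_table` containing the control samples.
#' @param control_sample_ids ids of the negative-control samples.
#' @param control_read_cap taxa with this many or more summed control reads
#'   are always removed (default 4, i.e. the exception requires < 4 reads).
#' @param abundance_floor minimum mean relative abundance across biological
#'   samples for the exception to apply (default 0.001).
#' @return a `count_table` without control samples or contaminant taxa.
#' @export
subtract_control_asvs <- function(table, control_sample_ids,
                                  control_read_cap = 4,
                                  abundance_floor = 0.001) {
  m <- ct_counts(table)
  missing <- setdiff(control_sample_ids, colnames(m))
  if (length(missing))
    stop("unknown control sample ids: ", paste(missing, collapse = ", "))
  bio <- setdiff(colnames(m), control_sample_ids)
  if (!length(bio)) stop("no biological samples left after removing controls")
  ctrl <- m[, control_sample_ids, drop = FALSE]
  ctrl_reads <- rowSums(ctrl)
  biom <- m[, bio, drop = FALSE]
  totals <- colSums(biom)
  rel <- sweep(biom, 2, pmax(totals, 1), "/")
  mean_rel <- rowMeans(rel)
  contaminated <- ctrl_reads > 0
  excepted <- contaminated & ctrl_reads < control_read_cap &
    mean_rel >= abundance_floor
  keep <- !contaminated | excepted
  ct_replace(table, biom[keep, , drop = FALSE])
}

#' Drop a curated list of taxa by id
#'
#' Covers manual exclusions such as non-bacterial ASVs matching host genes,
#' identified upstream by inspection and supplied by id.
#'
#' @param table a `count_table`.
#' @param taxa character vector of taxon ids to remove; ids absent from the
#'   table are an error to guard against typos.
#' @return a `count_table`.
#' @export
drop_taxa <- function(table, taxa) {
  m <- ct_counts(table)
  missing <- setdiff(taxa, rownames(m))
  if (length(missing))
    stop("unknown taxon ids: ", paste(missing, collapse = ", "))
  ct_replace(table, m[setdiff(rownames(m), taxa), , drop = FALSE])
}

## round half away from zero (counts are nonnegative, so half up)
round_half_up <- function(x) floor(x + 0.5)

#' Normalize samples to a common read depth by fraction scaling
#'
#' Converts each sample to relative abundances, multiplies by the target
#' depth, and rounds to integers. Column sums are left as rounding produces
#' them (within `ceiling(n_taxa/2)` of the target) rather than repaired, so
#' relative abundances are preserved to within half a read per taxon.
#'
#' @param table a `count_table`; every sample must have at least one read.
#' @param depth target reads per sample (default 11000).
#' @param rounding `"half_up"` (default) or `"banker"` (round-half-even).
#' @return a `count_table` at the common depth.
#' @export
normalize_scaling <- function(table, depth = 11000,
                              rounding = c("half_up", "banker")) {
  rounding <- match.arg(rounding)
  stopifnot(depth >= 1)
  m <- ct_counts(table)
  totals <- colSums(m)
  if (any(totals == 0))
    stop("all-zero sample(s): ",
         paste(colnames(m)[totals == 0], collapse = ", "))
  scaled <- sweep(m, 2, totals, "/") * depth
  out <- if (rounding == "half_up") round_half_up(scaled) else round(scaled)
  ct_replace(table, out)
}
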