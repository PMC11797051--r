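#' Configure an end-to-end pipeline run
#'
#' A run either reads a count table, metadata table, and Newick tree from
#' disk, or generates them from a [scenario_config()]. All tunable
#' parameters and the seed are echoed into the run manifest so any output
#' can be reproduced from the manifest alone.
#'
#' @param table_path,metadata_path,tree_path input files (tab-separated
#'   table and metadata, Newick tree); ignored when `scenario` is given.
#' @param scenario optional [scenario_config()] for a synthetic run.
#' @param output_dir directory for the report bundle (created if needed).
#' @param min_reads,min_reads_mode low-abundance filter (see
#'   [filter_min_reads()]).
#' @param control_read_cap,abundance_floor negative-control filter (see
#'   [subtract_control_asvs()]).
#' @param drop_taxa_ids optional curated ids to remove before filtering.
#' @param depth normalization depth (see [normalize_scaling()]).
#' @param nti_runs,bnti_runs null-model permutations.
#' @param nti_weighted,bnti_weighted abundance weighting of the null models.
#' @param n_perm PERMANOVA permutations.
#' @param prune_to_intersection if `TRUE`, taxa missing from the tree are
#'   dropped (with counts logged) instead of raising an error.
#' @param seed master seed for every stochastic step.
#' @return a list of class `run_config`.
#' @export
run_config <- function(table_path = NULL, metadata_path = NULL,
                       tree_path = NULL, scenario = NULL,
                       output_dir = "asvassembly_run",
                       min_reads = 8, min_reads_mode = "total",
                       control_read_cap = 4, abundance_floor = 0.001,
                       drop_taxa_ids = character(),
                       depth = 11000, nti_runs = 999, bnti_runs = 999,
                       nti_weighted = FALSE, bnti_weighted = TRUE,
                       n_perm = 9999, prune_to_intersection = FALSE,
                       seed = 1) {
  if (is.null(scenario) &&
      (is.null(table_path) || is.null(metadata_path) || is.null(tree_path)))
    stop("provide either a scenario or all three input paths")
  structure(list(table_path = table_path, metadata_path = metadata_path,
                 tree_path = tree_path, scenario = scenario,
                 output_dir = output_dir, min_reads = min_reads,
                 min_reads_mode = min_reads_mode,
                 control_read_cap = control_read_cap,
                 abundance_floor = abundance_floor,
                 drop_taxa_ids = drop_taxa_ids, depth = depth,
                 nti_runs = nti_runs, bnti_runs = bnti_runs,
                 nti_weighted = nti_weighted, bnti_weighted = bnti_weighted,
                 n_perm = n_perm,
                 prune_to_intersection = prune_to_intersection,
                 seed = as.integer(seed)),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full community-assembly pipeline
#'
#' Applies QC (negative-control subtraction, low-abundance filter) and
#' depth normalization, roots the tree at its longest branch, computes
#' cophenetic distances, and writes a deterministic report bundle: alpha
#' diversity, Bray-Curtis matrices, PCoA, one-way PERMANOVA contrasts
#' (strain among guts, water treatment among guts, gut vs rearing water),
#' SIMPER for the water-treatment contrast, per-gut-sample shared-ASV
#' fractions against the water communities, a Mantel correlogram of
#' phylogenetic signal, NTI per sample, betaNTI per sample group
#' (gut / rearing water x water treatment), and the assembly-process
#' summary. Reruns with the same config and seed are byte-identical.
#'
#' @param config a [run_config()].
#' @return invisibly, a list of the in-memory results plus `files`, the
#'   written paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  if (!is.null(config$scenario)) {
    note("input: synthetic scenario, process = ", config$scenario$process,
         ", master_seed = ", config$scenario$master_seed)
    exp <- generate_experiment(config$scenario)
    table <- exp$table; metadata <- exp$metadata; tree <- exp$tree
    write_count_table(table, out("input_count_table.tsv"))
    write_sample_metadata(metadata, out("input_metadata.tsv"))
    writeLines(write_newick(tree), out("input_tree.nwk"))
    write_truth_manifest(exp$truth, out("truth.txt"))
  } else {
    note("input: files ", config$table_path)
    table <- read_count_table(config$table_path)
    metadata <- read_sample_metadata(config$metadata_path)
    tree <- read_newick_file(config$tree_path)
  }

  extra <- setdiff(sample_ids(table), metadata$sample_id)
  if (length(extra))
    stop("samples missing from metadata: ", paste(extra, collapse = ", "))
  metadata <- metadata[match(sample_ids(table), metadata$sample_id), ]

  ## ---- QC and normalization ----
  if (length(config$drop_taxa_ids)) {
    table <- drop_taxa(table, config$drop_taxa_ids)
    note("dropped ", length(config$drop_taxa_ids), " curated taxa")
  }
  controls <- metadata$sample_id[metadata$sample_type == "negative_control"]
  if (length(controls)) {
    before <- nrow(ct_counts(table))
    table <- subtract_control_asvs(table, controls,
                                   config$control_read_cap,
                                   config$abundance_floor)
    metadata <- metadata[!metadata$sample_id %in% controls, ]
    note("negative-control filter: ", before - nrow(ct_counts(table)),
         " taxa removed using ", length(controls), " controls")
  }
  before <- nrow(ct_counts(table))
  table <- filter_min_reads(table, config$min_reads, config$min_reads_mode)
  note("low-abundance filter (", config$min_reads_mode, " < ",
       config$min_reads, "): ", before - nrow(ct_counts(table)),
       " taxa removed, ", nrow(ct_counts(table)), " kept")
  table <- normalize_scaling(table, config$depth)
  note("normalized to ", config$depth, " reads per sample")

  ## ---- tree handling ----
  missing_tips <- setdiff(taxon_ids(table), tree$tip.label)
  if (length(missing_tips)) {
    if (!config$prune_to_intersection)
      stop("taxa absent from the tree: ",
           paste(missing_tips, collapse = ", "))
    table <- ct_subset(table, taxa = intersect(taxon_ids(table),
                                               tree$tip.label))
    note("pruned ", length(missing_tips), " taxa absent from the tree")
  }
  tree <- root_longest_branch(tree)
  note("tree rooted at the midpoint of its longest branch")
  phylo_d <- cophenetic_distances(tree)

  md <- metadata
  gut <- md$sample_id[md$sample_type == "gut"]
  rw <- md$sample_id[md$sample_type == "rearing_water"]
  aw <- md$sample_id[md$sample_type == "added_water"]
  trt <- stats::setNames(md$water_treatment, md$sample_id)
  strain <- stats::setNames(md$strain, md$sample_id)

  results <- list(table = table, metadata = md, tree = tree)

  ## ---- diversity ----
  alpha <- alpha_diversity(table)
  write_tsv(alpha, out("alpha_diversity.tsv"))
  bc <- bray_curtis(table)
  write_tsv(data.frame(sample_id = rownames(bc), bc, check.names = FALSE),
            out("bray_curtis.tsv"))
  write_tsv(data.frame(sample_id = rownames(bc), bc_similarity(bc),
                       check.names = FALSE),
            out("bray_curtis_similarity.tsv"))
  ord <- pcoa(bc)
  write_tsv(data.frame(sample_id = rownames(ord$coordinates),
                       ord$coordinates, check.names = FALSE),
            out("pcoa_coordinates.tsv"))
  write_tsv(data.frame(axis = seq_along(ord$eigenvalues),
                       eigenvalue = ord$eigenvalues),
            out("pcoa_eigenvalues.tsv"))
  results$alpha <- alpha; results$bray_curtis <- bc; results$pcoa <- ord

  ## ---- PERMANOVA contrasts ----
  contrasts <- list(
    gut_strain = list(ids = gut, labels = strain[gut]),
    gut_water_treatment = list(ids = gut, labels = trt[gut]),
    gut_vs_rearing_water = list(
      ids = c(gut, rw),
      labels = stats::setNames(md$sample_type, md$sample_id)[c(gut, rw)])
  )
  perm_rows <- list()
  for (nm in names(contrasts)) {
    cc <- contrasts[[nm]]
    sizes <- table(cc$labels)
    if (length(sizes) < 2 || any(sizes < 2)) {
      note("PERMANOVA contrast ", nm, " skipped: infeasible group sizes")
      next
    }
    pr <- permanova_oneway(bc[cc$ids, cc$ids], cc$labels,
                           n_perm = config$n_perm,
                           seed = sub_seed(config$seed, 11))
    perm_rows[[nm]] <- data.frame(contrast = nm, pseudo_F = pr$pseudo_F,
                                  p_value = pr$p_value,
                                  n_permutations = pr$n_permutations)
  }
  permanova <- do.call(rbind, perm_rows)
  if (!is.null(permanova)) write_tsv(permanova, out("permanova.tsv"))
  results$permanova <- permanova

  ## ---- SIMPER: gut communities between water treatments ----
  if (length(unique(trt[gut])) == 2) {
    simper <- simper_bc(ct_subset(table, samples = gut), trt[gut])
    write_tsv(simper, out("simper.tsv"))
    results$simper <- simper
  } else {
    note("SIMPER skipped: need exactly two water treatments among guts")
  }

  ## ---- shared ASV fractions: each gut vs its water communities ----
  if (length(gut) && length(c(rw, aw))) {
    shared <- do.call(rbind, lapply(gut, function(s) {
      fr <- shared_asv_fraction(table, s, c(rw, aw))
      data.frame(sample_id = s, shared = fr$shared, unique = fr$unique,
                 n_focal_taxa = fr$n_focal_taxa)
    }))
    write_tsv(shared, out("shared_asv_fractions.tsv"))
    results$shared <- shared
  }

  ## ---- phylogenetic signal ----
  niche <- if (!is.null(config$scenario)) {
    exp$traits[taxon_ids(table)]
  } else {
    profile_niche_proxy(table)
  }
  mc <- mantel_correlogram(niche_distance(niche),
                           phylo_d[taxon_ids(table), taxon_ids(table)],
                           n_perm = 199, seed = sub_seed(config$seed, 12))
  write_tsv(mc, out("mantel_correlogram.tsv"))
  results$mantel <- mc

  ## ---- null models ----
  focal <- c(gut, rw)
  ## one-metacommunity assumption: the null pool for both indices is every
  ## taxon in the filtered table (gut, rearing and added water together)
  nti_res <- nti(ct_subset(table, samples = focal), phylo_d,
                 runs = config$nti_runs, seed = sub_seed(config$seed, 13),
                 weighted = config$nti_weighted,
                 null_pool = taxon_ids(table))
  write_tsv(nti_res, out("nti.tsv"))
  results$nti <- nti_res
  note("NTI: ", attr(nti_res, "runs"), " runs, weighted = ",
       config$nti_weighted, ", pool = ", attr(nti_res, "pool_size"), " taxa")

  group_of <- stats::setNames(paste(md$sample_type, md$water_treatment,
                                    sep = "/"), md$sample_id)
  bnti_rows <- list()
  i <- 0L
  for (g in sort(unique(group_of[focal]))) {
    ids <- focal[group_of[focal] == g]
    if (length(ids) < 2) { note("betaNTI group ", g, " skipped: < 2 samples"); next }
    i <- i + 1L
    br <- beta_nti(table, phylo_d, runs = config$bnti_runs,
                   seed = sub_seed(config$seed, 20 + i),
                   weighted = config$bnti_weighted, samples = ids,
                   null_pool = taxon_ids(table))
    br$group <- g
    bnti_rows[[g]] <- br
  }
  bnti_res <- do.call(rbind, lapply(bnti_rows, as.data.frame))
  rownames(bnti_res) <- NULL
  write_tsv(bnti_res, out("bnti.tsv"))
  results$bnti <- bnti_res
  summary_df <- do.call(rbind, lapply(names(bnti_rows), function(g) {
    s <- summarize_processes(bnti_rows[[g]])
    s$group <- g
    s
  }))
  write_tsv(summary_df, out("process_summary.tsv"))
  results$process_summary <- summary_df

  ## ---- manifest and log ----
  cf <- config[setdiff(names(config), "scenario")]
  flat <- unlist(lapply(cf, function(x) paste(x, collapse = ",")))
  manifest <- paste(names(flat), unname(flat), sep = " = ")
  if (!is.null(config$scenario))
    manifest <- c(manifest,
                  paste(paste0("scenario.",
                               names(unlist(config$scenario))),
                        unlist(config$scenario), sep = " = "))
  writeLines(manifest, out("manifest.txt"))
  writeLines(log_lines, out("log.txt"))
  results$files <- list.files(config$output_dir, full.names = TRUE)
  invisible(results)
}

#' Per-taxon niche proxy from relative-abundance profiles
#'
#' For observed data without measured traits, the niche proxy of a taxon is
#' its first principal coordinate in the space of relative-abundance
#' profiles across samples, so taxa with similar occurrence patterns get
#' similar proxies.
#'
#' @param table a `count_table`.
#' @return named numeric vector of per-taxon proxies.
#' @export
profile_niche_proxy <- function(table) {
  m <- ct_counts(table)
  rel <- sweep(m, 2, pmax(colSums(m), 1), "/")
  pc <- stats::prcomp(rel, center = TRUE, scale. = FALSE)
  stats::setNames(pc$x[, 1], rownames(m))
}
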