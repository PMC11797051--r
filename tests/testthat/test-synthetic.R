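test_that("Yule tree simulation is exact in size and seed-stable", {
  tr <- simulate_tree(25, seed = 3)
  expect_equal(length(tr$tip.label), 25)
  expect_identical(write_newick(tr), write_newick(simulate_tree(25, seed = 3)))
  cherry <- simulate_tree(2, seed = 1)
  d <- cophenetic_distances(cherry)
  depths <- ape::node.depth.edgelength(cherry)
  expect_equal(depths[1], depths[2])
})

test_that("Brownian traits have the closed-form variance", {
  tr <- simulate_tree(10, seed = 6)
  expect_true(all(evolve_trait_bm(tr, 0) == 0))
  # Monte-Carlo tip variance vs bm_rate x root-to-tip depth
  depth <- ape::node.depth.edgelength(tr)[1]
  tips <- replicate(400, evolve_trait_bm(tr, 0.5)[1])
  expect_equal(var(tips), 0.5 * depth, tolerance = 0.2)
  # early burst: total tip variance follows the integrated rate
  tips_eb <- replicate(400, evolve_trait_bm(tr, 0.5, eb_rate = 2)[1])
  expect_equal(var(tips_eb), 0.5 * (1 - exp(-2 * depth)) / 2,
               tolerance = 0.2)
  # conserved niches: sister tips are more similar under early burst
  tr2 <- simulate_tree(30, seed = 9)
  d2 <- cophenetic_distances(tr2)
  sib <- which(d2 == min(d2[d2 > 0]), arr.ind = TRUE)[1, ]
  diff_bm <- replicate(200, diff(evolve_trait_bm(tr2, 1)[sib]))
  diff_eb <- replicate(200, diff(evolve_trait_bm(tr2, 1, eb_rate = 2)[sib]))
  expect_lt(var(diff_eb), var(diff_bm))
})

test_that("microdiversity expansion separates intra- and inter-cluster scales", {
  bb <- simulate_tree(6, seed = 2)
  tr <- expand_microdiversity(bb, sizes = rep(3, 6), cluster_depth = 0.03,
                              seed = 1)
  expect_equal(length(tr$tip.label), 18)
  expect_setequal(tr$tip.label, sprintf("ASV_%03d", 1:18))
  d <- stats::cophenetic(tr)
  expect_lt(d["ASV_001", "ASV_002"], 0.1)   # same cluster
  expect_gt(d["ASV_001", "ASV_004"], 0.1)   # different clusters
})

test_that("sample assembly follows selection, dispersal and drift", {
  taxa <- paste0("t", 1:20)
  meta <- setNames(rep(1 / 20, 20), taxa)
  traits <- setNames(seq(-2, 2, length.out = 20), taxa)
  # neutral limit: expected counts proportional to the metacommunity
  counts <- Reduce(`+`, lapply(1:30, function(i)
    assemble_sample(meta, traits, 0, Inf, 2000, seed = i)))
  expect_equal(max(abs(counts / sum(counts) - 1 / 20)), 0, tolerance = 0.02)
  # vanishing width: all reads on the taxon nearest the optimum
  hard <- assemble_sample(meta, traits, traits["t7"], 1e-3, 500, seed = 1)
  expect_equal(unname(hard["t7"]), 500)
  # determinism
  expect_identical(assemble_sample(meta, traits, 0, 0.5, 1000, seed = 9),
                   assemble_sample(meta, traits, 0, 0.5, 1000, seed = 9))
  # all-zero weights are an explicit error
  far <- setNames(rep(100, 20), taxa)
  expect_error(assemble_sample(meta, far, 0, 1e-4, 100), "increase sigma")
  # dispersal reintroduces taxa excluded by the filter
  set.seed(2)
  with_tail <- Reduce(`+`, lapply(1:20, function(i)
    assemble_sample(meta, traits, traits["t7"], 1e-3, 5000, seed = i,
                    dispersal = 0.2)))
  expect_gt(sum(with_tail > 0), 10)
})

test_that("the generated experiment mirrors the factorial design", {
  ex <- generate_experiment(scenario_config(master_seed = 4))
  md <- ex$metadata
  expect_equal(sum(md$sample_type == "gut"), 64)        # 4 groups x 4 x 4
  expect_equal(sum(md$sample_type == "rearing_water"), 16)
  expect_equal(sum(md$sample_type == "added_water"), 8)
  expect_equal(sum(md$sample_type == "negative_control"), 2)
  expect_equal(nrow(md), length(sample_ids(ex$table)))
  expect_setequal(taxon_ids(ex$table), ex$tree$tip.label)
  expect_equal(ex$truth$process, "homogeneous_selection")
  # gut sample depth is the configured read depth
  m <- ct_counts(ex$table)
  gut <- md$sample_id[md$sample_type == "gut"]
  expect_true(all(colSums(m[, gut]) == 11000))
})

test_that("experiments are byte-identical under one master seed", {
  cfg <- small_scenario(seed = 11)
  a <- generate_experiment(cfg)
  b <- generate_experiment(cfg)
  expect_identical(ct_counts(a$table), ct_counts(b$table))
  expect_identical(write_newick(a$tree), write_newick(b$tree))
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth, b$truth)
})

test_that("contamination controls exercise the QC filter", {
  cfg <- small_scenario(seed = 5)
  ex <- generate_experiment(cfg)
  ctrl <- ex$metadata$sample_id[ex$metadata$sample_type == "negative_control"]
  ctrl_reads <- rowSums(ct_counts(ex$table)[, ctrl, drop = FALSE])
  expect_gt(sum(ctrl_reads > 0), 0)
  # zero contamination: the control filter removes nothing
  cfg0 <- scenario_config(n_taxa = 60, n_species = 15, flasks_per_group = 1,
                          guts_per_flask = 2, contamination_rate = 0,
                          master_seed = 5)
  ex0 <- generate_experiment(cfg0)
  ctrl0 <- ex0$metadata$sample_id[ex0$metadata$sample_type ==
                                    "negative_control"]
  filtered <- subtract_control_asvs(ex0$table, ctrl0)
  expect_equal(nrow(ct_counts(filtered)), nrow(ct_counts(ex0$table)))
})

test_that("simulated niches leave a detectable phylogenetic signal", {
  cfg <- small_scenario(seed = 7)
  ex <- generate_experiment(cfg)
  d <- cophenetic_distances(ex$tree)
  mc <- mantel_correlogram(niche_distance(ex$traits),
                           d[names(ex$traits), names(ex$traits)],
                           n_perm = 199, seed = 1)
  expect_gt(mc$mantel_r[1], 0)
  expect_lt(mc$p_value[1], 0.05)
})

test_that("truth manifests are flat text", {
  cfg <- small_scenario(seed = 3)
  ex <- generate_experiment(cfg)
  path <- withr::local_tempfile(fileext = ".txt")
  write_truth_manifest(ex$truth, path)
  lines <- readLines(path)
  expect_true(any(grepl("^process = homogeneous_selection$", lines)))
  expect_true(all(grepl(" = ", lines)))
})
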