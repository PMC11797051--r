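test_that("alpha diversity matches closed forms", {
  uni <- make_table(matrix(10, 4, 1))
  a <- alpha_diversity(uni)
  expect_equal(a$richness, 4)
  expect_equal(a$shannon_exp, 4)
  expect_equal(a$evenness, 1)

  ct <- make_table(matrix(c(5, 3, 2, 1, 1), 5, 1))
  a2 <- alpha_diversity(ct)
  expect_equal(a2$chao1, 5.5)  # 5 + 2*1/(2*(1+1))
  expect_gte(a2$chao1, a2$richness)

  single <- make_table(matrix(7, 1, 1))
  a3 <- alpha_diversity(single)
  expect_equal(unlist(a3[, -1]), c(richness = 1, chao1 = 1,
                                   shannon_exp = 1, evenness = 1))
  expect_error(alpha_diversity(make_table(matrix(0, 2, 1))), "empty")
})

test_that("doubling a uniform community doubles richness and Hill-1", {
  base <- make_table(matrix(8, 6, 1))
  dbl <- make_table(matrix(8, 12, 1))
  a1 <- alpha_diversity(base); a2 <- alpha_diversity(dbl)
  expect_equal(a2$richness, 2 * a1$richness)
  expect_equal(a2$shannon_exp, 2 * a1$shannon_exp)
})

test_that("Bray-Curtis has the expected values and metric properties", {
  ct <- make_table(cbind(s1 = c(6, 2), s2 = c(2, 2)))
  expect_equal(bray_curtis(ct)["s1", "s2"], 1 / 3)
  ct2 <- make_table(cbind(a = c(2, 0), b = c(0, 2), c = c(2, 0)))
  d <- bray_curtis(ct2)
  expect_equal(d["a", "b"], 1)
  expect_equal(d["a", "c"], 0)
  expect_equal(bc_similarity(d)["a", "b"], 0)
  for (seed in 1:3) {
    dd <- bray_curtis(random_table(15, 6, seed))
    expect_true(all(dd >= 0 & dd <= 1))
    expect_equal(dd, t(dd))
    expect_equal(diag(dd), setNames(rep(0, 6), colnames(dd)))
  }
})

test_that("PCoA recovers Euclidean configurations", {
  # two samples at distance 1 -> +-0.5 on the single axis
  d2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  ord <- pcoa(d2)
  expect_equal(sort(ord$coordinates[, 1]), c(-0.5, 0.5),
               ignore_attr = TRUE)
  # degenerate: all distances zero
  d0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(ncol(pcoa(d0)$coordinates), 0)
  # unit square: two equal leading eigenvalues
  pts <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  dsq <- as.matrix(dist(pts)); dimnames(dsq) <- list(1:4, 1:4)
  ev <- pcoa(dsq)$eigenvalues
  expect_equal(ev[1], ev[2])
  # distances reproduced from coordinates for a Euclidean cloud
  set.seed(42)
  x <- matrix(rnorm(8 * 3), 8)
  de <- as.matrix(dist(x)); dimnames(de) <- list(1:8, 1:8)
  co <- pcoa(de)$coordinates
  expect_equal(as.matrix(dist(co)), de, ignore_attr = TRUE,
               tolerance = 1e-8)
})

test_that("one-way PERMANOVA separates clusters and is seed-stable", {
  set.seed(7)
  pts <- rbind(matrix(rnorm(10, 0, 0.05), 5), matrix(rnorm(10, 5, 0.05), 5))
  d <- as.matrix(dist(pts)); dimnames(d) <- list(1:10, 1:10)
  g <- rep(c("a", "b"), each = 5)
  res <- permanova_oneway(d, g, n_perm = 199, seed = 1)
  # only label permutations recreating the partition can reach the observed
  # F, so p sits near its attainable floor
  expect_gte(res$p_value, 1 / 200)
  expect_lte(res$p_value, 0.03)
  res2 <- permanova_oneway(d, g, n_perm = 199, seed = 1)
  expect_identical(res, res2)
  expect_error(permanova_oneway(d, c("a", rep("b", 9)), 99), "fewer than two")
})

test_that("PERMANOVA pseudo-F agrees with vegan::adonis2", {
  skip_if_not_installed("vegan")
  set.seed(11)
  m <- matrix(rpois(60, 10), 10, 6)
  d <- as.matrix(vegan::vegdist(m))
  dimnames(d) <- list(1:10, 1:10)
  g <- rep(c("x", "y"), each = 5)
  mine <- permanova_oneway(d, g, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(d) ~ g, permutations = 99)
  expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-10)
})

test_that("SIMPER decomposes between-group dissimilarity", {
  # groups differ in exactly one taxon -> it contributes 100%
  ct <- make_table(cbind(a1 = c(5, 5, 0), a2 = c(5, 5, 0),
                         b1 = c(5, 5, 8), b2 = c(5, 5, 8)))
  sp <- simper_bc(ct, c("A", "A", "B", "B"))
  expect_equal(sp$percent[1], 100)
  expect_equal(sp$taxon_id[1], "t3")
  # single pair: contributions sum to the Bray-Curtis dissimilarity
  ct2 <- make_table(cbind(x = c(6, 2, 1), y = c(2, 2, 5)))
  sp2 <- simper_bc(ct2, c("A", "B"))
  expect_equal(sum(sp2$average), bray_curtis(ct2)["x", "y"])
  expect_equal(sum(sp2$percent), 100)
  expect_true(all(diff(sp2$cumulative_percent) >= 0))
  # brute-force oracle over between-group pairs
  ct3 <- random_table(5, 4, seed = 3)
  g3 <- c("A", "B", "A", "B")
  sp3 <- simper_bc(ct3, g3)
  m <- ct_counts(ct3)
  manual <- rowMeans(sapply(list(c(1, 2), c(1, 4), c(3, 2), c(3, 4)),
    function(pr) abs(m[, pr[1]] - m[, pr[2]]) / sum(m[, pr])))
  expect_equal(sp3$average, unname(manual[sp3$taxon_id]))
})

test_that("SIMPER averages agree with vegan::simper", {
  skip_if_not_installed("vegan")
  ct <- random_table(12, 8, seed = 9)
  g <- rep(c("A", "B"), each = 4)
  mine <- simper_bc(ct, g)
  ref <- summary(vegan::simper(t(ct_counts(ct)), g),
                 ordered = TRUE)[["A_B"]]
  expect_equal(mine$average[order(mine$taxon_id)],
               ref$average[order(rownames(ref))], tolerance = 1e-10)
})

test_that("group comparison follows the documented decision path", {
  set.seed(21)
  a <- rnorm(20); b <- rnorm(20) + 1
  res <- compare_groups(a, b)
  expect_equal(res$test, "student_t")
  expect_true(all(c("shapiro_a", "shapiro_b", "f_test") %in% res$path$step))
  # heavy-tailed data routes to the rank-sum test in most replicates
  picks <- sapply(1:20, function(i) {
    set.seed(i)
    compare_groups(rlnorm(15, 0, 1.5), rlnorm(15, 0.5, 1.5))$test
  })
  expect_gt(mean(picks == "wilcoxon"), 0.5)
  # unequal variances (normal) route to Welch in most replicates
  picks2 <- sapply(1:20, function(i) {
    set.seed(i)
    compare_groups(rnorm(25, 0, 1), rnorm(25, 0, 6))$test
  })
  expect_gt(mean(picks2 == "welch_t"), 0.5)
  set.seed(5)
  x <- rnorm(10)
  expect_gt(compare_groups(x, x)$p_value, 0.9)
  expect_error(compare_groups(1:2, 1:5), "at least three")
})

test_that("shared ASV fractions are set arithmetic on presence", {
  ct <- make_table(cbind(focal = c(1, 1, 1, 1), r1 = c(1, 0, 0, 0),
                         r2 = c(0, 1, 0, 0)))
  fr <- shared_asv_fraction(ct, "focal", c("r1", "r2"))
  expect_equal(fr$shared, 0.5)
  expect_equal(fr$unique, 0.5)
  ct2 <- make_table(cbind(focal = c(1, 1, 0), sup = c(2, 3, 1)))
  expect_equal(shared_asv_fraction(ct2, "focal", "sup")$shared, 1)
  ct3 <- make_table(cbind(focal = c(1, 0), disj = c(0, 5)))
  expect_equal(shared_asv_fraction(ct3, "focal", "disj")$shared, 0)
  expect_error(shared_asv_fraction(ct3, "disj", "focal"), NA)
})
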