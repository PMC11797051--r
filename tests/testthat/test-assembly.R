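test_that("MNTD and betaMNTD match hand values and the brute-force oracle", {
  d <- cophenetic_distances(tree3())
  expect_equal(mntd(c(A = 1, B = 1), d), 2)
  expect_equal(mntd(c(A = 1, B = 1, C = 1), d), 8 / 3)
  # weight concentrated on the A-B cherry approaches its distance
  expect_equal(mntd(c(A = 500, B = 499, C = 1), d, weighted = TRUE),
               (999 * 2 + 1 * 4) / 1000)
  expect_error(mntd(c(A = 1), d), "fewer than two")

  expect_equal(bmntd(c(A = 3, B = 1), c(A = 3, B = 1), d), 0)
  expect_equal(bmntd(c(A = 1), c(B = 1), d), 2)
  expect_error(bmntd(c(A = 0), c(B = 1), d), "empty")

  for (seed in 1:5) {
    set.seed(seed)
    tr <- simulate_tree(7, seed = seed)
    dd <- cophenetic_distances(tr)
    x <- setNames(rpois(7, 2), tr$tip.label)
    y <- setNames(rpois(7, 2), tr$tip.label)
    if (sum(x) == 0 || sum(y) == 0) next
    for (w in c(TRUE, FALSE)) {
      expect_equal(bmntd(x, y, dd, weighted = w),
                   oracle_bmntd(x, y, dd, weighted = w))
      expect_equal(bmntd(x, y, dd, weighted = w),
                   bmntd(y, x, dd, weighted = w))
    }
    if (sum(x > 0) >= 2)
      expect_equal(mntd(x, dd), oracle_mntd(x, dd))
  }
})

test_that("observed MNTD and betaMNTD agree with picante", {
  skip_if_not_installed("picante")
  tr <- simulate_tree(15, seed = 2)
  d <- cophenetic_distances(tr)
  ct <- random_table(15, 4, seed = 5, lambda = 3)
  rownames(ct$counts) <- tr$tip.label
  comm <- t(ct_counts(ct))
  expect_equal(
    unname(picante::mntd(comm, d, abundance.weighted = FALSE)),
    unname(apply(comm, 1, function(x) mntd(x, d))))
  ref <- as.matrix(picante::comdistnt(comm, d, abundance.weighted = TRUE))
  mine <- outer(rownames(comm), rownames(comm), Vectorize(function(i, j)
    if (i == j) 0 else bmntd(comm[i, ], comm[j, ], d, weighted = TRUE)))
  dimnames(mine) <- dimnames(ref)
  expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("exhaustive tip-shuffle nulls match independent enumeration", {
  tr <- simulate_tree(6, seed = 8)
  d <- cophenetic_distances(tr)
  pool <- tr$tip.label
  m <- cbind(s1 = c(2, 3, 0, 0, 1, 0), s2 = c(0, 1, 4, 2, 0, 0))
  rownames(m) <- pool
  ct <- count_table(m)

  perms <- oracle_perms(6)
  null_mntd <- apply(perms, 1, function(p) {
    dp <- d[p, p]; dimnames(dp) <- list(pool, pool)
    oracle_mntd(m[, "s1"], dp)
  })
  res <- nti(ct, d, null_pool = pool, exhaustive = TRUE)
  expect_equal(res$null_mean[1], mean(null_mntd))
  expect_equal(res$null_sd[1], sd(null_mntd))
  expect_equal(res$nti[1],
               -(oracle_mntd(m[, "s1"], d) - mean(null_mntd)) / sd(null_mntd))

  null_bm <- apply(perms, 1, function(p) {
    dp <- d[p, p]; dimnames(dp) <- list(pool, pool)
    oracle_bmntd(m[, "s1"], m[, "s2"], dp)
  })
  bres <- beta_nti(ct, d, null_pool = pool, exhaustive = TRUE)
  expect_equal(bres$null_mean, mean(null_bm))
  expect_equal(bres$null_sd, sd(null_bm))

  # sampled nulls agree within Monte-Carlo error (3 SE)
  sres <- nti(ct, d, runs = 400, seed = 1, null_pool = pool)
  se <- sd(null_mntd) / sqrt(400)
  expect_lt(abs(sres$null_mean[1] - mean(null_mntd)), 3 * se)
  sb <- beta_nti(ct, d, runs = 400, seed = 1, null_pool = pool)
  expect_lt(abs(sb$null_mean - mean(null_bm)), 3 * sd(null_bm) / sqrt(400))
})

test_that("NTI is positive for nearest relatives and flags degenerate nulls", {
  # ladder (pectinate) tree: the two closest tips are clustered
  ladder <- parse_newick(
    "(((((A:1,B:1):1,C:2):1,D:3):1,E:4):1,F:5);")
  d <- cophenetic_distances(ladder)
  m <- matrix(0L, 6, 1, dimnames = list(ladder$tip.label, "s"))
  m[c("A", "B"), 1] <- 5L
  res <- nti(count_table(m), d, null_pool = ladder$tip.label,
             exhaustive = TRUE)
  expect_gt(res$nti, 0)
  # community spanning the whole pool: every shuffle gives the same MNTD
  full <- matrix(1L, 6, 1, dimnames = list(ladder$tip.label, "s"))
  expect_message(res2 <- nti(count_table(full), d, runs = 50, seed = 1),
                 "degenerate")
  expect_true(is.na(res2$nti))
  # identical sample pair: betaMNTD is 0 under every shuffle
  two <- cbind(s1 = full[, 1], s2 = full[, 1])
  rownames(two) <- ladder$tip.label
  expect_message(bres <- beta_nti(count_table(two), d, runs = 50, seed = 1),
                 "degenerate")
  expect_identical(bres$process, "undefined")
})

test_that("null models are reproducible under a fixed seed", {
  tr <- simulate_tree(12, seed = 1)
  d <- cophenetic_distances(tr)
  ct <- random_table(12, 4, seed = 2, lambda = 5)
  rownames(ct$counts) <- tr$tip.label
  expect_identical(nti(ct, d, runs = 99, seed = 7),
                   nti(ct, d, runs = 99, seed = 7))
  expect_identical(beta_nti(ct, d, runs = 99, seed = 7),
                   beta_nti(ct, d, runs = 99, seed = 7))
})

test_that("betaNTI is calibrated for random draws from a neutral pool", {
  tr <- simulate_tree(40, seed = 10)
  d <- cophenetic_distances(tr)
  set.seed(11)
  m <- sapply(1:10, function(i) {
    v <- integer(40)
    v[sample(40, 12)] <- rpois(12, 8) + 1L
    v
  })
  dimnames(m) <- list(tr$tip.label, paste0("s", 1:10))
  res <- beta_nti(count_table(m), d, runs = 199, seed = 3)
  expect_gte(mean(abs(res$bnti) <= 2, na.rm = TRUE), 0.9)
})

test_that("process classification applies the +-2 thresholds", {
  expect_identical(classify_process(c(2.5, -3, 0, 2, -2, NA)),
                   c("heterogeneous_selection", "homogeneous_selection",
                     "stochastic", "stochastic", "stochastic", "undefined"))
})

test_that("process summaries count within-group pairs", {
  samples <- paste0("s", 1:32)
  pairs <- t(combn(32, 2))
  res <- data.frame(sample_1 = samples[pairs[, 1]],
                    sample_2 = samples[pairs[, 2]],
                    process = rep(c("stochastic", "homogeneous_selection"),
                                  length.out = nrow(pairs)))
  sm <- summarize_processes(res)
  expect_equal(sm$n_pairs, 496)  # C(32, 2)
  expect_equal(sum(unlist(sm[, grep("^frac_", names(sm))])), 1)
  # two groups of 8: 28 within-group pairs each; between-group pairs ignored
  g <- setNames(rep(c("A", "B"), each = 8), paste0("s", 1:16))
  pairs16 <- t(combn(16, 2))
  res16 <- data.frame(sample_1 = paste0("s", pairs16[, 1]),
                      sample_2 = paste0("s", pairs16[, 2]),
                      process = "stochastic")
  sm16 <- summarize_processes(res16, groups = g)
  expect_equal(sm16$n_pairs, c(28, 28))
  expect_equal(sm16$frac_stochastic, c(1, 1))
})
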