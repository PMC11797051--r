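# shared fixtures built in code

make_table <- function(mat, taxa = NULL, samples = NULL) {
  if (is.null(taxa))
    taxa <- if (!is.null(rownames(mat))) rownames(mat) else
      paste0("t", seq_len(nrow(mat)))
  if (is.null(samples))
    samples <- if (!is.null(colnames(mat))) colnames(mat) else
      paste0("s", seq_len(ncol(mat)))
  dimnames(mat) <- list(taxa, samples)
  count_table(mat)
}

random_table <- function(n_taxa, n_samples, seed, lambda = 20) {
  set.seed(seed)
  make_table(matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples))
}

# three tips: d(A,B)=2, d(A,C)=d(B,C)=4
tree3 <- function() parse_newick("((A:1,B:1):1,C:2);")

# small scenario for fast end-to-end runs
small_scenario <- function(seed = 1, process = "homogeneous_selection") {
  scenario_config(n_taxa = 60, n_species = 15, process = process,
                  flasks_per_group = 1, guts_per_flask = 2,
                  aw_days = c(14L, 21L), master_seed = seed)
}

# independent brute-force MNTD oracle (kept deliberately naive)
oracle_mntd <- function(community, d, weighted = FALSE) {
  present <- names(community)[community > 0]
  mins <- sapply(present, function(t) {
    min(sapply(setdiff(present, t), function(u) d[t, u]))
  })
  if (weighted) {
    w <- community[present] / sum(community[present])
    sum(w * mins)
  } else mean(mins)
}

# independent brute-force betaMNTD oracle
oracle_bmntd <- function(x, y, d, weighted = TRUE) {
  px <- names(x)[x > 0]
  py <- names(y)[y > 0]
  mx <- sapply(px, function(t) min(sapply(py, function(u) d[t, u])))
  my <- sapply(py, function(u) min(sapply(px, function(t) d[u, t])))
  if (weighted) {
    wx <- x[px] / sum(x[px])
    wy <- y[py] / sum(y[py])
  } else {
    wx <- rep(1 / length(px), length(px))
    wy <- rep(1 / length(py), length(py))
  }
  0.5 * (sum(wx * mx) + sum(wy * my))
}

# all permutations of 1..n, built by first-element insertion (independent
# of the package's enumeration)
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- oracle_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    m <- sub
    m[m >= i] <- m[m >= i] + 1L
    cbind(i, m, deparse.level = 0)
  }))
}
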