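## fast column minima (used in null-model loops); max.col runs in C
col_mins <- function(m) {
  if (nrow(m) == 1L) return(as.vector(m))
  tm <- -t(m)
  j <- max.col(tm, ties.method = "first")
  -tm[cbind(seq_along(j), j)]
}

## all permutations of 1..n as rows; exhaustive nulls only, so n is small
all_perms <- function(n) {
  if (n > 8) stop("exhaustive null restricted to pools of <= 8 taxa")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Mean nearest taxon distance of one community
#'
#' For each taxon present in the community, the phylogenetic distance to its
#' nearest other present taxon is found; MNTD is the (optionally
#' abundance-weighted) mean of these per-taxon minima.
#'
#' @param community named count vector (names are taxon ids in `d`); at
#'   least two taxa must be present.
#' @param d cophenetic distance matrix over at least the present taxa.
#' @param weighted if `TRUE`, weight each taxon's nearest-neighbour distance
#'   by its relative abundance; if `FALSE` (default) use the plain mean.
#' @return MNTD in branch-length units.
#' @export
mntd <- function(community, d, weighted = FALSE) {
  if (is.null(names(community))) stop("community must be named by taxon id")
  present <- names(community)[community > 0]
  if (length(present) < 2)
    stop("MNTD undefined for communities with fewer than two taxa")
  missing <- setdiff(present, rownames(d))
  if (length(missing))
    stop("taxa absent from the distance matrix: ",
         paste(missing, collapse = ", "))
  dsub <- d[present, present]
  diag(dsub) <- Inf
  mins <- col_mins(dsub)
  if (weighted) {
    w <- community[present] / sum(community[present])
    sum(w * mins)
  } else {
    mean(mins)
  }
}

#' Between-community mean nearest taxon distance
#'
#' For each taxon in one community, the distance to its nearest taxon in the
#' other community (self-matches count as distance zero for shared taxa);
#' betaMNTD averages the two directed means:
#' 0.5 * (sum_t w_t min_u d(t,u) + sum_u w_u min_t d(u,t)).
#'
#' @param x,y named count vectors; each must have at least one present taxon.
#' @param d cophenetic distance matrix.
#' @param weighted abundance-weight the per-taxon minima (default `TRUE`,
#'   the convention of abundance-weighted betaMNTD); if `FALSE` each present
#'   taxon gets weight 1/richness.
#' @return betaMNTD in branch-length units; zero iff the communities share
#'   identical taxon sets is not required — zero arises when every taxon
#'   finds a zero-distance neighbour, e.g. for identical communities.
#' @export
bmntd <- function(x, y, d, weighted = TRUE) {
  if (is.null(names(x)) || is.null(names(y)))
    stop("communities must be named by taxon id")
  px <- names(x)[x > 0]
  py <- names(y)[y > 0]
  if (!length(px) || !length(py)) stop("empty community")
  missing <- setdiff(c(px, py), rownames(d))
  if (length(missing))
    stop("taxa absent from the distance matrix: ",
         paste(missing, collapse = ", "))
  min_xy <- col_mins(d[py, px, drop = FALSE])  # per taxon of x, nearest in y
  min_yx <- col_mins(d[px, py, drop = FALSE])  # per taxon of y, nearest in x
  if (weighted) {
    wx <- x[px] / sum(x[px])
    wy <- y[py] / sum(y[py])
  } else {
    wx <- rep(1 / length(px), length(px))
    wy <- rep(1 / length(py), length(py))
  }
  0.5 * (sum(wx * min_xy) + sum(wy * min_yx))
}

## shared machinery: resolve pool, index communities into it
null_setup <- function(m, d, null_pool) {
  if (is.null(null_pool)) null_pool <- rownames(m)[rowSums(m) > 0]
  present_any <- rownames(m)[rowSums(m) > 0]
  outside <- setdiff(present_any, null_pool)
  if (length(outside))
    stop("null pool must contain every taxon present in the table; missing: ",
         paste(outside, collapse = ", "))
  missing <- setdiff(null_pool, rownames(d))
  if (length(missing))
    stop("taxa absent from the distance matrix: ",
         paste(missing, collapse = ", "))
  dp <- unname(d[null_pool, null_pool])
  mp <- m[null_pool, , drop = FALSE]
  list(pool = null_pool, dp = dp, mp = mp)
}

## permutation schedule: list of integer vectors over the pool
null_perms <- function(npool, runs, seed, exhaustive) {
  if (exhaustive) {
    pm <- all_perms(npool)
    lapply(seq_len(nrow(pm)), function(i) pm[i, ])
  } else {
    if (!is.null(seed)) set.seed(seed)
    lapply(seq_len(runs), function(i) sample.int(npool))
  }
}

#' Nearest taxon index (NTI) per sample
#'
#' Standardizes observed MNTD against a null in which taxon labels are
#' shuffled across the tips of the phylogeny restricted to a metacommunity
#' pool (the "taxa labels" null): NTI = -(MNTD_obs - mean_null) / sd_null.
#' NTI > 2 indicates phylogenetic clustering beyond chance (selection),
#' NTI < -2 overdispersion, |NTI| <= 2 no departure from the null.
#'
#' @param table a `count_table`.
#' @param d cophenetic distance matrix covering the null pool.
#' @param runs number of null permutations (default 999).
#' @param seed optional RNG seed for the null.
#' @param weighted abundance-weight MNTD (default `FALSE`, the classical
#'   presence-based index).
#' @param null_pool taxon ids forming the metacommunity; defaults to all
#'   taxa present anywhere in `table` (one-metacommunity assumption).
#' @param exhaustive if `TRUE`, enumerate all label permutations instead of
#'   sampling (pools of <= 8 taxa only).
#' @return a data.frame of class `nti_result`: `sample_id`, `n_present`,
#'   `mntd_obs`, `null_mean`, `null_sd`, `nti` (`NA` with a message when the
#'   null is degenerate, e.g. a sample containing the whole pool).
#' @export
nti <- function(table, d, runs = 999, seed = NULL, weighted = FALSE,
                null_pool = NULL, exhaustive = FALSE) {
  m <- ct_counts(table)
  ns <- null_setup(m, d, null_pool)
  npool <- length(ns$pool)
  pres <- lapply(seq_len(ncol(ns$mp)), function(j) which(ns$mp[, j] > 0))
  wts <- lapply(seq_len(ncol(ns$mp)), function(j) {
    x <- ns$mp[pres[[j]], j]
    x / sum(x)
  })
  usable <- vapply(pres, length, 1L) >= 2
  if (any(!usable))
    message("sample(s) with fewer than two taxa get NA NTI: ",
            paste(colnames(m)[!usable], collapse = ", "))
  mntd_for <- function(perm, j) {
    p <- perm[pres[[j]]]
    dsub <- ns$dp[p, p]
    diag(dsub) <- Inf
    mins <- col_mins(dsub)
    if (weighted) sum(wts[[j]] * mins) else mean(mins)
  }
  identity_perm <- seq_len(npool)
  obs <- ifelse(usable,
                vapply(seq_along(pres), function(j)
                  if (usable[j]) mntd_for(identity_perm, j) else NA_real_,
                  1), NA_real_)
  perms <- null_perms(npool, runs, seed, exhaustive)
  nulls <- matrix(NA_real_, length(perms), ncol(m))
  for (r in seq_along(perms)) {
    perm <- perms[[r]]
    for (j in which(usable)) nulls[r, j] <- mntd_for(perm, j)
  }
  null_mean <- colMeans(nulls)
  null_sd <- apply(nulls, 2, stats::sd)
  degenerate <- usable & !is.na(null_sd) & null_sd < 1e-12
  if (any(degenerate))
    message("degenerate null (sd = 0) for sample(s): ",
            paste(colnames(m)[degenerate], collapse = ", "))
  nti_val <- ifelse(usable & !degenerate,
                    -(obs - null_mean) / null_sd, NA_real_)
  out <- data.frame(sample_id = colnames(m),
                    n_present = vapply(pres, length, 1L),
                    mntd_obs = obs,
                    null_mean = ifelse(usable, null_mean, NA_real_),
                    null_sd = ifelse(usable, null_sd, NA_real_),
                    nti = nti_val,
                    stringsAsFactors = FALSE)
  attr(out, "runs") <- length(perms)
  attr(out, "weighted") <- weighted
  attr(out, "pool_size") <- npool
  attr(out, "exhaustive") <- exhaustive
  class(out) <- c("nti_result", "data.frame")
  out
}

#' Beta nearest taxon index (betaNTI) for sample pairs
#'
#' Standardizes observed betaMNTD for every unordered sample pair against
#' the tip-label-shuffle null over a per-analysis-group metacommunity pool:
#' betaNTI = (betaMNTD_obs - mean_null) / sd_null. Pairs are classified by
#' [classify_process()]: > 2 heterogeneous selection, < -2 homogeneous
#' selection, otherwise indistinguishable from the null (stochastic).
#'
#' @inheritParams nti
#' @param weighted abundance-weight betaMNTD (default `TRUE`, the common
#'   convention for abundance-weighted turnover).
#' @param samples optional sample ids restricting the analysis (e.g. one
#'   experimental group); default all samples in `table`.
#' @param null_pool defaults to the taxa present in the selected samples.
#' @return a data.frame of class `bnti_result`: `sample_1`, `sample_2`,
#'   `bmntd_obs`, `null_mean`, `null_sd`, `bnti`, `process`.
#' @export
beta_nti <- function(table, d, runs = 999, seed = NULL, weighted = TRUE,
                     samples = NULL, null_pool = NULL, exhaustive = FALSE) {
  m <- ct_counts(table)
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(m))
    if (length(missing))
      stop("unknown sample ids: ", paste(missing, collapse = ", "))
    m <- m[, samples, drop = FALSE]
  }
  if (ncol(m) < 2) stop("need at least two samples")
  ns <- null_setup(m, d, null_pool)
  npool <- length(ns$pool)
  nsamp <- ncol(ns$mp)
  pres <- lapply(seq_len(nsamp), function(j) which(ns$mp[, j] > 0))
  empty <- vapply(pres, length, 1L) == 0
  if (any(empty))
    stop("empty sample(s): ", paste(colnames(m)[empty], collapse = ", "))
  wts <- lapply(seq_len(nsamp), function(j) {
    if (weighted) {
      x <- ns$mp[pres[[j]], j]
      x / sum(x)
    } else {
      rep(1 / length(pres[[j]]), length(pres[[j]]))
    }
  })
  pairs <- utils::combn(nsamp, 2)
  npairs <- ncol(pairs)
  ## M[q, s]: distance from tip q to the nearest tip occupied by sample s;
  ## under a permutation, taxon t of sample j sits at tip perm[t], so sample
  ## s occupies tips perm[pres[[s]]] and the pair statistic reads
  ## M[perm[pres[[i]]], j].
  pair_values <- function(perm) {
    M <- matrix(NA_real_, npool, nsamp)
    for (j in seq_len(nsamp)) {
      M[, j] <- col_mins(ns$dp[perm[pres[[j]]], , drop = FALSE])
    }
    vals <- numeric(npairs)
    for (k in seq_len(npairs)) {
      i <- pairs[1, k]; j <- pairs[2, k]
      vals[k] <- 0.5 * (sum(wts[[i]] * M[perm[pres[[i]]], j]) +
                        sum(wts[[j]] * M[perm[pres[[j]]], i]))
    }
    vals
  }
  obs <- pair_values(seq_len(npool))
  perms <- null_perms(npool, runs, seed, exhaustive)
  nulls <- matrix(NA_real_, length(perms), npairs)
  for (r in seq_along(perms)) nulls[r, ] <- pair_values(perms[[r]])
  null_mean <- colMeans(nulls)
  null_sd <- apply(nulls, 2, stats::sd)
  degenerate <- null_sd < 1e-12
  if (any(degenerate))
    message(sum(degenerate), " pair(s) with a degenerate null (sd = 0)")
  bnti <- ifelse(degenerate, NA_real_, (obs - null_mean) / null_sd)
  out <- data.frame(sample_1 = colnames(m)[pairs[1, ]],
                    sample_2 = colnames(m)[pairs[2, ]],
                    bmntd_obs = obs,
                    null_mean = null_mean,
                    null_sd = null_sd,
                    bnti = bnti,
                    process = classify_process(bnti),
                    stringsAsFactors = FALSE)
  attr(out, "runs") <- length(perms)
  attr(out, "weighted") <- weighted
  attr(out, "pool_size") <- npool
  attr(out, "exhaustive") <- exhaustive
  class(out) <- c("bnti_result", "data.frame")
  out
}

#' Classify a betaNTI value into an assembly process
#'
#' betaNTI > 2: heterogeneous selection (turnover greater than expected by
#' chance); betaNTI < -2: homogeneous selection; values between -2 and 2
#' (boundaries included) are not distinguishable from the null and are
#' attributed to stochastic processes; `NA` maps to `"undefined"`.
#'
#' @param bnti numeric vector of betaNTI values.
#' @return character vector of process classes.
#' @export
classify_process <- function(bnti) {
  out <- rep("stochastic", length(bnti))
  out[!is.na(bnti) & bnti > 2] <- "heterogeneous_selection"
  out[!is.na(bnti) & bnti < -2] <- "homogeneous_selection"
  out[is.na(bnti)] <- "undefined"
  out
}

#' Summarize assembly-process fractions per sample group
#'
#' Tallies, for each group, the fraction of within-group sample pairs in
#' each process class. With n samples per group there are n (n - 1) / 2
#' within-group pairs.
#'
#' @param results a `bnti_result` data.frame (or any data.frame with
#'   `sample_1`, `sample_2`, `process`).
#' @param groups named character vector mapping sample id to group; if
#'   `NULL` all pairs form one group `"all"`. Pairs spanning two groups are
#'   not counted.
#' @return a data.frame: `group`, `n_pairs`, and one `frac_*` column per
#'   process class; fractions per row sum to 1.
#' @export
summarize_processes <- function(results, groups = NULL) {
  stopifnot(all(c("sample_1", "sample_2", "process") %in% names(results)))
  if (is.null(groups)) {
    g1 <- g2 <- rep("all", nrow(results))
  } else {
    miss <- setdiff(unique(c(results$sample_1, results$sample_2)),
                    names(groups))
    if (length(miss))
      stop("samples without a group: ", paste(miss, collapse = ", "))
    g1 <- unname(groups[results$sample_1])
    g2 <- unname(groups[results$sample_2])
  }
  within <- g1 == g2
  classes <- c("heterogeneous_selection", "homogeneous_selection",
               "stochastic", "undefined")
  out <- do.call(rbind, lapply(sort(unique(g1[within])), function(g) {
    sel <- within & g1 == g
    n <- sum(sel)
    fr <- vapply(classes, function(cl) sum(results$process[sel] == cl) / n, 1)
    data.frame(group = g, n_pairs = n, t(fr), stringsAsFactors = FALSE)
  }))
  names(out)[-(1:2)] <- paste0("frac_", classes)
  rownames(out) <- NULL
  out
}
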