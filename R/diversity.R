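#' Per-sample alpha diversity
#'
#' Computes observed richness S, the Chao1 richness estimate, the Hill
#' number of order one (exponential Shannon diversity, e^H with H in nats),
#' and evenness e^H / S. Chao1 defaults to the bias-corrected form
#' S + F1 (F1 - 1) / (2 (F2 + 1)), with F1 and F2 the singleton and
#' doubleton counts; the classic form S + F1^2 / (2 F2) is available.
#'
#' @param table a `count_table` of integer counts.
#' @param chao1 `"bias_corrected"` (default) or `"classic"`.
#' @return a data.frame with one row per sample: `sample_id`, `richness`,
#'   `chao1`, `shannon_exp`, `evenness`.
#' @export
alpha_diversity <- function(table, chao1 = c("bias_corrected", "classic")) {
  chao1 <- match.arg(chao1)
  m <- ct_counts(table)
  totals <- colSums(m)
  if (any(totals == 0))
    stop("empty sample(s): ", paste(colnames(m)[totals == 0], collapse = ", "))
  one <- function(x) {
    x <- x[x > 0]
    s <- length(x)
    p <- x / sum(x)
    h <- -sum(p * log(p))
    f1 <- sum(x == 1)
    f2 <- sum(x == 2)
    c1 <- if (chao1 == "bias_corrected") {
      s + f1 * (f1 - 1) / (2 * (f2 + 1))
    } else if (f2 > 0) {
      s + f1^2 / (2 * f2)
    } else {
      s + f1 * (f1 - 1) / 2
    }
    c(s, c1, exp(h), exp(h) / s)
  }
  res <- vapply(seq_len(ncol(m)), function(j) one(m[, j]), numeric(4))
  data.frame(sample_id = colnames(m), richness = res[1, ], chao1 = res[2, ],
             shannon_exp = res[3, ], evenness = res[4, ],
             stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity between samples
#'
#' d(x, y) = sum |x_t - y_t| / sum (x_t + y_t). The matching similarity used
#' for reporting is 1 - d (see [bc_similarity()]).
#'
#' @param table a `count_table` with at least two samples.
#' @return a symmetric sample-by-sample dissimilarity matrix with zero
#'   diagonal and entries in `[0, 1]`.
#' @export
bray_curtis <- function(table) {
  m <- ct_counts(table)
  if (ncol(m) < 2) stop("need at least two samples")
  zero <- colSums(m) == 0
  if (sum(zero) >= 2)
    stop("all-zero samples cannot be compared: ",
         paste(colnames(m)[zero], collapse = ", "))
  d <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  if (any(!is.finite(d))) stop("undefined Bray-Curtis distance")
  d
}

#' @rdname bray_curtis
#' @param d a Bray-Curtis dissimilarity matrix.
#' @return `bc_similarity()`: the matching similarity matrix 1 - d.
#' @export
bc_similarity <- function(d) {
  s <- 1 - as.matrix(d)
  diag(s) <- 1
  s
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centres -D^2 / 2 and eigendecomposes. Coordinates are returned for
#' axes with positive eigenvalues, scaled by the square root of the
#' eigenvalue; negative eigenvalues (possible for semimetric dissimilarities
#' such as Bray-Curtis) are reported rather than silently dropped. The
#' Lingoes correction (adding a constant to squared off-diagonal distances)
#' is available for fully Euclidean embeddings.
#'
#' @param d a symmetric dissimilarity matrix (or `dist`).
#' @param correction `"none"` (default) or `"lingoes"`.
#' @return a list of class `pcoa_result`: `coordinates` (samples x axes),
#'   `eigenvalues` (all, decreasing), `proportion_explained` (over positive
#'   eigenvalues).
#' @export
pcoa <- function(d, correction = c("none", "lingoes")) {
  correction <- match.arg(correction)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least two samples")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  if (correction == "lingoes") {
    a <- -0.5 * d^2
    g <- center_gower(a)
    ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
    c_l <- max(0, -min(ev))
    if (c_l > 0) {
      d2 <- d^2 + 2 * c_l
      diag(d2) <- 0
      d <- sqrt(d2)
    }
  }
  g <- center_gower(-0.5 * d^2)
  e <- eigen(g, symmetric = TRUE)
  ev <- e$values
  pos <- which(ev > max(ev[1], 0) * 1e-9)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(ev[pos]), length(pos))
  rownames(coords) <- rownames(d)
  if (length(pos)) colnames(coords) <- paste0("Axis.", seq_along(pos))
  structure(list(coordinates = coords,
                 eigenvalues = ev,
                 proportion_explained = ev[pos] / sum(ev[ev > 0])),
            class = "pcoa_result")
}

center_gower <- function(a) {
  rm <- rowMeans(a)
  cm <- colMeans(a)
  a - outer(rm, cm, function(x, y) x + y) + mean(a)
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- min(3, ncol(x$coordinates))
  cat("pcoa_result: ", nrow(x$coordinates), " samples, ",
      ncol(x$coordinates), " positive axes\n", sep = "")
  cat("proportion explained (first ", k, "): ",
      paste(sprintf("%.3f", x$proportion_explained[seq_len(k)]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

## pseudo-F for a labelling; d2 = squared distance matrix
permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  lv <- unique(groups)
  a <- length(lv)
  ss_total <- sum(d2) / (2 * n)
  ss_within <- 0
  for (g in lv) {
    idx <- which(groups == g)
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

#' One-way PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix
#' (Anderson's pseudo-F), with a free permutation of sample labels and
#' p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm).
#'
#' @param d distance matrix (or `dist`) over samples.
#' @param groups group label per sample (>= 2 groups of >= 2).
#' @param n_perm number of label permutations (default 9999).
#' @param seed optional RNG seed for reproducible permutations.
#' @return a list of class `permanova_result`: `pseudo_F`, `p_value`,
#'   `n_permutations`, `group_sizes`, `df`.
#' @export
permanova_oneway <- function(d, groups, n_perm = 9999, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (length(groups) != n) stop("groups must match the distance matrix")
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2))
    stop("group(s) with fewer than two samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  d2 <- d^2
  f_obs <- permanova_f(d2, groups)
  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    f_p <- permanova_f(d2, groups[sample.int(n)])
    if (f_p >= f_obs) exceed <- exceed + 1L
  }
  structure(list(pseudo_F = f_obs,
                 p_value = (1 + exceed) / (1 + n_perm),
                 n_permutations = n_perm,
                 group_sizes = as.integer(sizes),
                 df = c(length(sizes) - 1L, n - length(sizes))),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("one-way PERMANOVA: pseudo-F = %.4f (df %d, %d), p = %.4g (%d permutations)\n",
              x$pseudo_F, x$df[1], x$df[2], x$p_value, x$n_permutations))
  invisible(x)
}

#' SIMPER: taxon contributions to between-group Bray-Curtis dissimilarity
#'
#' For every between-group sample pair, the per-taxon contribution
#' |x_t - y_t| / sum_k (x_k + y_k) is computed (these sum over taxa to that
#' pair's Bray-Curtis dissimilarity), then averaged over pairs and expressed
#' as percentages of the average dissimilarity, sorted descending.
#'
#' @param table a `count_table`.
#' @param groups group label per sample; exactly two distinct labels.
#' @return a data.frame of class `simper_result`: `taxon_id`, `average`
#'   (mean contribution), `percent`, `cumulative_percent`; attribute
#'   `overall` holds the average between-group dissimilarity.
#' @export
simper_bc <- function(table, groups) {
  m <- ct_counts(table)
  groups <- as.character(groups)
  if (length(groups) != ncol(m)) stop("groups must match the samples")
  lv <- unique(groups)
  if (length(lv) != 2) stop("SIMPER requires exactly two groups")
  ia <- which(groups == lv[1])
  ib <- which(groups == lv[2])
  if (!length(ia) || !length(ib)) stop("empty group")
  contrib <- numeric(nrow(m))
  for (i in ia) {
    for (j in ib) {
      tot <- sum(m[, i]) + sum(m[, j])
      if (tot == 0) stop("pair of all-zero samples")
      contrib <- contrib + abs(m[, i] - m[, j]) / tot
    }
  }
  contrib <- contrib / (length(ia) * length(ib))
  ord <- order(contrib, decreasing = TRUE)
  out <- data.frame(taxon_id = rownames(m)[ord],
                    average = contrib[ord],
                    percent = 100 * contrib[ord] / sum(contrib),
                    stringsAsFactors = FALSE)
  out$cumulative_percent <- cumsum(out$percent)
  attr(out, "overall") <- sum(contrib)
  class(out) <- c("simper_result", "data.frame")
  out
}

#' Two-group comparison with data-driven test selection
#'
#' Mirrors common practice for alpha-diversity and similarity comparisons:
#' Shapiro-Wilk on both groups; if either departs from normality (p < alpha)
#' a Wilcoxon rank-sum test is used; otherwise an F-test of variances
#' decides between Welch's unequal-variance t-test (variance p < alpha) and
#' Student's t-test.
#'
#' @param values_a,values_b numeric vectors, each of length >= 3.
#' @param alpha decision level for the auxiliary tests (default 0.05).
#' @return a list of class `group_comparison`: `test` (one of
#'   `"student_t"`, `"welch_t"`, `"wilcoxon"`), `statistic`, `p_value`, and
#'   `path`, a data.frame recording each decision point.
#' @export
compare_groups <- function(values_a, values_b, alpha = 0.05) {
  if (length(values_a) < 3 || length(values_b) < 3)
    stop("each group needs at least three values")
  sw_a <- stats::shapiro.test(values_a)$p.value
  sw_b <- stats::shapiro.test(values_b)$p.value
  path <- data.frame(step = c("shapiro_a", "shapiro_b"),
                     p_value = c(sw_a, sw_b),
                     stringsAsFactors = FALSE)
  if (min(sw_a, sw_b) < alpha) {
    ht <- stats::wilcox.test(values_a, values_b, exact = FALSE)
    test <- "wilcoxon"
  } else {
    fv <- stats::var.test(values_a, values_b)
    path <- rbind(path, data.frame(step = "f_test", p_value = fv$p.value))
    if (fv$p.value < alpha) {
      ht <- stats::t.test(values_a, values_b, var.equal = FALSE)
      test <- "welch_t"
    } else {
      ht <- stats::t.test(values_a, values_b, var.equal = TRUE)
      test <- "student_t"
    }
  }
  structure(list(test = test,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 path = path),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g\n", x$test, x$statistic,
              x$p_value))
  invisible(x)
}

#' Fraction of a sample's taxa shared with a reference sample set
#'
#' The fraction of taxa present in the focal sample that are also present in
#' the union of the reference samples; the complementary fraction is the
#' focal sample's unique taxa.
#'
#' @param table a `count_table`.
#' @param focal_sample a single sample id with at least one nonzero taxon.
#' @param reference_samples one or more sample ids.
#' @return a list: `shared`, `unique`, `n_focal_taxa`.
#' @export
shared_asv_fraction <- function(table, focal_sample, reference_samples) {
  m <- ct_counts(table)
  ids <- c(focal_sample, reference_samples)
  missing <- setdiff(ids, colnames(m))
  if (length(missing))
    stop("unknown sample ids: ", paste(missing, collapse = ", "))
  focal <- rownames(m)[m[, focal_sample] > 0]
  if (!length(focal)) stop("focal sample has no taxa: ", focal_sample)
  ref <- rownames(m)[rowSums(m[, reference_samples, drop = FALSE] > 0) > 0]
  shared <- length(intersect(focal, ref)) / length(focal)
  list(shared = shared, unique = 1 - shared, n_focal_taxa = length(focal))
}
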