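#' Parse and write Newick trees
#'
#' Thin, validating wrappers around the ape Newick reader/writer. Parsing
#' requires balanced parentheses, unique tip labels, and branch lengths on
#' every edge; polytomies are preserved. `write_newick(parse_newick(s))`
#' round-trips up to whitespace.
#'
#' @param text a Newick string (terminated by `;`).
#' @return a rooted or unrooted `phylo` tree (ape).
#' @export
parse_newick <- function(text) {
  open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (open != close)
    stop("unbalanced parentheses in Newick: ", open, " '(' vs ", close, " ')'")
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("failed to parse Newick string")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length))
    stop("Newick tree lacks branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and nonnegative")
  tree
}

#' @rdname parse_newick
#' @param tree a `phylo` object.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' @rdname parse_newick
#' @param path file path.
#' @export
read_newick_file <- function(path) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Root a tree at the midpoint of its longest branch
#'
#' Finds the edge with the greatest length (ties broken by edge-matrix
#' traversal order, with a message) and reroots the tree at that edge's
#' midpoint. Tip-to-tip path lengths are unchanged by rooting.
#'
#' @param tree a `phylo` tree with branch lengths and >= 2 tips.
#' @return a rooted `phylo` tree.
#' @export
root_longest_branch <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree lacks branch lengths")
  if (length(tree$tip.label) < 2) stop("need at least two tips")
  len <- tree$edge.length
  longest <- which(len == max(len))
  if (length(longest) > 1)
    message("tie for longest branch among edges ",
            paste(longest, collapse = ", "), "; using the first")
  edge <- longest[1]
  child <- tree$edge[edge, 2]
  rooted <- phytools::reroot(tree, node.number = child,
                             position = len[edge] / 2)
  rooted
}

#' Cophenetic (tip-to-tip path length) distances
#'
#' @param tree a `phylo` tree with branch lengths.
#' @return a symmetric matrix of summed branch lengths between tips.
#' @export
cophenetic_distances <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree lacks branch lengths")
  if (any(is.na(tree$edge.length))) stop("missing branch length")
  d <- stats::cophenetic(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Pairwise niche distances from per-taxon trait values
#'
#' @param traits named numeric vector of per-taxon niche proxies.
#' @return symmetric matrix of absolute trait differences.
#' @export
niche_distance <- function(traits) {
  if (is.null(names(traits))) stop("traits must be named by taxon id")
  d <- abs(outer(traits, traits, "-"))
  dimnames(d) <- list(names(traits), names(traits))
  d
}

#' Mantel correlogram of niche versus phylogenetic distance
#'
#' Tests for phylogenetic signal in ecological differences — the assumption
#' licensing nearest-taxon null models. Phylogenetic distances are binned
#' into equal-width classes; per class a Mantel statistic correlates niche
#' distance with class membership, with permutation p-values under
#' progressive Holm correction (the behaviour of `vegan::mantel.correlog`,
#' which performs the computation).
#'
#' @param niche_dist,phylo_dist symmetric matrices sharing taxon ids.
#' @param n_classes number of distance classes (default: Sturges' rule).
#' @param n_perm permutations per class (default 999).
#' @param seed optional RNG seed.
#' @return a data.frame of class `mantel_correlogram`: `class_midpoint`,
#'   `n_pairs`, `mantel_r`, `p_value`, `p_corrected`; classes with too few
#'   pairs for a test are dropped with a message.
#' @export
mantel_correlogram <- function(niche_dist, phylo_dist, n_classes = NULL,
                               n_perm = 999, seed = NULL) {
  niche_dist <- as.matrix(niche_dist)
  phylo_dist <- as.matrix(phylo_dist)
  ids <- rownames(phylo_dist)
  if (is.null(ids) || is.null(rownames(niche_dist)))
    stop("both matrices must carry taxon ids")
  if (!setequal(ids, rownames(niche_dist)))
    stop("matrices cover different taxon sets")
  niche_dist <- niche_dist[ids, ids]
  if (!is.null(seed)) set.seed(seed)
  mc <- vegan::mantel.correlog(stats::as.dist(niche_dist),
                               stats::as.dist(phylo_dist),
                               n.class = if (is.null(n_classes)) 0 else n_classes,
                               nperm = n_perm, mult = "holm",
                               progressive = TRUE)
  res <- as.data.frame(mc$mantel.res)
  names(res) <- c("class_midpoint", "n_pairs", "mantel_r", "p_value",
                  "p_corrected")
  dropped <- is.na(res$mantel_r)
  if (any(dropped))
    message(sum(dropped), " distance class(es) without a testable Mantel ",
            "statistic dropped")
  res <- res[!dropped, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("mantel_correlogram", "data.frame")
  res
}
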