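#' Informative bipartitions (splits) of a tree
#'
#' Every internal edge of a tree partitions the leaves into two subsets.
#' Rooted trees are treated as unrooted: the root edge contributes at most
#' one split and duplicates are removed. Trivial splits (one side smaller
#' than 2 leaves) are excluded. Splits are returned in canonical form: a
#' logical matrix over the alphabetically sorted leaf labels, with each
#' row's `TRUE` side containing the lexicographically smallest label.
#'
#' @param tree an [ape::phylo] tree.
#' @return Logical matrix, one row per informative split, columns named by
#'   sorted leaf labels. Zero rows for star trees.
#' @export
tree_splits <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  nt <- length(tree$tip.label)
  labs <- sort(tree$tip.label)
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
  nnode <- tree$Nnode
  root <- nt + 1L
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  # tip membership of each node's clade, as logical over sorted labels
  clade <- matrix(FALSE, nt + nnode, nt)
  clade[cbind(seq_len(nt), match(tree$tip.label, labs))] <- TRUE
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, 1L]; ch <- edges[k, 2L]
    clade[p, ] <- clade[p, ] | clade[ch, ]
  }
  internal <- edges[edges[, 2L] > nt, 2L]
  if (length(internal) == 0L)
    return(matrix(FALSE, 0L, nt, dimnames = list(NULL, labs)))
  s <- clade[internal, , drop = FALSE]
  # canonical orientation: side holding the smallest label is TRUE
  flip <- !s[, 1L]
  s[flip, ] <- !s[flip, , drop = FALSE]
  sz <- rowSums(s)
  s <- s[sz >= 2L & (nt - sz) >= 2L, , drop = FALSE]
  s <- s[!duplicated(s), , drop = FALSE]
  colnames(s) <- labs
  rownames(s) <- NULL
  s
}

check_same_leaves <- function(t1, t2) {
  l1 <- sort(t1$tip.label); l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    d <- union(setdiff(l1, l2), setdiff(l2, l1))
    stop("leaf sets differ; unmatched labels: ", paste(d, collapse = ", "))
  }
}

#' Robinson-Foulds symmetric distance
#'
#' The number of informative splits present in exactly one of the two trees
#' (the size of the symmetric difference of their split sets). Zero for
#' topologically identical trees; at most `2(n - 3)` for two binary trees
#' on `n` shared leaves.
#'
#' @param t1,t2 [ape::phylo] trees on the same leaf set.
#' @return A nonnegative integer.
#' @export
rf_distance <- function(t1, t2) {
  check_same_leaves(t1, t2)
  s1 <- tree_splits(t1); s2 <- tree_splits(t2)
  k1 <- apply(s1, 1L, paste, collapse = "")
  k2 <- apply(s2, 1L, paste, collapse = "")
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Edge-matching topology similarity between two trees
#'
#' A global similarity score in `[0, 1]` built by aligning the edges of the
#' two trees, following the Nye et al. tree-comparison method (the approach
#' behind PhyloCore-style scores): every edge pair (one edge per tree) is
#' scored by the better of the two ways of pairing up their leaf-set sides,
#' each side pair scored by Jaccard overlap and the edge pair taking the
#' worse of its two sides; a maximum-weight one-to-one matching between the
#' two edge sets is then computed (Hungarian algorithm) and the total
#' matched score is normalised by the larger edge count. Identical
#' topologies score exactly 1; trees sharing no internal split still get
#' partial credit for near-matching clusters, which makes the score far
#' less brittle than Robinson-Foulds on large trees.
#'
#' With `edges = "all"` (the default, matching the published edge-alignment
#' method) pendant edges participate: each contributes its singleton split,
#' which matches its counterpart in the other tree perfectly, so two trees
#' on `n` leaves always share a floor of agreement and the score reflects
#' whole-tree edge correspondence. With `edges = "internal"` only
#' informative splits are aligned, a stricter variant: then a pair of
#' star trees scores 1 and a star against a resolved tree scores 0.
#'
#' @param t1,t2 [ape::phylo] trees on the same leaf set.
#' @param edges `"all"` (pendant + internal, deduplicated) or
#'   `"internal"` (informative splits only).
#' @return A scalar in `[0, 1]`.
#' @export
topology_similarity <- function(t1, t2, edges = c("all", "internal")) {
  edges <- match.arg(edges)
  check_same_leaves(t1, t2)
  if (edges == "all") {
    s1 <- all_splits(t1); s2 <- all_splits(t2)
  } else {
    s1 <- tree_splits(t1); s2 <- tree_splits(t2)
  }
  e1 <- nrow(s1); e2 <- nrow(s2)
  if (e1 == 0L && e2 == 0L) return(1)
  if (e1 == 0L || e2 == 0L) return(0)
  sc <- split_pair_scores(s1, s2)
  k <- max(e1, e2)
  cost <- matrix(0, k, k)
  cost[seq_len(e1), seq_len(e2)] <- -sc
  match_col <- hungarian_assignment(cost)
  total <- 0
  for (i in seq_len(e1)) {
    j <- match_col[i]
    if (j <= e2) total <- total + sc[i, j]
  }
  total / k
}

# all edges as canonical splits: pendant singletons plus informative
# internal splits, deduplicated (the two root edges of a rooted tree are one
# unrooted edge and collapse here)
all_splits <- function(tree) {
  s <- tree_splits(tree)
  n <- ncol(s)
  labs <- colnames(s)
  pend <- matrix(TRUE, n, n, dimnames = list(NULL, labs))
  pend[cbind(2:n, 2:n)] <- FALSE        # canonical: side with smallest label
  pend[1, ] <- c(TRUE, rep(FALSE, n - 1L))
  out <- rbind(pend, s)
  out[!duplicated(out), , drop = FALSE]
}

# Jaccard-based edge-pair score matrix between two canonical split sets
split_pair_scores <- function(s1, s2) {
  n <- ncol(s1)
  e1 <- nrow(s1); e2 <- nrow(s2)
  A1 <- matrix(rowSums(s1), e1, e2)
  A2 <- matrix(rowSums(s2), e1, e2, byrow = TRUE)
  iAA <- s1 %*% t(s2)                      # |A1 n A2|
  jAA <- iAA / (A1 + A2 - iAA)
  jBB <- (n - A1 - A2 + iAA) / (n - iAA)   # |B1 n B2| / |B1 u B2|
  p1 <- pmin(jAA, jBB)
  jAB <- (A1 - iAA) / (n - A2 + iAA)       # A1 paired with B2
  jBA <- (A2 - iAA) / (n - A1 + iAA)       # B1 paired with A2
  p2 <- pmin(jAB, jBA)
  pmax(p1, p2)
}
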