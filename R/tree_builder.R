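#' Distance-based tree inference
#'
#' Builds a phylogenetic tree from a symmetric distance matrix by neighbor
#' joining (Saitou-Nei Q-criterion; unrooted; negative intermediate branch
#' lengths clamped to 0) or by UPGMA (average-linkage agglomeration with
#' node heights at half the cluster distance; rooted and ultrametric).
#'
#' @param m symmetric numeric matrix with zero diagonal and labels as
#'   `dimnames` (as produced by [compression_matrix()] or
#'   [evolutionary_matrix()]).
#' @param method `"nj"` or `"upgma"`.
#' @return An [ape::phylo] tree; unrooted for NJ, rooted ultrametric for
#'   UPGMA.
#' @examples
#' m <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' build_tree(m, "upgma")
#' @export
build_tree <- function(m, method = c("nj", "upgma")) {
  method <- match.arg(method)
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || nrow(m) < 3L) stop("need a square matrix, n >= 3")
  if (any(is.na(m)) || any(!is.finite(m))) stop("NA/NaN/Inf in distance matrix")
  if (max(abs(m - t(m))) > 1e-8) stop("distance matrix is not symmetric")
  if (is.null(rownames(m))) stop("distance matrix must carry labels")
  if (method == "nj") {
    t <- ape::nj(as.dist(m))
    neg <- t$edge.length < 0
    if (any(neg)) t$edge.length[neg] <- 0
    t
  } else {
    h <- hclust(as.dist(m), method = "average")
    t <- ape::as.phylo(h)
    # as.phylo(hclust) uses height/2 per branch, i.e. ultrametric heights
    t
  }
}

#' Read and write Newick tree files
#'
#' Thin wrappers around the `ape` Newick parser/serialiser so trees created
#' by the package round-trip on topology, labels and branch lengths.
#'
#' @param text a Newick string (terminated by `;`).
#' @param tree an [ape::phylo] tree.
#' @return `read_newick` returns a `phylo`; `write_newick` a Newick string.
#' @export
read_newick <- function(text) {
  t <- tryCatch(ape::read.tree(text = text),
                error = function(e) stop("Newick parse error: ",
                                         conditionMessage(e)))
  if (is.null(t)) stop("Newick parse error in: ", substr(text, 1, 60))
  t
}

#' @rdname read_newick
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}
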