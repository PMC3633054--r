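#' Normalized Compression Distance between two sequences
#'
#' `ncd(x, y) = (C(xy) - min(C(x), C(y))) / max(C(x), C(y))`, where `C(.)`
#' is the compressed size from [compress_size()]. Values are near 0 for
#' near-identical strings and near 1 (slightly above is possible) for
#' unrelated strings. Gap characters are stripped before compression.
#'
#' @param x,y non-empty DNA strings.
#' @param symmetrize average the two argument orders (the raw value is not
#'   exactly symmetric because `C(xy) != C(yx)`); default `TRUE`.
#' @return A nonnegative scalar.
#' @seealso [ibd()], [compression_matrix()]
#' @export
ncd <- function(x, y, symmetrize = TRUE) {
  x <- strip_gaps(check_dna_arg(x)); y <- strip_gaps(check_dna_arg(y))
  cx <- compress_size(x); cy <- compress_size(y)
  if (max(cx, cy) <= 0) stop("degenerate compressor output")
  v <- (concat_size(x, y) - min(cx, cy)) / max(cx, cy)
  if (symmetrize)
    v <- (v + (concat_size(y, x) - min(cx, cy)) / max(cx, cy)) / 2
  v
}

#' Information-Based Distance between two sequences
#'
#' `ibd(x, y) = 1 - (C(x) - C(x|y)) / C(xy)`, using the conditional
#' compressed size `C(x|y)` from [conditional_size()]. When `y` carries no
#' information about `x` the numerator vanishes and the distance approaches
#' 1; when `x = y` the conditional size collapses and the distance is small.
#'
#' @inheritParams ncd
#' @return A scalar, finite and at most slightly above 1.
#' @seealso [ncd()], [compression_matrix()]
#' @export
ibd <- function(x, y, symmetrize = TRUE) {
  x <- strip_gaps(check_dna_arg(x)); y <- strip_gaps(check_dna_arg(y))
  one <- function(a, b) {
    cab <- concat_size(a, b)
    if (cab <= 0) stop("degenerate compressor output")
    1 - (compress_size(a) - conditional_size(a, b)) / cab
  }
  if (symmetrize) (one(x, y) + one(y, x)) / 2 else one(x, y)
}

#' All-pairs compression distance matrix
#'
#' Evaluates [ncd()] or [ibd()] on every unordered pair of a sequence set and
#' returns a symmetric matrix with zero diagonal (self-distances are forced
#' to 0, as tree building requires, even though the raw self-NCD is a small
#' positive number). Gaps are stripped, so aligned and unaligned input give
#' the same result — the method is alignment-free.
#'
#' @param set a [seq_set] with at least 3 sequences.
#' @param method `"ncd"` or `"ibd"`.
#' @return A symmetric numeric matrix with `dimnames` from the labels and
#'   attribute `method`.
#' @export
compression_matrix <- function(set, method = c("ncd", "ibd")) {
  stopifnot(inherits(set, "seq_set"))
  method <- match.arg(method)
  n <- length(set)
  if (n < 3L) stop("need at least 3 sequences for a distance matrix")
  seqs <- strip_gaps(set$residues)
  plain <- vapply(seqs, lz_parse_bits, numeric(1), dict_len = 0L)
  m <- matrix(0, n, n, dimnames = list(set$labels, set$labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      x <- seqs[[i]]; y <- seqs[[j]]
      cx <- plain[[i]]; cy <- plain[[j]]
      cxy <- lz_parse_bits(paste0(x, y), 0L)
      cyx <- lz_parse_bits(paste0(y, x), 0L)
      if (method == "ncd") {
        v <- ((cxy - min(cx, cy)) / max(cx, cy) +
              (cyx - min(cx, cy)) / max(cx, cy)) / 2
      } else {
        cx_y <- lz_parse_bits(paste0(y, x), nchar(y))
        cy_x <- lz_parse_bits(paste0(x, y), nchar(x))
        v <- ((1 - (cx - cx_y) / cxy) + (1 - (cy - cy_x) / cyx)) / 2
      }
      m[i, j] <- m[j, i] <- v
    }
  }
  attr(m, "method") <- toupper(method)
  m
}
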