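#' Compressed size of a DNA string
#'
#' Deterministic size, in bits, of a greedy LZ (dictionary) parse of `x`:
#' the longest match against the already-emitted prefix is taken at each
#' position (minimum match length 4, ties broken by smallest offset, matches
#' may overlap the current position). An `A`/`C`/`G`/`T` literal costs
#' 1 flag + 2 payload bits; any other byte is escaped at 1 flag + 1 escape +
#' 8 payload bits, so non-nucleotide text degrades to generic byte coding;
#' a match costs 1 flag + Elias-gamma(offset) + Elias-gamma(length) bits.
#' Only sizes are computed, no bitstream is produced.
#'
#' These three functionals — `compress_size(x)`, `concat_size(x, y)` (the
#' parse of the concatenation `xy`) and `conditional_size(x, y)` (the parse
#' of `x` with the match dictionary preloaded from `y`, counting only `x`'s
#' tokens) — are the C(x), C(xy) and C(x|y) from which the compression
#' distances [ncd()] and [ibd()] are built. Sizes are kept in bits; the
#' distances are ratios of sizes, so the unit cancels.
#'
#' @param x,y non-empty character strings (uppercased internally).
#' @return Size in bits (a positive scalar).
#' @examples
#' compress_size(strrep("ACGT", 100))
#' concat_size("ACGTACGTAC", "ACGTACGTAC")
#' conditional_size("ACGTACGTAC", "ACGTACGTAC")
#' @export
compress_size <- function(x) {
  x <- check_dna_arg(x)
  lz_parse_bits(x, 0L)
}

#' @rdname compress_size
#' @export
concat_size <- function(x, y) {
  x <- check_dna_arg(x); y <- check_dna_arg(y)
  lz_parse_bits(paste0(x, y), 0L)
}

#' @rdname compress_size
#' @export
conditional_size <- function(x, y) {
  x <- check_dna_arg(x); y <- check_dna_arg(y)
  lz_parse_bits(paste0(y, x), nchar(y))
}

check_dna_arg <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop("input must be a single non-empty string")
  toupper(x)
}
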