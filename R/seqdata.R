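#' Construct a sequence set
#'
#' A `seq_set` is an ordered collection of labelled DNA sequences, the basic
#' container of the package. Sequences are stored as uppercase character
#' strings; any IUPAC code (including `N` and the gap character `-`) is
#' accepted. The set is flagged as aligned when all residue strings have
#' identical length.
#'
#' @param residues character vector of sequences; names are used as labels
#'   when `labels` is not given.
#' @param labels character vector of unique, non-empty sequence labels.
#' @param species optional character vector assigning a taxon to each
#'   sequence (unused by the core pipeline).
#' @return An object of class `seq_set`: a list with elements `labels`,
#'   `residues` (named character), `species` (or `NULL`) and `is_aligned`.
#' @examples
#' s <- seq_set(c(a = "ACGT", b = "ACGA"))
#' s$is_aligned
#' @export
seq_set <- function(residues, labels = names(residues), species = NULL) {
  if (length(residues) == 0L) stop("a seq_set needs at least one sequence")
  force(labels)  # resolve before toupper() strips the names
  residues <- toupper(as.character(residues))
  if (is.null(labels)) stop("sequence labels are required")
  labels <- as.character(labels)
  if (length(labels) != length(residues))
    stop("labels and residues differ in length")
  if (any(!nzchar(labels))) stop("empty sequence label")
  dup <- labels[duplicated(labels)]
  if (length(dup))
    stop("duplicate sequence label(s): ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(residues))) stop("empty sequence in set")
  if (!is.null(species)) {
    species <- as.character(species)
    if (length(species) != length(residues))
      stop("species vector must match the number of sequences")
    names(species) <- labels
  }
  names(residues) <- labels
  structure(
    list(labels = labels, residues = residues, species = species,
         is_aligned = length(unique(nchar(residues))) == 1L),
    class = "seq_set")
}

#' @export
print.seq_set <- function(x, ...) {
  cat("seq_set:", length(x$labels), "sequences,",
      if (x$is_aligned) paste0("aligned (", nchar(x$residues[[1]]), " bp)")
      else paste0("unaligned (", min(nchar(x$residues)), "-",
                  max(nchar(x$residues)), " bp)"), "\n")
  show <- head(x$labels, 5L)
  for (l in show) cat("  ", l, " [", nchar(x$residues[[l]]), " bp]\n", sep = "")
  if (length(x$labels) > 5L) cat("  ...\n")
  invisible(x)
}

#' @export
length.seq_set <- function(x) length(x$labels)

#' Read a FASTA file into a sequence set
#'
#' Wrapped or single-line multi-record FASTA is accepted. Record IDs (the
#' header up to the first whitespace by default, or the full header) become
#' labels. Optionally a species field is parsed from the header by splitting
#' on a delimiter.
#'
#' @param path path to a FASTA file.
#' @param species_delim optional single-character delimiter; when given, the
#'   label is split on it and the second field is taken as the species.
#' @return A [seq_set].
#' @export
read_fasta <- function(path, species_delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("no FASTA records in ", path)
  labels <- names(recs)
  residues <- as.character(recs)
  species <- NULL
  if (!is.null(species_delim)) {
    parts <- strsplit(labels, species_delim, fixed = TRUE)
    species <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else NA_character_,
                      character(1))
  }
  seq_set(residues, labels = labels, species = species)
}

#' Write a sequence set to FASTA
#'
#' @param set a [seq_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(set, path) {
  stopifnot(inherits(set, "seq_set"))
  x <- Biostrings::BStringSet(set$residues)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Dataset quality report
#'
#' Summarises a barcode dataset the way datasets are screened before
#' compression-based analysis: the fraction of sequences containing undefined
#' bases (any character outside `A`, `C`, `G`, `T`, including `N`, other IUPAC
#' ambiguity codes and gaps) and the range of ungapped sequence lengths.
#' Dictionary compression of DNA is only effective on the four-letter
#' alphabet, so datasets with many undefined bases compress poorly and yield
#' unreliable compression distances.
#'
#' @param set a [seq_set].
#' @return An object of class `qc_report`: list with `n_species` (`NA` when no
#'   species metadata is present), `n_specimens`, `pct_with_undefined`
#'   (percentage in `[0, 100]`), `min_length` and `max_length` (bp, gaps
#'   excluded).
#' @examples
#' s <- seq_set(c(a = "ACGT", b = "ACNT"))
#' dataset_qc(s)
#' @export
dataset_qc <- function(set) {
  stopifnot(inherits(set, "seq_set"))
  if (length(set) == 0L) stop("empty sequence set")
  undef <- grepl("[^ACGT]", set$residues)
  ungapped <- nchar(gsub("-", "", set$residues, fixed = TRUE))
  structure(
    list(n_species = if (is.null(set$species)) NA_integer_
         else length(unique(set$species[!is.na(set$species)])),
         n_specimens = length(set),
         pct_with_undefined = 100 * mean(undef),
         min_length = min(ungapped),
         max_length = max(ungapped)),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("n_species\tn_specimens\tpct_with_undefined\tlength_range\n")
  cat(x$n_species, "\t", x$n_specimens, "\t",
      sprintf("%.1f%%", x$pct_with_undefined), "\t",
      x$min_length, "-", x$max_length, "\n", sep = "")
  invisible(x)
}

# gap-stripped raw residues, the compressor's input
strip_gaps <- function(residues) gsub("-", "", residues, fixed = TRUE)
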