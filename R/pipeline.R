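#' Compare compression-based and evolutionary trees for one dataset
#'
#' The core comparison of the package, run once per replicate: a
#' compression distance matrix (on the raw, gap-stripped sequences) and an
#' evolutionary distance matrix (on the alignment) are each turned into a
#' tree with the same algorithm, and the two trees are scored with
#' [topology_similarity()].
#'
#' @param seqs an aligned [seq_set] (simulated sequences are born aligned;
#'   real data must be pre-aligned).
#' @param comp_method `"ncd"` or `"ibd"`.
#' @param evo_model one of `"k2p"`, `"tajima_nei"`, `"tamura3"`, `"tn93"`,
#'   `"mcl"`.
#' @param algo `"nj"` or `"upgma"`.
#' @return The topology-similarity score in `[0, 1]`, with the two trees
#'   attached as attributes `comp_tree` and `evo_tree`. A saturated
#'   (inestimable) evolutionary distance raises a
#'   `barcodecmp_inestimable` condition, which [run_simulation_study()]
#'   turns into a skipped replicate.
#' @export
run_replicate <- function(seqs, comp_method = "ncd", evo_model = "k2p",
                          algo = "nj") {
  cm <- compression_matrix(seqs, comp_method)
  em <- evolutionary_matrix(seqs, evo_model)
  ct <- build_tree(cm, algo)
  et <- build_tree(em, algo)
  s <- topology_similarity(ct, et)
  attr(s, "comp_tree") <- ct
  attr(s, "evo_tree") <- et
  s
}

#' Run the replicated simulation study
#'
#' Simulates `config$n_replicates` barcode datasets (see
#' [simulate_dataset()]) and, for every combination of compression
#' distance, evolutionary model and tree algorithm, scores the topology
#' similarity between the compression-based and the evolutionary tree of
#' each replicate. Distance matrices and trees are computed once per
#' replicate and shared across combinations. Replicates whose evolutionary
#' distances are inestimable (saturated pairs) are skipped for that model
#' with a logged warning; a cell with more than 20% skipped replicates is
#' flagged unreliable.
#'
#' @param config a [sim_config].
#' @param comp_methods subset of `c("ncd", "ibd")`.
#' @param evo_models subset of
#'   `c("k2p", "tajima_nei", "tamura3", "tn93", "mcl")`.
#' @param algos subset of `c("nj", "upgma")`.
#' @param replicates optional pre-generated `sim_replicates` object (so
#'   several studies can share one set of simulations); defaults to
#'   `simulate_dataset(config)`.
#' @return A `similarity_table`: a data frame with one row per
#'   (n_sequences, comp, model, algo) cell carrying the mean and variance
#'   of the similarity over replicates, the replicate counts, and an
#'   `unreliable` flag.
#' @export
run_simulation_study <- function(config, comp_methods = "ncd",
                                 evo_models = "k2p",
                                 algos = c("nj", "upgma"),
                                 replicates = NULL) {
  stopifnot(inherits(config, "sim_config"))
  comp_methods <- match.arg(comp_methods, c("ncd", "ibd"), several.ok = TRUE)
  evo_models <- match.arg(evo_models,
                          c("k2p", "tajima_nei", "tamura3", "tn93", "mcl"),
                          several.ok = TRUE)
  algos <- match.arg(algos, c("nj", "upgma"), several.ok = TRUE)
  if (is.null(replicates)) replicates <- simulate_dataset(config)
  n_seq <- config$n_species * config$individuals_per_species
  scores <- list()  # scores[[cell]] = numeric vector over replicates
  skipped <- integer(0)
  for (r in seq_along(replicates)) {
    seqs <- replicates[[r]]$sequences
    comp_trees <- list()
    for (cmp in comp_methods) {
      m <- compression_matrix(seqs, cmp)
      for (al in algos) comp_trees[[paste(cmp, al)]] <- build_tree(m, al)
    }
    for (mod in evo_models) {
      em <- tryCatch(evolutionary_matrix(seqs, mod),
                     barcodecmp_inestimable = function(e) e)
      if (inherits(em, "condition")) {
        warning("replicate ", r, ", model ", mod, " skipped: ",
                conditionMessage(em), call. = FALSE)
        for (al in algos) for (cmp in comp_methods) {
          cell <- paste(cmp, mod, al)
          skipped[cell] <- (if (is.na(skipped[cell][1L])) 0L
                            else skipped[[cell]]) + 1L
        }
        next
      }
      for (al in algos) {
        et <- build_tree(em, al)
        for (cmp in comp_methods) {
          cell <- paste(cmp, mod, al)
          s <- topology_similarity(comp_trees[[paste(cmp, al)]], et)
          scores[[cell]] <- c(scores[[cell]], s)
        }
      }
    }
  }
  rows <- expand.grid(comp = comp_methods, model = evo_models, algo = algos,
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    cell <- paste(rows$comp[i], rows$model[i], rows$algo[i])
    v <- scores[[cell]]
    nsk <- if (is.na(skipped[cell][1L])) 0L else skipped[[cell]]
    data.frame(n_sequences = n_seq, comp = toupper(rows$comp[i]),
               model = rows$model[i], algo = toupper(rows$algo[i]),
               mean = if (length(v)) mean(v) else NA_real_,
               variance = if (length(v) > 1L) var(v) else NA_real_,
               n_replicates = length(v), n_skipped = nsk,
               unreliable = nsk > 0.2 * (length(v) + nsk))
  }))
  class(out) <- c("similarity_table", "data.frame")
  attr(out, "config") <- config
  out
}

#' @export
print.similarity_table <- function(x, ...) {
  cat("Topology similarity over", max(x$n_replicates + x$n_skipped),
      "replicates (", x$n_sequences[1L], "sequences )\n")
  df <- as.data.frame(x)
  df$mean <- sprintf("%.3f", df$mean)
  df$variance <- sprintf("%.2e", df$variance)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Serialise a similarity table
#'
#' Writes a [run_simulation_study()] table as TSV and/or JSON, with the
#' similarity reported both as a fraction (`mean`) and as a percentage
#' (`mean_pct`).
#'
#' @param x a `similarity_table`.
#' @param tsv,json output paths; either may be `NULL` to skip. JSON output
#'   requires the `jsonlite` package.
#' @return `x`, invisibly.
#' @export
write_similarity_table <- function(x, tsv = NULL, json = NULL) {
  stopifnot(inherits(x, "similarity_table"))
  df <- as.data.frame(x)
  df$mean_pct <- 100 * df$mean
  if (!is.null(tsv))
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("JSON output requires the jsonlite package")
    jsonlite::write_json(df, json, dataframe = "rows", digits = NA)
  }
  invisible(x)
}

#' Analyse one real (pre-aligned) barcode dataset
#'
#' Runs the full comparison grid on a single dataset supplied both raw
#' (for compression distances) and aligned (for evolutionary distances):
#' quality report, then topology similarity for every combination of
#' compression distance, evolutionary model and tree algorithm. A dataset
#' whose sequences frequently contain undefined bases triggers a warning,
#' since dictionary compression degrades on non-ACGT text and the
#' compression distances become unreliable.
#'
#' @param raw a [seq_set] (or FASTA path) with the unaligned barcode
#'   sequences.
#' @param aligned a [seq_set] (or FASTA path) with the same sequences
#'   aligned; labels must match `raw`.
#' @param evo_models,algos,comp_methods combinations to evaluate (defaults:
#'   all five models, both algorithms, both compression distances).
#' @param qc_warn_pct warn when the percentage of sequences with undefined
#'   bases exceeds this (default 30).
#' @return A list with `qc` (the [dataset_qc()] report) and `scores` (a
#'   data frame of similarity scores, as fraction and percentage).
#' @export
run_real_dataset <- function(raw, aligned,
                             evo_models = c("k2p", "tajima_nei", "tamura3",
                                            "tn93", "mcl"),
                             algos = c("nj", "upgma"),
                             comp_methods = c("ncd", "ibd"),
                             qc_warn_pct = 30) {
  if (is.character(raw)) raw <- read_fasta(raw)
  if (is.character(aligned)) aligned <- read_fasta(aligned)
  stopifnot(inherits(raw, "seq_set"), inherits(aligned, "seq_set"))
  if (!setequal(raw$labels, aligned$labels))
    stop("label mismatch between raw and aligned input")
  if (!aligned$is_aligned) stop("aligned input has unequal lengths")
  qc <- dataset_qc(raw)
  if (qc$pct_with_undefined > qc_warn_pct)
    warning(sprintf(paste0("%.1f%% of sequences contain undefined bases; ",
                           "compression distances degrade on non-ACGT ",
                           "input and tree similarity is expected to drop"),
                    qc$pct_with_undefined), call. = FALSE)
  comp_trees <- list()
  for (cmp in comp_methods) {
    m <- compression_matrix(raw, cmp)
    for (al in algos) comp_trees[[paste(cmp, al)]] <- build_tree(m, al)
  }
  rows <- list()
  for (mod in evo_models) {
    em <- evolutionary_matrix(aligned, mod)
    for (al in algos) {
      et <- build_tree(em, al)
      for (cmp in comp_methods) {
        s <- topology_similarity(comp_trees[[paste(cmp, al)]], et)
        rows[[length(rows) + 1L]] <-
          data.frame(comp = toupper(cmp), model = mod, algo = toupper(al),
                     similarity = s, similarity_pct = 100 * s)
      }
    }
  }
  list(qc = qc, scores = do.call(rbind, rows))
}
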