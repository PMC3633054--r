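# shared fixtures and small independent oracles

random_dna <- function(n, freqs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freqs),
        collapse = "")
}

# mutate a pair of sequences apart with a TN93 transition matrix; returns the
# two descendant strings of a common ancestor at total divergence d
tn93_pair <- function(d, len, freqs = c(0.3, 0.2, 0.2, 0.3),
                      kappa1 = 6.25, kappa2 = 6.25) {
  P <- tn93_prob_matrix(d / 2, freqs, kappa1, kappa2)
  root <- sample.int(4L, len, replace = TRUE, prob = freqs)
  draw <- function(parent) {
    out <- integer(len)
    for (s in 1:4) {
      idx <- which(parent == s)
      if (length(idx))
        out[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[s, ])
    }
    out
  }
  bases <- c("A", "C", "G", "T")
  c(paste(bases[draw(root)], collapse = ""),
    paste(bases[draw(root)], collapse = ""))
}

# ape's pairwise distance on two plain strings, as an independent reference
ape_pair_dist <- function(a, b, model) {
  x <- ape::as.DNAbin(strsplit(tolower(c(a = a, b = b)), ""))
  as.numeric(ape::dist.dna(x, model = model, pairwise.deletion = TRUE))
}

# brute-force maximum-weight one-to-one matching over two split sets,
# normalised like topology_similarity
brute_match_similarity <- function(s1, s2) {
  sc <- barcodecmp:::split_pair_scores(s1, s2)
  e1 <- nrow(s1); e2 <- nrow(s2)
  if (e1 > e2) { sc <- t(sc); tmp <- e1; e1 <- e2; e2 <- tmp }
  best <- 0
  rec <- function(i, avail, acc) {
    if (i > e1) { best <<- max(best, acc); return(invisible()) }
    # allow leaving edge i unmatched too
    rec(i + 1L, avail, acc)
    for (j in avail) rec(i + 1L, setdiff(avail, j), acc + sc[i, j])
  }
  rec(1L, seq_len(e2), 0)
  best / max(e1, e2)
}

brute_similarity <- function(t1, t2, edges = "all") {
  g <- if (edges == "all") barcodecmp:::all_splits else tree_splits
  s1 <- g(t1); s2 <- g(t2)
  if (nrow(s1) == 0L && nrow(s2) == 0L) return(1)
  if (nrow(s1) == 0L || nrow(s2) == 0L) return(0)
  brute_match_similarity(s1, s2)
}

# a labelled random binary tree
rand_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ape::rtree(n, tip.label = paste0("t", seq_len(n)))
}
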