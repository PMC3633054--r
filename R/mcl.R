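#' TN93 transition probability matrix
#'
#' Closed-form `P(d) = exp(Q d)` for the Tamura-Nei substitution model with
#' purine-transition/transversion and pyrimidine-transition/transversion
#' rate ratios `kappa1` (A/G) and `kappa2` (C/T), stationary frequencies
#' `freqs`, and the rate matrix normalised so that `d` is in expected
#' substitutions per site. Base order is A, C, G, T. Setting
#' `kappa1 = kappa2` gives the HKY model.
#'
#' @param d branch length, expected substitutions per site (scalar >= 0).
#' @param freqs stationary base frequencies, length 4 (A, C, G, T), summing
#'   to 1.
#' @param kappa1,kappa2 transition/transversion rate ratios for A/G and C/T.
#' @return A 4x4 stochastic matrix.
#' @export
tn93_prob_matrix <- function(d, freqs, kappa1, kappa2) {
  stopifnot(d >= 0, length(freqs) == 4L, abs(sum(freqs) - 1) < 1e-8,
            kappa1 > 0, kappa2 > 0)
  pA <- freqs[[1L]]; pC <- freqs[[2L]]; pG <- freqs[[3L]]; pT <- freqs[[4L]]
  pR <- pA + pG; pY <- pC + pT
  # transversion rate beta scaled for mean rate 1
  beta <- 1 / (2 * (kappa1 * pA * pG + kappa2 * pC * pT + pR * pY))
  aR <- kappa1 * beta   # A<->G transition rate factor
  aY <- kappa2 * beta   # C<->T
  eb <- exp(-beta * d)
  eR <- exp(-(pY * beta + pR * aR) * d)
  eY <- exp(-(pR * beta + pY * aY) * d)
  P <- matrix(0, 4L, 4L, dimnames = list(DNA_BASES, DNA_BASES))
  # purine block (A, G)
  P["A", "A"] <- pA + pA * pY / pR * eb + pG / pR * eR
  P["A", "G"] <- pG + pG * pY / pR * eb - pG / pR * eR
  P["G", "G"] <- pG + pG * pY / pR * eb + pA / pR * eR
  P["G", "A"] <- pA + pA * pY / pR * eb - pA / pR * eR
  # pyrimidine block (C, T)
  P["C", "C"] <- pC + pC * pR / pY * eb + pT / pY * eY
  P["C", "T"] <- pT + pT * pR / pY * eb - pT / pY * eY
  P["T", "T"] <- pT + pT * pR / pY * eb + pC / pY * eY
  P["T", "C"] <- pC + pC * pR / pY * eb - pC / pY * eY
  # transversions
  for (i in c("A", "G")) for (j in c("C", "T"))
    P[i, j] <- freqs[[match(j, DNA_BASES)]] * (1 - eb)
  for (i in c("C", "T")) for (j in c("A", "G"))
    P[i, j] <- freqs[[match(j, DNA_BASES)]] * (1 - eb)
  P
}

# composite log-likelihood of one pair's ordered 4x4 count matrix N at
# distance d under TN93(freqs, kappa1, kappa2); reversibility makes the
# orientation irrelevant
pair_loglik <- function(d, N, freqs, kappa1, kappa2) {
  P <- tn93_prob_matrix(d, freqs, kappa1, kappa2)
  M <- freqs * P  # pi_i * P_ij
  idx <- N > 0
  sum(N[idx] * log(pmax(M[idx], 1e-300)))
}

#' Maximum composite likelihood distance matrix
#'
#' Estimates all pairwise distances and the shared Tamura-Nei substitution
#' parameters jointly, by maximising the sum over pairs of the
#' log-likelihood of each pair's 4x4 site-pattern count matrix under the
#' TN93 transition-probability model at that pair's distance. Base
#' frequencies are pooled over the whole alignment; the two rate ratios are
#' common to all pairs. The optimiser alternates per-pair distance updates
#' (one-dimensional maximisation) with shared rate-ratio updates until the
#' composite log-likelihood improves by less than `tol` (default 1e-8), up
#' to `max_iter` sweeps.
#'
#' @param set an aligned [seq_set] with at least 3 sequences.
#' @param tol convergence tolerance on the composite log-likelihood.
#' @param max_iter maximum number of alternation sweeps.
#' @param d_max upper bound of the per-pair distance search interval.
#' @return A symmetric distance matrix with attributes `method = "MCL"` and
#'   `params` (estimated `kappa1`, `kappa2`, pooled `freqs`, sweeps used,
#'   final composite log-likelihood).
#' @export
mcl_matrix <- function(set, tol = 1e-8, max_iter = 500L, d_max = 10) {
  stopifnot(inherits(set, "seq_set"))
  if (!set$is_aligned) stop("MCL requires aligned input")
  n <- length(set)
  if (n < 3L) stop("need at least 3 sequences for a distance matrix")
  ints <- lapply(set$residues, dna_to_int)
  # pooled base frequencies over all defined sites
  allb <- tabulate(unlist(ints), nbins = 4L)
  freqs <- allb / sum(allb)
  pairs <- utils::combn(n, 2L)
  npair <- ncol(pairs)
  counts <- vector("list", npair)
  d <- numeric(npair)
  for (k in seq_len(npair)) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    ia <- ints[[i]]; ib <- ints[[j]]
    keep <- ia > 0L & ib > 0L
    if (!any(keep)) stop("no comparable sites for pair ", i, ",", j)
    N <- matrix(tabulate((ia[keep] - 1L) * 4L + ib[keep], nbins = 16L),
                4L, 4L, byrow = TRUE)
    counts[[k]] <- N
    p <- 1 - sum(diag(N)) / sum(N)
    d[k] <- max(p, 1e-8)  # initial value; refined below
  }
  kappa1 <- 2; kappa2 <- 2
  comp_ll <- function(dd, k1, k2)
    sum(vapply(seq_len(npair), function(k)
      pair_loglik(dd[k], counts[[k]], freqs, k1, k2), numeric(1)))
  ll_old <- -Inf
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    # per-pair distance updates
    for (k in seq_len(npair)) {
      N <- counts[[k]]
      if (sum(N) == sum(diag(N))) { d[k] <- 0; next }
      d[k] <- optimize(function(x) pair_loglik(x, N, freqs, kappa1, kappa2),
                       interval = c(0, d_max), maximum = TRUE,
                       tol = 1e-10)$maximum
    }
    # shared rate-ratio update (on log scale to stay positive)
    opt <- optim(log(c(kappa1, kappa2)),
                 function(lk) -comp_ll(d, exp(lk[1L]), exp(lk[2L])),
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 500L))
    kappa1 <- exp(opt$par[1L]); kappa2 <- exp(opt$par[2L])
    ll_new <- -opt$value
    if (abs(ll_new - ll_old) < tol || sweeps >= max_iter) break
    ll_old <- ll_new
  }
  if (sweeps >= max_iter && abs(ll_new - ll_old) >= tol)
    stop("MCL optimiser failed to converge after ", max_iter,
         " sweeps (last composite log-likelihood change ",
         signif(abs(ll_new - ll_old), 3), ")")
  m <- matrix(0, n, n, dimnames = list(set$labels, set$labels))
  for (k in seq_len(npair)) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    m[i, j] <- m[j, i] <- d[k]
  }
  attr(m, "method") <- "MCL"
  attr(m, "params") <- list(kappa1 = kappa1, kappa2 = kappa2, freqs = freqs,
                            sweeps = sweeps, loglik = ll_new)
  m
}
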