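#' Pairwise site-pattern counts for two aligned sequences
#'
#' Alignment columns where either sequence carries a gap or a non-ACGT
#' character are excluded (pairwise deletion). Over the remaining `n` sites
#' the observed transition proportions (`P1` for A/G, `P2` for C/T,
#' `P = P1 + P2`), the transversion proportion `Q`, the base frequencies `g`
#' pooled over the pair, the per-sequence G+C contents and the full 4x4
#' joint divergence matrix `F` are tabulated. These are the sufficient
#' statistics for all distance estimators in the package.
#'
#' @param a,b aligned DNA strings of equal length.
#' @return An object of class `site_counts`.
#' @export
pairwise_counts <- function(a, b) {
  a <- check_dna_arg(a); b <- check_dna_arg(b)
  if (nchar(a) != nchar(b)) stop("sequences must be aligned (equal length)")
  ia <- dna_to_int(a); ib <- dna_to_int(b)
  keep <- ia > 0L & ib > 0L
  n <- sum(keep)
  if (n == 0L) stop("no comparable sites after pairwise deletion")
  ia <- ia[keep]; ib <- ib[keep]
  # joint counts, rows = a, cols = b, order A C G T
  Fc <- matrix(tabulate((ia - 1L) * 4L + ib, nbins = 16L), 4L, 4L,
               byrow = TRUE, dimnames = list(DNA_BASES, DNA_BASES))
  Fm <- Fc / n
  P1 <- (Fm["A", "G"] + Fm["G", "A"])
  P2 <- (Fm["C", "T"] + Fm["T", "C"])
  Q <- 1 - sum(diag(Fm)) - P1 - P2
  ga <- tabulate(ia, nbins = 4L) / n
  gb <- tabulate(ib, nbins = 4L) / n
  g <- (ga + gb) / 2
  names(g) <- DNA_BASES
  structure(
    list(n = n, P = P1 + P2, P1 = unname(P1), P2 = unname(P2), Q = unname(Q),
         g = g, gc1 = ga[2L] + ga[3L], gc2 = gb[2L] + gb[3L], F = Fm),
    class = "site_counts")
}

DNA_BASES <- c("A", "C", "G", "T")

# A=1 C=2 G=3 T=4, anything else 0
dna_to_int <- function(x) {
  code <- integer(256)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  code[utf8ToInt(x)]
}

inestimable <- function(model) {
  stop(structure(
    class = c("barcodecmp_inestimable", "error", "condition"),
    list(message = paste0(model, " distance inestimable (saturated pair: ",
                          "logarithm argument not positive)"),
         call = sys.call(-1))))
}

#' Kimura 2-parameter distance
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`, correcting the observed
#' transition (`P`) and transversion (`Q`) proportions for multiple hits
#' under equal base frequencies.
#'
#' @param counts a `site_counts` object from [pairwise_counts()].
#' @return Distance in expected substitutions per site.
#' @export
k2p <- function(counts) {
  w1 <- 1 - 2 * counts$P - counts$Q
  w2 <- 1 - 2 * counts$Q
  if (w1 <= 0 || w2 <= 0) inestimable("K2P")
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Tajima-Nei distance
#'
#' The equal-input correction `d = -b log(1 - p/b)` of the proportion of
#' different sites `p = P + Q`, with
#' `b = (1 - sum(g_i^2) + p^2 / h) / 2` and
#' `h = sum_{i<j} x_ij^2 / (2 g_i g_j)`, where `x_ij` are the observed
#' unordered mismatch proportions between bases i and j.
#'
#' @inheritParams k2p
#' @return Distance in expected substitutions per site.
#' @export
tajima_nei <- function(counts) {
  p <- counts$P + counts$Q
  if (p == 0) return(0)
  g <- counts$g
  Fm <- counts$F
  h <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    xij <- Fm[i, j] + Fm[j, i]
    if (xij > 0) h <- h + xij^2 / (2 * g[i] * g[j])
  }
  b <- unname((1 - sum(g^2) + p^2 / h) / 2)
  if (p >= b) inestimable("Tajima-Nei")
  -b * log(1 - p / b)
}

#' Tamura 3-parameter distance
#'
#' Extends K2P with a correction for G+C-content bias:
#' `d = -c log(1 - P/c - Q) - (1 - c)/2 log(1 - 2Q)` with
#' `c = t1 + t2 - 2 t1 t2`, where `t1`, `t2` are the two sequences' G+C
#' contents. At `t1 = t2 = 1/2` the estimator reduces to K2P.
#'
#' @inheritParams k2p
#' @return Distance in expected substitutions per site.
#' @export
tamura3 <- function(counts) {
  cc <- counts$gc1 + counts$gc2 - 2 * counts$gc1 * counts$gc2
  w1 <- 1 - counts$P / cc - counts$Q
  w2 <- 1 - 2 * counts$Q
  if (w1 <= 0 || w2 <= 0) inestimable("Tamura3")
  -cc * log(w1) - 0.5 * (1 - cc) * log(w2)
}

#' Tamura-Nei (TN93) distance
#'
#' Corrects separately for the two transition types and for unequal base
#' frequencies. With purine/pyrimidine sums `gR = gA + gG`, `gY = gC + gT`:
#' `d = -(2 gA gG / gR) log(w1) - (2 gT gC / gY) log(w2)
#'      - 2 (gR gY - gA gG gY/gR - gT gC gR/gY) log(w3)`, where
#' `w1 = 1 - P1 gR/(2 gA gG) - Q/(2 gR)`,
#' `w2 = 1 - P2 gY/(2 gT gC) - Q/(2 gY)`,
#' `w3 = 1 - Q/(2 gR gY)`.
#' With `gamma_shape = a` the gamma-rates variant replaces each `-log(w)`
#' by `a (w^(-1/a) - 1)`.
#'
#' @inheritParams k2p
#' @param gamma_shape optional gamma shape parameter for rate variation
#'   across sites; `NULL` (the default, used throughout the pipeline) gives
#'   the plain uniform-rates estimator.
#' @return Distance in expected substitutions per site.
#' @export
tn93 <- function(counts, gamma_shape = NULL) {
  g <- counts$g
  gA <- g[["A"]]; gC <- g[["C"]]; gG <- g[["G"]]; gT <- g[["T"]]
  gR <- gA + gG; gY <- gC + gT
  if (gA * gG == 0 || gT * gC == 0 || gR * gY == 0)
    stop("TN93 undefined: zero base frequency in a denominator")
  w1 <- 1 - counts$P1 * gR / (2 * gA * gG) - counts$Q / (2 * gR)
  w2 <- 1 - counts$P2 * gY / (2 * gT * gC) - counts$Q / (2 * gY)
  w3 <- 1 - counts$Q / (2 * gR * gY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) inestimable("TN93")
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  nl <- if (is.null(gamma_shape)) function(w) -log(w)
        else function(w) gamma_shape * (w^(-1 / gamma_shape) - 1)
  k1 * nl(w1) + k2 * nl(w2) + k3 * nl(w3)
}

#' All-pairs evolutionary distance matrix
#'
#' Applies one of the pairwise estimators ([k2p()], [tajima_nei()],
#' [tamura3()], [tn93()]) to every pair of an aligned sequence set, or the
#' joint maximum-composite-likelihood estimator ([mcl_matrix()]). A
#' saturated (inestimable) pair raises a condition of class
#' `barcodecmp_inestimable`, which the pipeline uses to skip the replicate.
#'
#' @param set an aligned [seq_set] with at least 3 sequences.
#' @param model one of `"k2p"`, `"tajima_nei"`, `"tamura3"`, `"tn93"`,
#'   `"mcl"`.
#' @param gamma_shape passed to [tn93()] when `model = "tn93"`.
#' @return A symmetric numeric matrix with zero diagonal and attribute
#'   `method`.
#' @export
evolutionary_matrix <- function(set,
                                model = c("k2p", "tajima_nei", "tamura3",
                                          "tn93", "mcl"),
                                gamma_shape = NULL) {
  stopifnot(inherits(set, "seq_set"))
  model <- match.arg(model)
  if (!set$is_aligned) stop("evolutionary distances require aligned input")
  n <- length(set)
  if (n < 3L) stop("need at least 3 sequences for a distance matrix")
  if (model == "mcl") return(mcl_matrix(set))
  fn <- switch(model, k2p = k2p, tajima_nei = tajima_nei, tamura3 = tamura3,
               tn93 = function(cnt) tn93(cnt, gamma_shape = gamma_shape))
  m <- matrix(0, n, n, dimnames = list(set$labels, set$labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      cnt <- pairwise_counts(set$residues[[i]], set$residues[[j]])
      m[i, j] <- m[j, i] <- fn(cnt)
    }
  }
  attr(m, "method") <- switch(model, k2p = "K2P", tajima_nei = "TajimaNei",
                              tamura3 = "Tamura3", tn93 = "TN93")
  m
}
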