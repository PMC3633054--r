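test_that("pairwise counts follow manual column enumeration", {
  cnt <- pairwise_counts("ACGT", "GCGA")
  expect_equal(cnt$n, 4)
  expect_equal(cnt$P, 0.25)   # A<->G in column 1
  expect_equal(cnt$P1, 0.25)
  expect_equal(cnt$P2, 0)
  expect_equal(cnt$Q, 0.25)   # T<->A in column 4
  expect_equal(sum(cnt$F), 1)
  expect_equal(sum(cnt$g), 1)

  idc <- pairwise_counts("ACGTT", "ACGTT")
  expect_equal(idc$P + idc$Q, 0)

  # pairwise deletion drops the N column
  cnt <- pairwise_counts("ACGN", "ACGA")
  expect_equal(cnt$n, 3)
  expect_equal(cnt$P + cnt$Q, 0)

  expect_error(pairwise_counts("NNN", "ACG"), "no comparable sites")
  expect_error(pairwise_counts("ACGT", "ACG"), "aligned")
})

test_that("K2P matches its closed form and the ape reference", {
  expect_equal(k2p(pairwise_counts("ACGT", "ACGT")), 0)
  # P = 0.1, Q = 0.05 engineered on a 20-site pair
  a <- paste(rep("A", 20), collapse = "")
  b <- paste(c(rep("G", 2), "C", rep("A", 17)), collapse = "")
  cnt <- pairwise_counts(a, b)
  expect_equal(cnt$P, 0.1); expect_equal(cnt$Q, 0.05)
  expect_equal(k2p(cnt), -0.5 * log(0.75) - 0.25 * log(0.90))

  set.seed(301)
  for (i in 1:10) {
    p <- tn93_pair(runif(1, 0.02, 0.4), 800)
    cnt <- pairwise_counts(p[1], p[2])
    expect_equal(k2p(cnt), ape_pair_dist(p[1], p[2], "K80"),
                 tolerance = 1e-9)
  }
})

test_that("Tajima-Nei approaches Jukes-Cantor under equal frequencies", {
  expect_equal(tajima_nei(pairwise_counts("ACGT", "ACGT")), 0)
  set.seed(302)
  p <- tn93_pair(0.05, 20000, freqs = rep(0.25, 4), kappa1 = 1, kappa2 = 1)
  cnt <- pairwise_counts(p[1], p[2])
  pdist <- cnt$P + cnt$Q
  jc <- -0.75 * log(1 - 4 * pdist / 3)
  expect_equal(tajima_nei(cnt), jc, tolerance = 0.01)
})

test_that("Tamura-3p reduces to K2P at 50% G+C", {
  expect_equal(tamura3(pairwise_counts("ACGT", "ACGT")), 0)
  set.seed(303)
  for (i in 1:5) {
    # alternating purine/pyrimidine composition keeps both GC contents at 1/2
    p <- tn93_pair(0.15, 4000, freqs = rep(0.25, 4))
    cnt <- pairwise_counts(p[1], p[2])
    if (abs(cnt$gc1 - 0.5) > 0.02 || abs(cnt$gc2 - 0.5) > 0.02) next
    cnt$gc1 <- 0.5; cnt$gc2 <- 0.5
    expect_equal(tamura3(cnt), k2p(cnt), tolerance = 1e-12)
  }
})

test_that("TN93 reduces to K2P at equal frequencies and matches ape", {
  expect_equal(tn93(pairwise_counts("ACGT", "ACGT")), 0)
  # algebraic identity: equal frequencies and balanced transition types
  cnt <- structure(list(P = 0.12, P1 = 0.06, P2 = 0.06, Q = 0.06,
                        g = setNames(rep(0.25, 4), c("A", "C", "G", "T"))),
                   class = "site_counts")
  expect_equal(tn93(cnt), k2p(cnt), tolerance = 1e-12)

  set.seed(304)
  for (i in 1:10) {
    p <- tn93_pair(runif(1, 0.02, 0.4), 800, kappa1 = 4, kappa2 = 8)
    cnt <- pairwise_counts(p[1], p[2])
    expect_equal(tn93(cnt), ape_pair_dist(p[1], p[2], "TN93"),
                 tolerance = 1e-9)
  }
})

test_that("saturated pairs raise an inestimable-distance condition", {
  a <- strrep("A", 40); b <- strrep("G", 40)   # all transitions: P = 1
  expect_error(k2p(pairwise_counts(a, b)),
               class = "barcodecmp_inestimable")
  s <- seq_set(c(x = a, y = b, z = strrep("A", 40)))
  expect_error(evolutionary_matrix(s, "k2p"),
               class = "barcodecmp_inestimable")
})

test_that("estimators are symmetric in their arguments", {
  set.seed(305)
  p <- tn93_pair(0.2, 600)
  c1 <- pairwise_counts(p[1], p[2]); c2 <- pairwise_counts(p[2], p[1])
  for (f in list(k2p, tajima_nei, tamura3, tn93))
    expect_equal(f(c1), f(c2))
})

test_that("estimators are monotone in true divergence", {
  set.seed(306)
  ds <- c(0.02, 0.08, 0.2, 0.4)
  means <- sapply(ds, function(d) {
    reps <- replicate(8, {
      p <- tn93_pair(d, 2000)
      cnt <- pairwise_counts(p[1], p[2])
      c(k2p(cnt), tajima_nei(cnt), tamura3(cnt), tn93(cnt))
    })
    rowMeans(reps)
  })
  for (r in 1:4) expect_true(all(diff(means[r, ]) > 0))
})

test_that("TN93 probability matrix is a proper transition kernel", {
  freqs <- c(0.3, 0.2, 0.2, 0.3)
  P0 <- tn93_prob_matrix(0, freqs, 4, 8)
  expect_equal(P0, diag(4), ignore_attr = TRUE)
  P <- tn93_prob_matrix(0.3, freqs, 4, 8)
  expect_equal(rowSums(P), rep(1, 4), ignore_attr = TRUE)
  expect_true(all(P >= 0))
  # detailed balance and convergence to the stationary distribution
  expect_equal(freqs * P, t(freqs * P), ignore_attr = TRUE)
  Pinf <- tn93_prob_matrix(500, freqs, 4, 8)
  expect_equal(Pinf, matrix(freqs, 4, 4, byrow = TRUE),
               ignore_attr = TRUE, tolerance = 1e-8)
  # mean substitution rate is normalised to one at d -> 0
  expect_equal(sum(freqs * (1 - diag(tn93_prob_matrix(1e-6, freqs, 4, 8)))) /
                 1e-6, 1, tolerance = 1e-4)
})

test_that("MCL recovers distances simulated under TN93", {
  set.seed(307)
  d_true <- 0.2
  P <- tn93_prob_matrix(d_true / 2, c(0.3, 0.2, 0.2, 0.3), 4, 8)
  bases <- c("A", "C", "G", "T")
  root <- sample.int(4, 10000, replace = TRUE, prob = c(0.3, 0.2, 0.2, 0.3))
  tip <- function() {
    out <- integer(10000)
    for (s in 1:4) {
      idx <- which(root == s)
      out[idx] <- sample.int(4, length(idx), replace = TRUE, prob = P[s, ])
    }
    paste(bases[out], collapse = "")
  }
  s <- seq_set(setNames(c(tip(), tip(), tip()), c("x", "y", "z")))
  m <- mcl_matrix(s)
  expect_identical(attr(m, "method"), "MCL")
  expect_lt(abs(mean(m[upper.tri(m)]) - d_true) / d_true, 0.05)

  ident <- seq_set(setNames(rep(strrep("ACGT", 50), 3), c("a", "b", "c")))
  expect_true(all(mcl_matrix(ident) == 0))
})

test_that("MCL converges to K2P under the symmetric model", {
  set.seed(308)
  P <- tn93_prob_matrix(0.08, rep(0.25, 4), 3, 3)
  bases <- c("A", "C", "G", "T")
  root <- sample.int(4, 8000, replace = TRUE)
  tip <- function() {
    out <- integer(8000)
    for (s in 1:4) {
      idx <- which(root == s)
      out[idx] <- sample.int(4, length(idx), replace = TRUE, prob = P[s, ])
    }
    paste(bases[out], collapse = "")
  }
  s <- seq_set(setNames(c(tip(), tip(), tip()), c("a", "b", "c")))
  mk <- evolutionary_matrix(s, "k2p")
  mm <- mcl_matrix(s)
  expect_lt(max(abs(mm - mk)) / max(mk), 0.03)
})
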