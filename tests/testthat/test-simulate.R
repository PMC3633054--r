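test_that("Yule trees have the requested size and exact depth", {
  for (n in c(2, 5, 10)) {
    t <- yule_tree(n, depth = 1e6, seed = 600 + n)
    expect_equal(length(t$tip.label), n)
    depths <- ape::node.depth.edgelength(t)[seq_len(n)]
    expect_true(all(abs(depths - 1e6) < 1e-6 * 1e6))
  }
  t2 <- yule_tree(2, depth = 500, seed = 601)
  expect_equal(t2$Nnode, 1L)
  expect_equal(ape::node.depth.edgelength(t2)[1:2], c(500, 500))
})

test_that("Yule internode intervals follow pure-birth waiting times", {
  # Independent oracle: the normalised interval pattern of exponentials
  # with rates 2, 3, ..., n (plus the final stretch at rate n).
  set.seed(602)
  n <- 10
  oracle <- replicate(3000, {
    w <- c(rexp(n - 2, rate = 2:(n - 1)), rexp(1, rate = n))
    w / sum(w)
  })
  sim <- replicate(3000, {
    t <- yule_tree(n, depth = 1)
    splits <- sort(1 - ape::branching.times(t))  # from the root, in [0, 1)
    diff(c(splits, 1))
  })
  expect_equal(unname(rowMeans(sim)), rowMeans(oracle), tolerance = 0.05)
})

test_that("coalescent times match the pairwise expectation", {
  # two lineages in one population coalesce after Exp(mean 2Ne) generations
  set.seed(603)
  sp <- yule_tree(2, depth = 1e7)   # deep split: coalescence well before it
  Ne <- 10000
  tm <- replicate(5000, {
    g <- coalescent_gene_tree(sp, k_per_species = 2, Ne = Ne)
    d <- ape::cophenetic.phylo(g)
    d["s1_1", "s1_2"] / 2          # TMRCA of the within-species pair
  })
  expect_equal(mean(tm), 2 * Ne, tolerance = 0.05)
})

test_that("gene trees have the right tips and respect the species tree", {
  sp <- yule_tree(4, depth = 1e6, seed = 604)
  g <- coalescent_gene_tree(sp, k_per_species = 10, Ne = 10000, seed = 605)
  expect_equal(length(g$tip.label), 40L)
  expect_true(all(grepl("^s[0-9]+_[0-9]+$", g$tip.label)))
  # cross-species TMRCA is at least the species divergence time
  dg <- ape::cophenetic.phylo(g) / 2
  ds <- ape::cophenetic.phylo(sp) / 2
  for (a in c("s1", "s2")) for (b in c("s3", "s4")) {
    expect_gte(min(dg[paste0(a, "_", 1:10), paste0(b, "_", 1:10)]),
               ds[a, b] - 1e-6)
  }
})

test_that("deep species trees give monophyletic species", {
  set.seed(606)
  sp <- yule_tree(3, depth = 1e6)
  mono <- replicate(150, {
    g <- coalescent_gene_tree(sp, k_per_species = 3, Ne = 10000)
    all(vapply(paste0("s", 1:3), function(s)
      ape::is.monophyletic(g, paste0(s, "_", 1:3)), logical(1)))
  })
  expect_gte(mean(mono), 0.99)
})

test_that("branch noise is additive, unbiased and clamped", {
  t <- yule_tree(5, depth = 1e6, seed = 607)
  expect_identical(add_branch_noise(t, 0), t)
  # moments on a single long branch
  set.seed(608)
  l <- 1e6
  two <- read_newick(sprintf("(a:%d,b:%d);", l, l))
  draws <- replicate(8000, add_branch_noise(two, 0.7)$edge.length[1])
  expect_equal(mean(draws), l, tolerance = 0.001)
  expect_equal(var(draws), 0.7 * l, tolerance = 0.05)
  # heavy noise on tiny branches gets clamped to a positive floor
  tiny <- read_newick("(a:0.001,b:1000000);")
  set.seed(609)
  noised <- add_branch_noise(tiny, 0.7)
  expect_true(all(noised$edge.length > 0))
})

test_that("HKY evolution is stationary with the requested ts/tv ratio", {
  hk <- hky_params(3, c(0.3, 0.2, 0.2, 0.3))
  expect_equal(hk$kappa, 6.25)
  # zero-length branches copy the root
  z <- read_newick("(a:0,b:0);")
  s <- evolve_sequences(z, hk, 200, rate = 1, seed = 610)
  expect_identical(s$residues[["a"]], s$residues[["b"]])
  # long branch: child composition converges to the stationary frequencies
  lng <- read_newick("(a:0,b:50);")
  s <- evolve_sequences(lng, hk, 20000, rate = 1, seed = 611)
  obs <- table(factor(strsplit(s$residues[["b"]], "")[[1]],
                      c("A", "C", "G", "T"))) / 20000
  chi <- 20000 * sum((as.numeric(obs) - hk$freqs)^2 / hk$freqs)
  expect_lt(chi, qchisq(0.999, df = 3))
  # moderate branch: observed transition:transversion ratio near R = 3
  mod <- read_newick("(a:0,b:0.05);")
  s <- evolve_sequences(mod, hk, 60000, rate = 1, seed = 612)
  x <- strsplit(s$residues[["a"]], "")[[1]]
  y <- strsplit(s$residues[["b"]], "")[[1]]
  diffs <- x != y
  ts <- sum((x %in% c("A", "G") & y %in% c("A", "G") |
             x %in% c("C", "T") & y %in% c("C", "T")) & diffs)
  tv <- sum(diffs) - ts
  expect_equal(ts / tv, 3, tolerance = 0.15)
})

test_that("replicated simulation is deterministic and well-formed", {
  cfg <- sim_config(n_species = 10, n_replicates = 2, seed = 99)
  r1 <- simulate_dataset(cfg)
  expect_length(r1, 2L)
  seqs <- r1[[1]]$sequences
  expect_equal(length(seqs), 100L)
  expect_true(seqs$is_aligned)
  expect_equal(nchar(seqs$residues[[1]]), 650L)
  expect_false(any(grepl("[^ACGT]", seqs$residues)))
  # same master seed: byte-identical; different replicates differ
  r2 <- simulate_dataset(cfg)
  expect_identical(r1[[1]]$sequences$residues, r2[[1]]$sequences$residues)
  expect_identical(write_newick(r1[[2]]$gene_tree),
                   write_newick(r2[[2]]$gene_tree))
  expect_false(identical(r1[[1]]$sequences$residues,
                         r1[[2]]$sequences$residues))
})
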