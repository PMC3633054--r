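#' Simulation protocol configuration
#'
#' Bundles every stochastic parameter of the barcode simulation protocol:
#' a Yule (pure-birth) species tree of `n_species` tips rescaled to a
#' root-to-tip depth of `tree_depth` generations; a multispecies-coalescent
#' gene tree with `individuals_per_species` sampled lineages per species and
#' effective population size `Ne`; additive Gaussian branch-length noise
#' with variance `noise_variance_factor` times each branch length; and HKY
#' sequence evolution with transition/transversion ratio `tstv_ratio`, base
#' frequencies `base_freqs` and `seq_length` sites. `subs_per_depth` sets
#' the clock: the expected number of substitutions per site accumulated
#' over one `tree_depth` of generations (default 0.1, a COI-like scale).
#'
#' @param n_species number of species (tips of the species tree).
#' @param tree_depth species-tree root-to-tip depth in generations.
#' @param individuals_per_species sampled gene lineages per species.
#' @param Ne effective population size (diploid convention by default; see
#'   `ploidy`).
#' @param noise_variance_factor variance of the branch noise as a multiple
#'   of the branch length.
#' @param seq_length sequence length in bp.
#' @param tstv_ratio expected transition/transversion ratio R of the HKY
#'   model.
#' @param base_freqs stationary base frequencies (A, C, G, T).
#' @param n_replicates number of independent replicates.
#' @param subs_per_depth expected substitutions/site per `tree_depth`
#'   generations (clock calibration).
#' @param ploidy coalescent time-scaling convention: pairs coalesce at rate
#'   `1 / (ploidy * Ne)` per generation (2 = diploid, the default).
#' @param seed master seed; every replicate derives its own seed from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_species = 10, tree_depth = 1e6,
                       individuals_per_species = 10, Ne = 10000,
                       noise_variance_factor = 0.7, seq_length = 650,
                       tstv_ratio = 3,
                       base_freqs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                       n_replicates = 25, subs_per_depth = 0.1, ploidy = 2,
                       seed = 1L) {
  stopifnot(n_species >= 2, tree_depth > 0, individuals_per_species >= 1,
            Ne > 0, noise_variance_factor >= 0, seq_length >= 1,
            tstv_ratio > 0, length(base_freqs) == 4L, all(base_freqs > 0),
            abs(sum(base_freqs) - 1) < 1e-8, n_replicates >= 1,
            subs_per_depth > 0, ploidy > 0)
  structure(list(n_species = n_species, tree_depth = tree_depth,
                 individuals_per_species = individuals_per_species, Ne = Ne,
                 noise_variance_factor = noise_variance_factor,
                 seq_length = seq_length, tstv_ratio = tstv_ratio,
                 base_freqs = unname(base_freqs),
                 n_replicates = n_replicates,
                 subs_per_depth = subs_per_depth, ploidy = ploidy,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' HKY model parameters
#'
#' Converts the Seq-gen-style expected transition/transversion ratio `R`
#' into the rate ratio `kappa` used by the transition-probability matrix:
#' `kappa = R * piR * piY / (piA piG + piC piT)`, where `piR`/`piY` are the
#' purine/pyrimidine frequency sums. At the protocol's frequencies
#' (0.3, 0.2, 0.2, 0.3) a ratio of 3 corresponds to `kappa = 6.25`.
#'
#' @param tstv_ratio expected transition/transversion ratio R.
#' @param base_freqs stationary base frequencies (A, C, G, T).
#' @return An object of class `hky_params` with elements `kappa`, `freqs`
#'   and `tstv_ratio`.
#' @export
hky_params <- function(tstv_ratio = 3,
                       base_freqs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  stopifnot(tstv_ratio > 0, length(base_freqs) == 4L,
            abs(sum(base_freqs) - 1) < 1e-8)
  p <- unname(base_freqs)
  pR <- p[1L] + p[3L]; pY <- p[2L] + p[4L]
  kappa <- tstv_ratio * pR * pY / (p[1L] * p[3L] + p[2L] * p[4L])
  structure(list(kappa = kappa, freqs = p, tstv_ratio = tstv_ratio),
            class = "hky_params")
}

#' Simulate a Yule (pure-birth) species tree
#'
#' A pure-birth tree is grown forward in time (waiting time between the
#' k-lineage and (k+1)-lineage stages exponential with rate k, a uniformly
#' chosen lineage splitting at each event, plus a final exponential stretch
#' before the present), then linearly rescaled so the root-to-tip depth
#' equals `depth` exactly. The result is ultrametric with tips labelled
#' `s1 ... sn`.
#'
#' @param n_species number of tips (>= 2).
#' @param depth root-to-tip depth after rescaling (generations).
#' @param seed optional seed.
#' @return An ultrametric [ape::phylo] tree.
#' @export
yule_tree <- function(n_species, depth = 1e6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_species >= 2, depth > 0)
  n <- as.integer(n_species)
  # root split at t = 0; lineages carry (parent node id, start time)
  par <- c(n + 1L, n + 1L); st <- c(0, 0)
  next_int <- n + 2L
  edge <- matrix(0L, 2L * n - 2L, 2L); elen <- numeric(2L * n - 2L)
  ne <- 0L
  t_now <- 0
  k <- 2L
  while (k < n) {
    t_now <- t_now + rexp(1L, rate = k)
    i <- sample.int(k, 1L)
    new <- next_int; next_int <- next_int + 1L
    ne <- ne + 1L
    edge[ne, ] <- c(par[i], new); elen[ne] <- t_now - st[i]
    par <- c(par[-i], new, new); st <- c(st[-i], t_now, t_now)
    k <- k + 1L
  }
  t_end <- t_now + rexp(1L, rate = n)
  for (i in seq_len(n)) {
    ne <- ne + 1L
    edge[ne, ] <- c(par[i], i); elen[ne] <- t_end - st[i]
  }
  tr <- structure(list(edge = edge, edge.length = elen * (depth / t_end),
                       tip.label = paste0("s", seq_len(n)), Nnode = n - 1L),
                  class = "phylo")
  ape::reorder.phylo(tr)
}

#' Simulate a multispecies-coalescent gene tree
#'
#' Standard multispecies coalescent on an ultrametric species tree in
#' generation units: within each population (species-tree branch), while
#' `k` gene lineages are present any pair coalesces at rate
#' `1 / (ploidy * Ne)` per generation (total rate `choose(k, 2)` times
#' that); lineages that fail to coalesce by the top of the branch enter the
#' parent population, and the interval above the species root is unbounded.
#' Gene-tree tips are labelled `<species>_<individual>`.
#'
#' @param species_tree ultrametric [ape::phylo] in generations.
#' @param k_per_species sampled lineages per species.
#' @param Ne effective population size.
#' @param seed optional seed.
#' @param ploidy time-scaling convention (2 = diploid).
#' @return A rooted [ape::phylo] gene tree in generations, ultrametric over
#'   its tips.
#' @export
coalescent_gene_tree <- function(species_tree, k_per_species = 10,
                                 Ne = 10000, seed = NULL, ploidy = 2) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(species_tree, "phylo"), k_per_species >= 1, Ne > 0)
  st <- species_tree
  S <- length(st$tip.label)
  nodes_total <- S + st$Nnode
  depths <- ape::node.depth.edgelength(st)
  btime <- max(depths[seq_len(S)]) - depths      # backward time; tips ~ 0
  parent_of <- integer(nodes_total)
  parent_of[st$edge[, 2L]] <- st$edge[, 1L]
  root_sp <- setdiff(st$edge[, 1L], st$edge[, 2L])[1L]

  n_tips <- S * k_per_species
  g_total <- 2L * n_tips - 1L
  gtime <- numeric(g_total)
  gedge <- matrix(0L, 2L * (n_tips - 1L), 2L)
  ge <- 0L
  next_g <- n_tips + 1L
  rate1 <- 1 / (ploidy * Ne)

  coalesce_interval <- function(lin, t0, t1) {
    k <- length(lin); t <- t0
    while (k >= 2L) {
      w <- rexp(1L, rate = k * (k - 1L) / 2 * rate1)
      if (t + w > t1) break
      t <- t + w
      pr <- sample.int(k, 2L)
      new <- next_g; next_g <<- next_g + 1L
      gtime[new] <<- t
      gedge[ge + 1L, ] <<- c(new, lin[pr[1L]])
      gedge[ge + 2L, ] <<- c(new, lin[pr[2L]])
      ge <<- ge + 2L
      lin <- c(lin[-pr], new)
      k <- k - 1L
    }
    lin
  }

  lin_at <- vector("list", nodes_total)
  labels <- character(n_tips)
  for (s in seq_len(S)) {
    ids <- seq.int((s - 1L) * k_per_species + 1L, s * k_per_species)
    labels[ids] <- paste0(st$tip.label[s], "_", seq_len(k_per_species))
    gtime[ids] <- btime[s]
    lin_at[[s]] <- ids
  }
  internals <- seq.int(S + 1L, nodes_total)
  proc <- c(seq_len(S)[order(btime[seq_len(S)])],
            internals[order(btime[internals])])
  for (v in proc) {
    if (v == root_sp) next
    p <- parent_of[v]
    surv <- coalesce_interval(lin_at[[v]], btime[v], btime[p])
    lin_at[[p]] <- c(lin_at[[p]], surv)
  }
  last <- coalesce_interval(lin_at[[root_sp]], btime[root_sp], Inf)
  stopifnot(length(last) == 1L)

  # renumber internals by decreasing age so the root becomes n_tips + 1
  internal_old <- seq.int(n_tips + 1L, g_total)
  new_id <- integer(g_total)
  new_id[seq_len(n_tips)] <- seq_len(n_tips)
  new_id[internal_old[order(gtime[internal_old], decreasing = TRUE)]] <-
    seq.int(n_tips + 1L, g_total)
  edge <- cbind(new_id[gedge[, 1L]], new_id[gedge[, 2L]])
  tnew <- numeric(g_total)
  tnew[new_id] <- gtime
  elen <- tnew[edge[, 1L]] - tnew[edge[, 2L]]
  tr <- structure(list(edge = edge, edge.length = elen, tip.label = labels,
                       Nnode = n_tips - 1L),
                  class = "phylo")
  ape::reorder.phylo(tr)
}

#' Add Gaussian noise to branch lengths
#'
#' Each branch length `l` is replaced by `l + e` with
#' `e ~ Normal(0, variance = factor * l)`, independently per branch, which
#' generally destroys ultrametricity. Results below a small positive floor
#' (1e-8 times the tree height) are clamped to the floor; the number of
#' clamped branches is recorded in attribute `n_clamped`.
#'
#' @param tree an [ape::phylo] tree.
#' @param factor variance multiplier (>= 0); 0 returns the tree unchanged.
#' @param seed optional seed.
#' @return The noised tree.
#' @export
add_branch_noise <- function(tree, factor = 0.7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(tree, "phylo"), factor >= 0)
  if (factor == 0) return(tree)
  l <- tree$edge.length
  eps_min <- 1e-8 * max(ape::node.depth.edgelength(tree))
  noisy <- l + rnorm(length(l), mean = 0, sd = sqrt(factor * l))
  n_clamped <- sum(noisy < eps_min)
  tree$edge.length <- pmax(noisy, eps_min)
  attr(tree, "n_clamped") <- n_clamped
  tree
}

#' Evolve sequences along a tree under the HKY model
#'
#' The root sequence is drawn i.i.d. from the stationary frequencies; each
#' branch then applies the HKY transition matrix `P(l * rate)`
#' site-independently (no indels), so the output is alignment-ready: equal
#' lengths, gap-free, one sequence per leaf.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param hky an [hky_params] object.
#' @param seq_length number of sites.
#' @param rate expected substitutions/site per unit branch length (use
#'   `subs_per_depth / tree_depth` for trees in generations).
#' @param seed optional seed.
#' @return A [seq_set] of aligned sequences labelled by the leaf labels.
#' @export
evolve_sequences <- function(tree, hky = hky_params(), seq_length = 650,
                             rate = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(tree, "phylo"), inherits(hky, "hky_params"),
            seq_length >= 1, rate > 0)
  nt <- length(tree$tip.label)
  nnode <- nt + tree$Nnode
  tr <- ape::reorder.phylo(tree)  # cladewise: parents before children
  states <- matrix(0L, nnode, seq_length)
  root <- tr$edge[1L, 1L]
  states[root, ] <- sample.int(4L, seq_length, replace = TRUE,
                               prob = hky$freqs)
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    P <- tn93_prob_matrix(tr$edge.length[e] * rate, hky$freqs,
                          hky$kappa, hky$kappa)
    ps <- states[p, ]
    cs <- integer(seq_length)
    for (s in 1:4) {
      idx <- which(ps == s)
      if (length(idx))
        cs[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[s, ])
    }
    states[ch, ] <- cs
  }
  residues <- vapply(seq_len(nt), function(i)
    paste(DNA_BASES[states[i, ]], collapse = ""), character(1))
  seq_set(residues, labels = tr$tip.label)
}

# deterministic per-replicate seed below 2^31
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 7919 + as.double(index) * 1000003) %%
               2147483629) + 1L
}

#' Simulate replicated barcode datasets
#'
#' Runs the full protocol `n_replicates` times: Yule species tree,
#' multispecies-coalescent gene tree, Gaussian branch noise, HKY sequence
#' evolution. Each replicate is generated under its own seed derived
#' deterministically from the master seed and the replicate index, so any
#' replicate is reproducible in isolation.
#'
#' @param config a [sim_config].
#' @return A list of class `sim_replicates`; each element is a list with
#'   `seed`, `species_tree`, `gene_tree` (pre-noise), `noisy_tree` and
#'   `sequences` (a [seq_set] of `n_species * individuals_per_species`
#'   aligned sequences). The configuration is attached as attribute
#'   `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  hky <- hky_params(config$tstv_ratio, config$base_freqs)
  rate <- config$subs_per_depth / config$tree_depth
  reps <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    seed_r <- derive_seed(config$seed, r)
    set.seed(seed_r)
    sp <- yule_tree(config$n_species, config$tree_depth)
    gt <- coalescent_gene_tree(sp, config$individuals_per_species,
                               config$Ne, ploidy = config$ploidy)
    nt <- add_branch_noise(gt, config$noise_variance_factor)
    seqs <- evolve_sequences(nt, hky, config$seq_length, rate)
    reps[[r]] <- list(seed = seed_r, species_tree = sp, gene_tree = gt,
                      noisy_tree = nt, sequences = seqs)
  }
  structure(reps, class = "sim_replicates", config = config)
}
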