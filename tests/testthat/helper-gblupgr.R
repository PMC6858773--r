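# Shared fixtures and independent oracles for the test suite.

# Small population used across module tests: 3 chromosomes, 30 founders,
# 6 full-sib families of 8.
toy_population <- function(seed = 1, n_marker = 800, offspring_per_dam = 8) {
  set.seed(seed)
  f <- simulate_base_population(
    genome_config(n_chr = 3, total_cM = 300, n_qtl = 100,
                  n_marker = n_marker),
    historical_config(n_ind = 50, generations = 30, oversample = 3),
    n_founders = 30)
  trait <- assign_qtl_effects(f, 0.3, 0.7)
  pop <- nested_mating(f, list(n_sires = 3L, dams_per_sire = 2L,
                               offspring_per_dam = offspring_per_dam))
  phen <- simulate_phenotypes(pop, trait)
  list(founders = f, trait = trait, pop = pop, phen = phen,
       grm = grm_from_population(pop))
}

# Hand-built founder population with explicit map and haplotypes
# (loci x 2*n raw matrix), for exact-inheritance tests.
manual_founders <- function(chr_cM, chr, pos, haps) {
  H <- matrix(as.raw(haps), nrow = length(chr))
  structure(list(
    map = structure(list(chr_cM = chr_cM, chr = as.integer(chr),
                         pos = as.numeric(pos),
                         role = rep("marker", length(chr))),
                    class = "genome_map"),
    haps = H,
    ids = seq_len(ncol(H) %/% 2)), class = "founder_pop")
}

# Wrap a plain relationship matrix as a grm object.
as_grm <- function(G, ids = seq_len(nrow(G))) {
  gblupgr:::.new_grm("full", ids, p = rep(0.5, 10), denom = 1, G = G)
}

# Naive REML log-likelihood: explicit V, determinants and projection,
# independent of the package's eigendecomposition path.
naive_reml_ll <- function(y, K, R, s2g, s2e) {
  V <- s2g * K + s2e * diag(R, nrow = length(y))
  Vi <- solve(V)
  xv <- colSums(Vi)              # X = 1
  xvx <- sum(xv)
  beta <- sum(xv * y) / xvx
  r <- y - beta
  -0.5 * (as.numeric(determinant(V)$modulus) + log(xvx) +
            drop(t(r) %*% Vi %*% r) + (length(y) - 1) * log(2 * pi))
}

# Naive BLUP of genetic values: g_hat = s2g G Z' V^-1 (y - 1 mu_GLS).
naive_blup <- function(y, Z, G, R, s2g, s2e) {
  V <- s2g * Z %*% G %*% t(Z) + s2e * diag(R, nrow = length(y))
  Vi <- solve(V)
  xv <- colSums(Vi)
  mu <- sum(xv * y) / sum(xv)
  list(mu = mu, gebv = drop(s2g * G %*% t(Z) %*% Vi %*% (y - mu)))
}

# All 35 partitions of 8 items into two unlabelled groups of 4,
# as a list of logical masks for the group containing item 1.
partitions_8_into_2 <- function() {
  sets <- utils::combn(8, 4)
  keep <- sets[, sets[1, ] == 1, drop = FALSE]
  lapply(seq_len(ncol(keep)), function(j) keep[, j])
}

# Mean within-group relationship of a 2x4 partition of an 8x8 matrix.
partition_objective <- function(G, grp1) {
  grp2 <- setdiff(1:8, grp1)
  pair_mean <- function(idx) {
    B <- G[idx, idx]
    B[upper.tri(B)]
  }
  mean(c(pair_mean(grp1), pair_mean(grp2)))
}
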