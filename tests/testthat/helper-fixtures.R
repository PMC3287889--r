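# Fixtures and independent oracles shared across tests.

# Small genotype matrix with exact column MAFs, built from 0/1 counts on
# n individuals (maf = ones / (2 n)).
toy_genotypes <- function(ones_per_col, n = 10) {
  counts <- sapply(ones_per_col, function(o) c(rep(1, o), rep(0, n - o)))
  genotype_matrix(counts)
}

# Exhaustive-search oracle: enumerate every size-k subset, return the best
# fitness and the full Boltzmann distribution exp(ll)/Z.
brute_force_search <- function(genotypes, weights, phenotype, k) {
  m <- n_variants(genotypes)
  subs <- utils::combn(m, k)
  r2 <- apply(subs, 2, function(s) {
    fitness(aggregate_score(genotypes, snp_subset(s), weights), phenotype)$r2
  })
  n <- length(phenotype)
  ll <- -(n / 2) * log1p(-pmin(r2, 1 - 1e-12))
  pi <- exp(ll - max(ll)); pi <- pi / sum(pi)
  keys <- apply(subs, 2, paste, collapse = "-")
  list(subsets = subs, r2 = r2, best_r2 = max(r2),
       best = subs[, which.max(r2)], keys = keys, boltzmann = pi)
}

subset_key <- function(idx) paste(sort(idx), collapse = "-")

# Hudson-style two-population Fst estimator (ratio of averages), used as an
# independent oracle for the population-structure simulator.
fst_hudson <- function(counts, pops) {
  stopifnot(length(unique(pops)) == 2)
  g1 <- counts[pops == unique(pops)[1], , drop = FALSE]
  g2 <- counts[pops == unique(pops)[2], , drop = FALSE]
  n1 <- 2 * nrow(g1); n2 <- 2 * nrow(g2)
  p1 <- colMeans(g1) / 2; p2 <- colMeans(g2) / 2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# Tiny dataset with planted causal signal for optimizer tests.
planted_instance <- function(n = 100, m = 12, k = 3, seed = 3,
                             effects = rep(1, k)) {
  cfg <- sim_config(n_individuals = n, n_variants = m, n_subpops = 1,
                    fst = 0, causal_ids = seq(2, by = 3,
                                              length.out = length(effects)),
                    effect_sizes = effects, n_replicates = 1, seed = seed)
  sim <- simulate_dataset(cfg)
  list(genotypes = sim$genotypes, phenotype = sim$phenotypes[[1]]$values,
       causal = cfg$causal_ids)
}
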