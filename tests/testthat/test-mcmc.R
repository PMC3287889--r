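test_that("temperature ladder follows 1 / (1 + 0.2 j)", {
  expect_equal(rvsearch:::temperature_ladder(5),
               c(1, 1 / 1.2, 1 / 1.4, 1 / 1.6, 1 / 1.8),
               tolerance = 1e-12)
  expect_equal(rvsearch:::temperature_ladder(1), 1)
})

test_that("chain initialization samples subsets from the kernel", {
  inst <- planted_instance(n = 50, m = 5, k = 2, seed = 9)
  w <- compute_weights(inst$genotypes, "LL")
  # uniform kernel -> all C(5,2) = 10 subsets equally likely
  set.seed(10)
  keys <- replicate(800, {
    ch <- init_chains(inst$genotypes, w, inst$phenotype,
                      kernel_weights = rep(1, 5), k = 2, n_chains = 1)
    subset_key(ch[[1]]$subset$indices)
  })
  tab <- table(factor(keys, levels = apply(combn(5, 2), 2, paste,
                                           collapse = "-")))
  expect_gt(chisq.test(tab)$p.value, 0.001)
  # k = m holds the full set; k > m errors
  ch <- init_chains(inst$genotypes, w, inst$phenotype, k = 5, n_chains = 2)
  expect_equal(ch[[1]]$subset$indices, 1:5)
  expect_error(init_chains(inst$genotypes, w, inst$phenotype, k = 6),
               "exceeds")
  # cached log-likelihood is coherent with the subset it belongs to
  ch3 <- init_chains(inst$genotypes, w, inst$phenotype, k = 2, n_chains = 3,
                     rng_seed = 1)
  for (st in ch3) {
    fit <- fitness(aggregate_score(inst$genotypes, st$subset, w),
                   inst$phenotype)
    expect_equal(st$log_lik, log_likelihood(fit))
  }
})

test_that("swap proposals follow the kernel and carry the exact Hastings
           correction", {
  inst <- planted_instance(n = 40, m = 3, k = 1, seed = 11)
  w <- compute_weights(inst$genotypes, "LL")
  st <- rvsearch:::chain_state(snp_subset(1L), inst$genotypes, w,
                               inst$phenotype)
  kw <- c(0.5, 1, 3)
  set.seed(12)
  added <- replicate(3000, propose_swap(st, kw)$added)
  # P(add 3) = 3 / (1 + 3) = 0.75 among non-members {2, 3}
  expect_equal(mean(added == 3), 0.75, tolerance = 0.03)
  # analytic Hastings correction for a specific move
  pr <- list(removed = 1, added = 3)
  total_fwd <- kw[2] + kw[3]
  total_rev <- total_fwd - kw[3] + kw[1]
  expected_h <- log(kw[1] / total_rev) - log(kw[3] / total_fwd)
  set.seed(13)
  repeat {
    p <- propose_swap(st, kw)
    if (p$added == 3) break
  }
  expect_equal(p$log_hastings, expected_h)
  expect_equal(p$candidate$k, 1L)
  # uniform kernel -> correction is exactly zero
  for (i in 1:20) {
    expect_identical(propose_swap(st, rep(1, 3))$log_hastings, 0)
  }
})

test_that("steps with non-decreasing likelihood are always accepted", {
  # two-variant space with k = 1: the proposal is forced, so acceptance
  # logic is observable directly
  set.seed(14)
  g <- genotype_matrix(cbind(rbinom(60, 2, 0.4), rbinom(60, 2, 0.4)))
  y <- 0.8 * g$counts[, 2] + rnorm(60)
  w <- compute_weights(g, "LL")
  kw <- rep(1, 2)
  worse <- rvsearch:::chain_state(snp_subset(1L), g, w, y)
  for (i in 1:25) {
    st <- mcmc_step(worse, g, w, y, kw)
    expect_equal(st$subset$indices, 2L)  # uphill move always taken
  }
  # equal likelihood (duplicated variant) is also always accepted
  g2 <- genotype_matrix(cbind(g$counts[, 1], g$counts[, 1]))
  st0 <- rvsearch:::chain_state(snp_subset(1L), g2, w, y)
  for (i in 1:25) {
    expect_true(attr(mcmc_step(st0, g2, w, y, kw), "accepted"))
  }
})

test_that("a flat likelihood with uniform kernel samples subsets uniformly", {
  # all-zero score weights make every subset score constant, hence l = 0
  set.seed(15)
  g <- genotype_matrix(matrix(rbinom(180, 2, 0.3), 30, 6))
  y <- rnorm(30)
  w0 <- structure(list(kind = "ME", weights = rep(0, 6)),
                  class = "weight_scheme")
  res <- run_mc3(g, w0, y, k = 2, n_chains = 1, iterations = 16000,
                 burn_in = 1000, kernel_weights = rep(1, 6), rng_seed = 16,
                 keep_samples = TRUE)
  keys <- apply(res$samples, 1, subset_key)
  lv <- apply(combn(6, 2), 2, paste, collapse = "-")
  emp <- table(factor(keys, levels = lv)) / length(keys)
  tv <- 0.5 * sum(abs(as.numeric(emp) - 1 / 15))
  expect_lt(tv, 0.05)
})

test_that("the cold chain converges to the enumerated Boltzmann
           distribution", {
  inst <- planted_instance(n = 80, m = 6, k = 2, seed = 17,
                           effects = c(0.5, 0.4))
  w <- compute_weights(inst$genotypes, "LL")
  oracle <- brute_force_search(inst$genotypes, w, inst$phenotype, 2)
  res <- run_mc3(inst$genotypes, w, inst$phenotype, k = 2, n_chains = 1,
                 iterations = 25000, burn_in = 2500, rng_seed = 18,
                 keep_samples = TRUE)
  keys <- apply(res$samples, 1, subset_key)
  emp <- table(factor(keys, levels = oracle$keys)) / length(keys)
  tv <- 0.5 * sum(abs(as.numeric(emp) - oracle$boltzmann))
  expect_lt(tv, 0.08)
})

test_that("swap moves exchange adjacent chains by the tempered ratio", {
  inst <- planted_instance(n = 60, m = 8, k = 2, seed = 19)
  w <- compute_weights(inst$genotypes, "LL")
  chains <- init_chains(inst$genotypes, w, inst$phenotype, k = 2,
                        n_chains = 2, rng_seed = 20)
  # force equal log-likelihoods: swap must always be accepted
  chains[[2]]$subset <- chains[[1]]$subset
  chains[[2]]$fitness <- chains[[1]]$fitness
  chains[[2]]$log_lik <- chains[[1]]$log_lik
  for (i in 1:10) expect_true(attr(swap_move(chains), "swapped"))
  # hotter chain holding the better subset: exponent >= 0, always swapped
  oracle <- brute_force_search(inst$genotypes, w, inst$phenotype, 2)
  best <- rvsearch:::chain_state(snp_subset(oracle$best), inst$genotypes,
                                 w, inst$phenotype, temperature = 1 / 1.2)
  worst <- rvsearch:::chain_state(
    snp_subset(oracle$subsets[, which.min(oracle$r2)]),
    inst$genotypes, w, inst$phenotype, temperature = 1)
  ch2 <- list(worst, best)
  sw <- swap_move(ch2)
  expect_true(attr(sw, "swapped"))
  # temperatures stay attached to positions
  expect_equal(sw[[1]]$temperature, 1)
  expect_equal(sw[[1]]$subset$indices, sort(oracle$best))
  # single chain is a no-op
  expect_false(attr(swap_move(ch2[1]), "swapped"))
})

test_that("run_mc3 is deterministic under a fixed seed and tracks the best
           subset across chains", {
  inst <- planted_instance(n = 80, m = 10, k = 3, seed = 21)
  w <- compute_weights(inst$genotypes, "MB")
  r1 <- run_mc3(inst$genotypes, w, inst$phenotype, k = 3, iterations = 800,
                burn_in = 200, rng_seed = 22)
  r2 <- run_mc3(inst$genotypes, w, inst$phenotype, k = 3, iterations = 800,
                burn_in = 200, rng_seed = 22)
  expect_identical(r1$inclusion_freq, r2$inclusion_freq)
  expect_identical(r1$best_subset$indices, r2$best_subset$indices)
  expect_identical(r1$trace, r2$trace)
  # inclusion frequencies are a distribution over memberships summing to k
  expect_true(all(r1$inclusion_freq >= 0 & r1$inclusion_freq <= 1))
  expect_equal(sum(r1$inclusion_freq), 3, tolerance = 1e-9)
  # the recorded best dominates every cold-chain likelihood in the trace
  n <- length(inst$phenotype)
  trace_r2 <- 1 - exp(-2 * r1$trace / n)
  expect_gte(r1$best_fitness$r2 + 1e-12, max(trace_r2))
})

test_that("a strongly causal variant attains high posterior inclusion and a
           null trait produces no runaway variant", {
  set.seed(23)
  for (s in 1:3) {
    n <- 300; m <- 120
    counts <- matrix(rbinom(n * m, 2, 0.25), n, m)
    g <- genotype_matrix(counts)
    gc <- counts[, 7]
    y <- gc / sd(gc) + rnorm(n)  # variant 7 explains ~50% of variance
    w <- compute_weights(g, "LL")
    res <- run_mc3(g, w, y, k = 5, iterations = 3000, burn_in = 600,
                   rng_seed = 100 + s)
    expect_gt(res$inclusion_freq[7], 0.9)
    ynull <- rnorm(n)
    resn <- run_mc3(g, w, ynull, k = 5, iterations = 3000, burn_in = 600,
                    rng_seed = 200 + s)
    expect_lt(max(resn$inclusion_freq), 5 * 5 / m + 0.05)
  }
})
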