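test_that("simulation is reproducible and produces valid genotypes", {
  cfg <- sim_config(n_individuals = 60, n_variants = 30, n_subpops = 2,
                    fst = 0.05, n_replicates = 3, seed = 50)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$genotypes$counts, s2$genotypes$counts)
  expect_identical(s1$phenotypes[[2]]$values, s2$phenotypes[[2]]$values)
  expect_true(all(s1$genotypes$counts %in% 0:2))
  expect_true(all(s1$genotypes$maf >= 0 & s1$genotypes$maf <= 0.5))
  expect_equal(s1$genotypes$maf, compute_maf(s1$genotypes$counts))
  # replicates share one genotype matrix but differ in noise
  expect_false(identical(s1$phenotypes[[1]]$values,
                         s1$phenotypes[[2]]$values))
  expect_equal(length(s1$phenotypes), 3)
  expect_error(sim_config(fst = 0.7), "fst")
  expect_error(sim_config(causal_ids = 5, effect_sizes = numeric(0),
                          n_variants = 10), "align")
})

test_that("the MAF spectrum is rare-skewed", {
  sim <- simulate_genotypes(sim_config(n_individuals = 200,
                                       n_variants = 400, n_subpops = 1,
                                       fst = 0, n_replicates = 1,
                                       seed = 51))
  frac_rare <- mean(sim$ancestral_maf < 0.05)
  expect_gt(frac_rare, 0.7)
  expect_lt(frac_rare, 0.92)
  expect_true(all(sim$ancestral_maf >= 0.002 - 1e-12))
})

test_that("without structure the sample MAF tracks the ancestral MAF", {
  sim <- simulate_genotypes(sim_config(n_individuals = 1500,
                                       n_variants = 80, n_subpops = 1,
                                       fst = 0, n_replicates = 1,
                                       seed = 52))
  folded_anc <- pmin(sim$ancestral_maf, 1 - sim$ancestral_maf)
  expect_lt(mean(abs(sim$genotypes$maf - folded_anc)), 0.01)
})

test_that("the realized divergence matches the configured Fst", {
  est <- vapply(1:3, function(sd) {
    sim <- simulate_genotypes(sim_config(n_individuals = 2000,
                                         n_variants = 400, n_subpops = 2,
                                         fst = 0.05, n_replicates = 1,
                                         seed = sd))
    fst_hudson(sim$genotypes$counts, sim$subpop_labels)
  }, numeric(1))
  expect_gt(mean(est), 0.05 * 0.7)
  expect_lt(mean(est), 0.05 * 1.3)
})

test_that("a single common causal variant explains its configured share of
           trait variance", {
  cfg <- sim_config(n_individuals = 2000, n_variants = 5, n_subpops = 1,
                    fst = 0, maf_min = 0.3, maf_max = 0.5, maf_shape = 2,
                    causal_ids = 3L, effect_sizes = 1, noise_sd = 1,
                    n_replicates = 1, seed = 53)
  gsim <- simulate_genotypes(cfg)
  gvec <- gsim$genotypes$counts[, 3]
  # scale the effect so the genetic variance share is one half
  cfg$effect_sizes <- 1 / sd(gvec)
  ph <- simulate_traits(gsim$genotypes, gsim$subpop_labels, cfg)
  r2 <- cor(ph[[1]]$values, gvec)^2
  expect_equal(r2, 0.5, tolerance = 0.05)
})

test_that("trait variance decomposes into genetic, structure and noise
           components", {
  cfg <- sim_config(n_individuals = 400, n_variants = 40, n_subpops = 2,
                    fst = 0.05, maf_min = 0.1, maf_max = 0.5,
                    maf_shape = 2, causal_ids = c(5L, 9L),
                    effect_sizes = c(0.5, 0.7), structure_effect = 0.8,
                    noise_sd = 1, n_replicates = 100, seed = 54)
  sim <- simulate_dataset(cfg)
  counts <- sim$genotypes$counts
  base <- drop(counts[, cfg$causal_ids] %*% cfg$effect_sizes) +
    cfg$structure_effect * sim$subpop_labels
  v_obs <- mean(vapply(sim$phenotypes, function(p) var(p$values),
                       numeric(1)))
  expect_equal(v_obs, var(base) + 1, tolerance = 0.1 * v_obs)
})

test_that("scenario presets encode the three trait archetypes", {
  q1 <- scenario_presets("q1_like", seed = 55)
  q2 <- scenario_presets("q2_like", seed = 55)
  q4 <- scenario_presets("q4_like", seed = 55)
  expect_length(q4$causal_ids, 0)
  expect_gt(q4$structure_effect, 0)
  expect_gte(length(q1$causal_ids), 10)
  expect_gt(length(q1$causal_ids), length(q2$causal_ids))
  expect_gt(mean(q1$effect_sizes), mean(q2$effect_sizes))
  expect_error(scenario_presets("q9_like"))
  # q1-like causal variants are planted rare (ancestral MAF cap 0.05)
  sim <- simulate_dataset(scenario_presets("q1_like", n_individuals = 300,
                                           n_replicates = 1, seed = 56))
  expect_true(all(sim$truth$ancestral_maf[sim$truth$causal_ids] <= 0.05))
})

test_that("a trait with planted signal beats the structured null end to
           end", {
  ctrl <- list(n_chains = 2, iterations = 80, burn_in = 16)
  sf <- make_search_fn("mcmc", "MB", k = 20, control = ctrl)
  p_med <- vapply(c("q1_like", "q4_like"), function(nm) {
    sim <- simulate_dataset(scenario_presets(nm, n_replicates = 6,
                                             seed = 57))
    g <- sim$genotypes
    scores <- pc_scores(g, 10)
    ps <- vapply(1:6, function(r) {
      y <- pc_adjust(g, sim$phenotypes[[r]]$values, 10,
                     scores = scores)$residual_phenotype
      permutation_test(sf, g, y, B = 40,
                       rng_seed = derive_seed(58, nm, r))$p_value
    }, numeric(1))
    median(ps)
  }, numeric(1))
  expect_lt(p_med["q1_like"], p_med["q4_like"])
})
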