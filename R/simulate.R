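#' Simulation configuration
#'
#' Describes a synthetic mini-exome-style dataset: a fixed genotype matrix
#' drawn once for a structured population, shared by many quantitative-trait
#' replicates that redraw only the noise. Ancestral minor-allele frequencies
#' follow a rare-skewed truncated Beta(shape, 10) spectrum on
#' \[maf_min, maf_max\] (the default shape 0.1 puts about 80% of variants
#' below MAF 0.05); subpopulation allele frequencies follow the
#' Balding-Nichols model with divergence parameter \code{fst}; genotypes are
#' binomial(2, subpopulation frequency).
#'
#' @param n_individuals number of individuals (default 697, split evenly
#'   across subpopulations).
#' @param n_variants number of variants in the region (default 200).
#' @param n_subpops number of ancestral subpopulations (default 2).
#' @param fst Balding-Nichols divergence in \[0, 0.5).
#' @param maf_min,maf_max,maf_shape truncated-Beta ancestral MAF spectrum.
#' @param causal_ids integer indices of causal variants (may be empty).
#' @param effect_sizes per-causal additive effects on the trait, per copy of
#'   the minor allele.
#' @param causal_maf_max optional cap on the ancestral MAF of causal
#'   variants (e.g. 0.05 to plant only rare causal variants).
#' @param structure_effect additive trait shift per subpopulation label
#'   (0-based), the confounding between trait and ancestry.
#' @param noise_sd residual standard deviation.
#' @param n_replicates number of trait replicates sharing the genotypes
#'   (default 200).
#' @param trait_name label carried on the phenotypes.
#' @param seed master simulation seed.
#' @return an object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_individuals = 697, n_variants = 200, n_subpops = 2,
                       fst = 0.1, maf_min = 0.002, maf_max = 0.5,
                       maf_shape = 0.1, causal_ids = integer(0),
                       effect_sizes = numeric(0), causal_maf_max = NA,
                       structure_effect = 0, noise_sd = 1,
                       n_replicates = 200, trait_name = "trait", seed = 1) {
  stopifnot(n_individuals >= 2, n_variants >= 1, n_subpops >= 1,
            fst >= 0, fst < 0.5, maf_min > 0, maf_max <= 0.5,
            maf_min < maf_max, maf_shape > 0, noise_sd >= 0,
            n_replicates >= 1)
  causal_ids <- as.integer(causal_ids)
  if (length(causal_ids) > 0) {
    if (any(causal_ids < 1 | causal_ids > n_variants)) {
      stop("causal_ids out of range")
    }
    if (length(effect_sizes) != length(causal_ids)) {
      stop("effect_sizes must align with causal_ids")
    }
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_variants = as.integer(n_variants), n_subpops = as.integer(n_subpops),
    fst = fst, maf_min = maf_min, maf_max = maf_max, maf_shape = maf_shape,
    causal_ids = causal_ids, effect_sizes = as.numeric(effect_sizes),
    causal_maf_max = causal_maf_max, structure_effect = structure_effect,
    noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
    trait_name = trait_name, seed = as.integer(seed)),
    class = "sim_config")
}

# Draw from the truncated Beta(shape, 10) ancestral MAF spectrum.
draw_maf <- function(n, lo, hi, shape) {
  s1 <- shape; s2 <- 10
  u <- stats::runif(n, stats::pbeta(lo, s1, s2), stats::pbeta(hi, s1, s2))
  stats::qbeta(u, s1, s2)
}

#' Simulate structured genotypes
#'
#' Ancestral MAFs come from the configured rare-skewed spectrum; each
#' subpopulation's allele frequency is drawn from the Balding-Nichols
#' distribution \code{Beta(p(1-F)/F, (1-p)(1-F)/F)}; each individual's
#' allele count is binomial(2, its subpopulation's frequency). Variants that
#' come out monomorphic in sample are redrawn up to 20 times, then kept
#' with a warning.
#'
#' @param config a [sim_config()].
#' @return list with \code{genotypes} (a [genotype_matrix()]),
#'   \code{subpop_labels} (0-based integer per individual), and
#'   \code{ancestral_maf}.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals; m <- config$n_variants
  pops <- rep(seq_len(config$n_subpops) - 1L, length.out = n)
  with_seed(derive_seed(config$seed, "sim-genotypes"), {
    counts <- matrix(0, n, m)
    p_anc <- numeric(m)
    for (j in seq_len(m)) {
      hi <- config$maf_max
      if (j %in% config$causal_ids && !is.na(config$causal_maf_max)) {
        hi <- min(hi, config$causal_maf_max)
      }
      for (try in 1:20) {
        p <- draw_maf(1, config$maf_min, hi, config$maf_shape)
        if (config$fst > 0 && config$n_subpops > 1) {
          a <- p * (1 - config$fst) / config$fst
          b <- (1 - p) * (1 - config$fst) / config$fst
          p_sub <- stats::rbeta(config$n_subpops, a, b)
        } else {
          p_sub <- rep(p, config$n_subpops)
        }
        g <- stats::rbinom(n, 2, p_sub[pops + 1L])
        if (stats::var(g) > 0) break
      }
      if (stats::var(g) == 0) {
        warning("variant ", j, " is monomorphic in sample after 20 redraws")
      }
      counts[, j] <- g
      p_anc[j] <- p
    }
    pos <- sort(sample.int(5e7, m))
    list(genotypes = genotype_matrix(counts,
                                     variant_ids = sprintf("snp%05d",
                                                           seq_len(m)),
                                     chromosome = "chr1", position = pos),
         subpop_labels = pops, ancestral_maf = p_anc)
  })
}

#' Simulate replicated quantitative traits on fixed genotypes
#'
#' Each replicate draws
#' \code{y = sum(effect_i * count_i) + structure_effect * subpop + N(0, noise_sd)}
#' with fresh noise; all replicates share the same genotypes, mirroring a
#' benchmark design of many phenotype replicates on one SNP dataset.
#'
#' @param genotypes a [genotype_matrix()].
#' @param subpop_labels 0-based integer per individual.
#' @param config a [sim_config()].
#' @return list of phenotype objects (each a list with \code{values},
#'   \code{replicate_id}, \code{trait_name}).
#' @export
simulate_traits <- function(genotypes, subpop_labels, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- n_individuals(genotypes)
  genetic <- if (length(config$causal_ids) > 0) {
    drop(counts_filled(genotypes$counts)[, config$causal_ids, drop = FALSE] %*%
           config$effect_sizes)
  } else numeric(n)
  base <- genetic + config$structure_effect * subpop_labels
  with_seed(derive_seed(config$seed, "sim-traits"), {
    lapply(seq_len(config$n_replicates), function(r) {
      structure(list(values = base + stats::rnorm(n, 0, config$noise_sd),
                     replicate_id = r, trait_name = config$trait_name),
                class = "phenotype")
    })
  })
}

#' Simulate a complete dataset
#'
#' @param config a [sim_config()].
#' @return an object of class \code{"sim_output"}: \code{genotypes},
#'   \code{subpop_labels}, \code{phenotypes} (list, one per replicate), and
#'   \code{truth} (causal ids, effect sizes, ancestral MAFs).
#' @export
simulate_dataset <- function(config) {
  g <- simulate_genotypes(config)
  ph <- simulate_traits(g$genotypes, g$subpop_labels, config)
  structure(list(genotypes = g$genotypes, subpop_labels = g$subpop_labels,
                 phenotypes = ph,
                 truth = list(causal_ids = config$causal_ids,
                              effect_sizes = config$effect_sizes,
                              ancestral_maf = g$ancestral_maf),
                 config = config),
            class = "sim_output")
}

#' Scenario presets emulating benchmark quantitative traits
#'
#' Three canned configurations:
#' \describe{
#'   \item{q1_like}{many (15) rare causal variants (ancestral MAF <= 0.05)
#'     with sizable effects and mild structure confounding -- a trait with
#'     real aggregative rare-variant signal.}
#'   \item{q2_like}{fewer (8) and weaker causal variants.}
#'   \item{q4_like}{no causal variants but a strong trait shift between
#'     subpopulations: a pure structured null whose association signal is
#'     entirely confounding.}
#' }
#'
#' @param name one of \code{"q1_like"}, \code{"q2_like"}, \code{"q4_like"}.
#' @param ... overrides passed to [sim_config()] (e.g. \code{seed},
#'   \code{n_replicates}, \code{structure_effect}).
#' @return a [sim_config()].
#' @export
scenario_presets <- function(name = c("q1_like", "q2_like", "q4_like"), ...) {
  name <- match.arg(name)
  over <- list(...)
  nv <- if (!is.null(over$n_variants)) over$n_variants else 200
  spread <- function(n_causal) {
    unique(round(seq(max(2, nv * 0.02), nv * 0.75, length.out = n_causal)))
  }
  base <- switch(name,
    q1_like = {
      ids <- spread(15)
      list(causal_ids = ids,
           effect_sizes = seq(0.5, 1.1, length.out = length(ids)),
           causal_maf_max = 0.05, structure_effect = 0.5,
           trait_name = "q1_like")
    },
    q2_like = {
      ids <- spread(8)
      list(causal_ids = ids,
           effect_sizes = seq(0.3, 0.6, length.out = length(ids)),
           causal_maf_max = 0.05, structure_effect = 0.5,
           trait_name = "q2_like")
    },
    q4_like = list(causal_ids = integer(0), effect_sizes = numeric(0),
                   structure_effect = 1.6, trait_name = "q4_like"))
  do.call(sim_config, utils::modifyList(base, over))
}
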