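#' Run the full per-region association pipeline
#'
#' For each region: adjust every trait replicate for population structure by
#' regressing out the leading genotype PCs (computed once per region), run
#' the configured subset search per replicate, assess overall fit by a
#' permutation test, accumulate per-variant selection frequencies across
#' replicates, and (when causal variants are known) test causal enrichment.
#' Every random stream is derived from the single master seed, so repeated
#' runs with the same configuration produce byte-identical outputs.
#'
#' @param genotypes a [genotype_matrix()] or a genotype file path.
#' @param phenotypes list of phenotype objects (or a phenotype TSV path).
#' @param region chromosome name or \code{"all"}.
#' @param statistic \code{"LL"}, \code{"MB"} or \code{"ME"}.
#' @param optimizer \code{"mcmc"} or \code{"ga"}.
#' @param k subset size (default 20).
#' @param n_pcs PCs regressed out of each phenotype (default 10; 0 disables
#'   adjustment).
#' @param B permutations per replicate (default 1000).
#' @param control optimizer hyperparameters for [make_search_fn()].
#' @param causal_ids optional known causal variant ids (character) or
#'   indices, enabling the enrichment test.
#' @param seed master seed.
#' @param output_dir directory for the TSV/JSON outputs; created if needed.
#'   NULL skips file output.
#' @param perm_effort see [permutation_test()].
#' @param verbose print per-region progress.
#' @return (invisibly) a list with one element per region:
#'   \code{p_table} (data.frame region/statistic/replicate/observed_best_r2/
#'   B/p_value), \code{inclusion} (per-variant selection frequency across
#'   replicates' best subsets), \code{qq} (Q-Q pairs), \code{enrichment}
#'   (or NULL), \code{best_subsets}.
#' @export
run_pipeline <- function(genotypes, phenotypes, region = "all",
                         statistic = "MB", optimizer = "mcmc", k = 20,
                         n_pcs = 10, B = 1000, control = list(),
                         causal_ids = NULL, seed = 1, output_dir = NULL,
                         perm_effort = 1, verbose = TRUE) {
  if (is.character(genotypes)) genotypes <- read_genotypes(genotypes)
  if (is.character(phenotypes)) {
    phenotypes <- read_phenotypes(phenotypes, rownames(genotypes$counts))
  }
  regions <- if (identical(region, "all")) unique(genotypes$chromosome)
             else region
  if (!is.null(output_dir) && !dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }
  search_fn <- make_search_fn(optimizer, statistic, k = k, control = control)
  out <- list()

  for (reg in regions) {
    g <- subset_region(genotypes, reg)
    if (verbose) {
      message(sprintf(
        "region %s: %d variants, %d individuals | stat=%s opt=%s k=%d n_pcs=%d B=%d",
        reg, n_variants(g), n_individuals(g), statistic, optimizer, k,
        n_pcs, B))
    }
    scores <- if (n_pcs > 0) pc_scores(g, n_pcs) else NULL
    rows <- list(); best_subsets <- list()
    for (r in seq_along(phenotypes)) {
      ph <- phenotypes[[r]]
      y <- if (n_pcs > 0) {
        pc_adjust(g, ph$values, n_pcs, scores = scores)$residual_phenotype
      } else ph$values
      pt <- permutation_test(search_fn, g, y, B = B,
                             rng_seed = derive_seed(seed, paste0("perm-", reg), r),
                             perm_effort = perm_effort)
      best_subsets[[r]] <- pt$observed_result$best_subset
      rows[[r]] <- data.frame(region = reg, statistic = statistic,
                              replicate = r,
                              observed_best_r2 = pt$observed_best,
                              B = B, p_value = pt$p_value)
      if (verbose && r %% 25 == 0) {
        message(sprintf("  replicate %d/%d done", r, length(phenotypes)))
      }
    }
    p_table <- do.call(rbind, rows)
    incl <- numeric(n_variants(g))
    for (s in best_subsets) incl[s$indices] <- incl[s$indices] + 1
    inclusion <- data.frame(region = reg, variant_id = g$variant_ids,
                            chromosome = g$chromosome,
                            position = g$position,
                            selection_freq = incl / length(best_subsets))
    qq <- qq_data(p_table$p_value, B = B)
    enrich <- NULL
    if (!is.null(causal_ids)) {
      cid <- if (is.character(causal_ids)) {
        stats::na.omit(match(causal_ids, g$variant_ids))
      } else causal_ids
      if (length(cid) > 0 && length(cid) < n_variants(g)) {
        enrich <- causal_enrichment(best_subsets, cid, n_variants(g))
      }
    }
    if (!is.null(output_dir)) {
      pre <- file.path(output_dir, paste0(reg, "_", statistic, "_",
                                          optimizer))
      utils::write.table(p_table, paste0(pre, "_pvalues.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(inclusion, paste0(pre, "_inclusion.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(qq, paste0(pre, "_qq.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      if (!is.null(enrich)) {
        jsonlite::write_json(
          list(table = enrich$table, chi2 = enrich$chi2, p = enrich$p,
               n_replicates = enrich$n_replicates),
          paste0(pre, "_enrichment.json"), auto_unbox = TRUE, digits = NA)
      }
      cfg <- list(region = reg, statistic = statistic, optimizer = optimizer,
                  k = k, n_pcs = n_pcs, B = B, seed = seed,
                  n_replicates = length(phenotypes), control = control)
      yaml::write_yaml(cfg, paste0(pre, "_config.yaml"))
    }
    out[[reg]] <- list(p_table = p_table, inclusion = inclusion, qq = qq,
                       enrichment = enrich, best_subsets = best_subsets)
  }
  invisible(out)
}
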