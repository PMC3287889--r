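#' Build a configured subset-search function
#'
#' Packages an optimizer, score statistic and hyperparameters into a closure
#' \code{function(genotypes, phenotype, rng_seed)} returning a search result.
#' Weights and the association-weighted proposal kernel are recomputed
#' inside the closure on every call, so that under phenotype permutation the
#' marginal-effect (ME) weights and the kernel are re-derived from the
#' permuted trait, as the null requires.
#'
#' @param optimizer \code{"mcmc"} or \code{"ga"}.
#' @param statistic \code{"LL"}, \code{"MB"} or \code{"ME"}.
#' @param k subset size (default 20).
#' @param control named list of optimizer hyperparameters passed on to
#'   [run_mc3()] or [run_ga()] (e.g. \code{iterations}, \code{n_chains},
#'   \code{pop_size}, \code{generations}).
#' @return a search closure suitable for [permutation_test()].
#' @export
make_search_fn <- function(optimizer = c("mcmc", "ga"),
                           statistic = c("MB", "LL", "ME"),
                           k = 20, control = list()) {
  optimizer <- match.arg(optimizer)
  statistic <- match.arg(statistic)
  function(genotypes, phenotype, rng_seed = NULL) {
    w <- compute_weights(genotypes, statistic,
                         phenotype = if (statistic == "ME") phenotype)
    kern <- proposal_kernel(genotypes, phenotype)
    args <- c(list(genotypes = genotypes, weights = w,
                   phenotype = phenotype, k = k, kernel_weights = kern,
                   rng_seed = rng_seed),
              control)
    if (optimizer == "mcmc") do.call(run_mc3, args)
    else do.call(run_ga, args)
  }
}

# Pull the best r2 out of whatever a search function returned.
best_r2_of <- function(res) {
  if (is.numeric(res) && length(res) == 1) return(res)
  if (!is.null(res$best_fitness)) return(res$best_fitness$r2)
  stop("search function must return a numeric or an object with best_fitness")
}

#' Permutation test for the optimized score statistic
#'
#' Runs the configured search once on the observed phenotype and once on
#' each of B independent uniform permutations of it, and reports the
#' empirical p-value \eqn{p = (1 + \#\{null \ge observed\}) / (1 + B)},
#' which is strictly positive (minimum 1/(1+B)). Permutation is applied to
#' the supplied (typically PC-adjusted) phenotype vector; genotypes and PC
#' scores stay attached to individuals.
#'
#' @param search_fn a closure \code{function(genotypes, phenotype,
#'   rng_seed)}, e.g. from [make_search_fn()]; deterministic given its seed.
#' @param genotypes a [genotype_matrix()].
#' @param phenotype numeric trait vector (PC-adjusted when correcting for
#'   structure).
#' @param B number of permutations (default 1000).
#' @param rng_seed master seed; permutation draws and per-search seeds are
#'   derived from it.
#' @param perm_effort scale factor in (0, 1] applied to the search effort of
#'   the null runs only, via a \code{control} override understood by the
#'   closure; the default 1 keeps observed and null searches identical
#'   (required for calibrated p-values). Values below 1 are a logged
#'   approximation.
#' @return an object of class \code{"permutation_null"}: \code{observed_best}
#'   (r-squared), \code{null_best} (length-B numeric), \code{p_value},
#'   \code{B}, and \code{observed_result} (the full search result).
#' @export
permutation_test <- function(search_fn, genotypes, phenotype, B = 1000,
                             rng_seed = NULL, perm_effort = 1) {
  if (B < 1) stop("B must be at least 1")
  if (perm_effort < 1) {
    message("perm_effort = ", perm_effort,
            ": null searches use reduced effort; p-values are approximate")
  }
  seed0 <- if (is.null(rng_seed)) sample.int(2^30, 1) else as.integer(rng_seed)
  obs_res <- search_fn(genotypes, phenotype,
                       rng_seed = derive_seed(seed0, "perm-obs"))
  observed <- best_r2_of(obs_res)
  null_best <- numeric(B)
  n <- length(phenotype)
  for (b in seq_len(B)) {
    perm <- with_seed(derive_seed(seed0, "perm-shuffle", b),
                      sample.int(n, n))
    res_b <- search_fn(genotypes, phenotype[perm],
                       rng_seed = derive_seed(seed0, "perm-search", b))
    null_best[b] <- best_r2_of(res_b)
  }
  p <- (1 + sum(null_best >= observed)) / (1 + B)
  structure(list(observed_best = observed, null_best = null_best,
                 p_value = p, B = B, observed_result = obs_res),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "permutation_null: observed best r2 = %.4f, B = %d, p = %.4g\n",
    x$observed_best, x$B, x$p_value))
  invisible(x)
}

#' Chi-square test for enrichment of causal variants in selected subsets
#'
#' Pools, over replicates, the (variant, replicate) pairs cross-classified
#' by selection status (member of that replicate's best subset) and
#' causality, and applies the Pearson chi-square test with 1 df (no
#' continuity correction; pooled counts are large).
#'
#' @param selected_per_replicate list of [snp_subset()] (or index vectors),
#'   one per replicate.
#' @param causal_ids integer indices (or character ids, with
#'   \code{variant_ids} supplied) of the truly causal variants; must be a
#'   non-empty strict subset of the variants.
#' @param n_variants total number of variants.
#' @param variant_ids optional character vector to resolve character
#'   \code{causal_ids}.
#' @param unique_snps if TRUE, count each variant at most once across
#'   replicates (selected if it was ever selected) instead of pooling
#'   (variant, replicate) pairs.
#' @return an object of class \code{"enrichment_table"}: \code{table} (2x2),
#'   \code{chi2}, \code{p}, \code{n_replicates}.
#' @export
causal_enrichment <- function(selected_per_replicate, causal_ids, n_variants,
                              variant_ids = NULL, unique_snps = FALSE) {
  if (length(selected_per_replicate) < 1) stop("need at least one replicate")
  if (is.character(causal_ids)) {
    if (is.null(variant_ids)) stop("variant_ids needed for character causal_ids")
    causal_ids <- match(causal_ids, variant_ids)
    if (anyNA(causal_ids)) stop("unknown causal variant id")
  }
  causal <- logical(n_variants)
  causal[causal_ids] <- TRUE
  if (!any(causal) || all(causal)) {
    stop("causal_ids must be a non-empty strict subset of the variants")
  }
  sel_mat <- vapply(selected_per_replicate, function(s) {
    idx <- if (inherits(s, "snp_subset")) s$indices else as.integer(s)
    v <- logical(n_variants); v[idx] <- TRUE; v
  }, logical(n_variants))
  R <- length(selected_per_replicate)
  if (unique_snps) {
    sel <- rowSums(sel_mat) > 0
    tab <- matrix(c(sum(sel & causal), sum(sel & !causal),
                    sum(!sel & causal), sum(!sel & !causal)),
                  2, 2, byrow = TRUE)
  } else {
    sel_causal <- sum(sel_mat[causal, , drop = FALSE])
    sel_non <- sum(sel_mat[!causal, , drop = FALSE])
    tab <- matrix(c(sel_causal, sel_non,
                    R * sum(causal) - sel_causal,
                    R * sum(!causal) - sel_non),
                  2, 2, byrow = TRUE)
  }
  dimnames(tab) <- list(c("selected", "not_selected"),
                        c("causal", "non_causal"))
  res <- pearson_chi2(tab)
  structure(list(table = tab, chi2 = res$chi2, p = res$p, n_replicates = R,
                 unique_snps = unique_snps),
            class = "enrichment_table")
}

# Pearson chi-square for a 2x2 table, 1 df, no continuity correction.
# Degenerate margins (a zero row or column) give chi2 = 0, p = 1.
pearson_chi2 <- function(tab) {
  if (any(tab < 0)) stop("counts must be non-negative")
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  if (any(e == 0) || n == 0) return(list(chi2 = 0, p = 1))
  chi2 <- sum((tab - e)^2 / e)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf(
    "causal enrichment over %d replicate(s): chi2 = %.4f, p = %.3g%s\n",
    x$n_replicates, x$chi2, x$p,
    if (x$unique_snps) " (unique SNPs)" else " (pooled)"))
  print(x$table)
  invisible(x)
}

#' Q-Q diagnostic pairs for a set of p-values
#'
#' Expected quantiles are \eqn{-\log_{10}(i/(m+1))} for rank i of m;
#' observed are \eqn{-\log_{10}} of the sorted p-values. Zero p-values are
#' clamped to 1/(1+B) with a warning.
#'
#' @param p_values numeric vector of p-values in (0, 1\].
#' @param B permutation count used to clamp exact zeros (default 1000).
#' @return data.frame with columns \code{expected} and \code{observed}
#'   (both on the -log10 scale, smallest p last).
#' @export
qq_data <- function(p_values, B = 1000) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  if (any(p_values == 0)) {
    warning("zero p-value(s) clamped to 1/(1+B) = ", 1 / (1 + B))
    p_values[p_values == 0] <- 1 / (1 + B)
  }
  m <- length(p_values)
  p_sorted <- sort(p_values)
  data.frame(expected = -log10(seq_len(m) / (m + 1)),
             observed = -log10(p_sorted))
}
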