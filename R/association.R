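# Fast core: squared Pearson correlation between a score vector and a
# pre-centered phenotype. yc = y - mean(y); syy = sum(yc^2) > 0.
# A constant score (zero variance) gets r = 0 by convention so the samplers
# can traverse all-zero burden scores without error.
r2_core <- function(s, yc, syy) {
  n <- length(s)
  sx <- sum(s)
  vs <- sum(s * s) - sx * sx / n
  if (vs <= 1e-12 * max(1, sx * sx / n)) return(c(r = 0, r2 = 0))
  sxy <- sum(s * yc)
  r <- sxy / sqrt(vs * syy)
  r <- max(-1, min(1, r))
  c(r = r, r2 = r * r)
}

#' Association fitness: squared Pearson correlation
#'
#' The optimizers measure how well a subset's aggregated burden score
#' predicts the trait by the square of the sample Pearson correlation
#' coefficient between score and phenotype. A constant score vector is
#' assigned r = 0 (rare-variant subsets can yield all-zero scores in small
#' samples and the search must be able to move through them).
#'
#' @param score numeric score vector (e.g. from [aggregate_score()]).
#' @param phenotype numeric trait vector of the same length; must not be
#'   constant.
#' @return an object of class \code{"rv_fitness"}: list with \code{r},
#'   \code{r2}, \code{n}.
#' @export
#' @examples
#' fitness(c(0, 1, 2), c(0, 0, 1))$r2  # 0.75
fitness <- function(score, phenotype) {
  n <- length(score)
  if (length(phenotype) != n) stop("score and phenotype lengths differ")
  if (n < 3) stop("need at least 3 individuals")
  yc <- phenotype - mean(phenotype)
  syy <- sum(yc^2)
  if (syy == 0) stop("phenotype is constant")
  v <- r2_core(score, yc, syy)
  structure(list(r = unname(v["r"]), r2 = unname(v["r2"]), n = n),
            class = "rv_fitness")
}

#' @export
print.rv_fitness <- function(x, ...) {
  cat(sprintf("fitness: r = %.4f, r2 = %.4f (n = %d)\n", x$r, x$r2, x$n))
  invisible(x)
}

#' Profile log-likelihood of the linear score-trait model
#'
#' Under the working model of a linear relationship between the burden score
#' and the mean trait value with normal residuals, the profile log-likelihood
#' of the fitted simple regression is \eqn{-(n/2) \log(1 - r^2)} up to an
#' additive constant that cancels in the MCMC Hastings ratio. r-squared is
#' clamped to 1 - 1e-12 before the logarithm.
#'
#' @param fit an \code{rv_fitness} (or a list with \code{r2} and \code{n}).
#' @return scalar log-likelihood (0 when r = 0; strictly increasing in r2).
#' @export
#' @examples
#' log_likelihood(fitness(c(0, 1, 2), c(0, 0, 1)))  # -1.5 * log(0.25)
log_likelihood <- function(fit) {
  r2 <- min(fit$r2, 1 - 1e-12)
  -(fit$n / 2) * log1p(-r2)
}

#' Per-variant marginal association with the trait
#'
#' The squared Pearson correlation between each variant's allele count and
#' the phenotype; the quantity the MCMC proposal kernel uses to favour
#' trait-associated variants. Monomorphic variants get 0.
#'
#' @inheritParams marginal_effects
#' @return numeric vector of per-variant r-squared values in \[0, 1\].
#' @export
marginal_association <- function(genotypes, phenotype) {
  counts <- counts_filled(genotypes$counts)
  n <- nrow(counts)
  if (length(phenotype) != n) stop("phenotype length must match individuals")
  yc <- phenotype - mean(phenotype)
  syy <- sum(yc^2)
  if (syy == 0) stop("phenotype is constant")
  gs <- colSums(counts)
  sgg <- colSums(counts^2) - gs^2 / n
  sgy <- drop(crossprod(counts, yc))
  r2 <- ifelse(sgg > 1e-12, sgy^2 / (sgg * syy), 0)
  unname(pmin(r2, 1))
}

#' Principal-component scores of a genotype matrix
#'
#' PCs are computed from the column-standardized allele-count matrix
#' (mean 0, unit variance per variant with the 1/(n-1) convention).
#' Missing entries are filled with the variant mean before standardization;
#' monomorphic (zero-variance) variants are dropped from the PCA but remain
#' in the search space.
#'
#' @param genotypes a [genotype_matrix()].
#' @param n_pcs number of leading components to return.
#' @return an individuals x \code{n_pcs} matrix of PC scores.
#' @export
pc_scores <- function(genotypes, n_pcs = 10) {
  counts <- genotypes$counts
  if (anyNA(counts)) {
    mu <- colMeans(counts, na.rm = TRUE)
    na_idx <- which(is.na(counts), arr.ind = TRUE)
    counts[na_idx] <- mu[na_idx[, 2]]
  }
  sds <- apply(counts, 2, stats::sd)
  keep <- sds > 0
  if (sum(keep) < n_pcs) {
    stop("need at least ", n_pcs, " non-monomorphic variants for ", n_pcs,
         " PCs")
  }
  x <- scale(counts[, keep, drop = FALSE])
  n_pcs <- min(n_pcs, nrow(x) - 1, ncol(x))
  sv <- svd(x, nu = n_pcs, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  scores
}

#' Adjust a phenotype for population structure
#'
#' Regresses the phenotype on an intercept and the leading genotype
#' principal components, returning the residual. The residual is orthogonal
#' to every retained PC and to the constant vector, and its variance never
#' exceeds the original phenotype's.
#'
#' @param genotypes a [genotype_matrix()]; ignored when \code{scores} is
#'   supplied.
#' @param phenotype numeric trait vector.
#' @param n_pcs number of PCs to regress out (default 10). \code{n_pcs <= 0}
#'   yields the identity adjustment: the centered phenotype.
#' @param scores optional precomputed PC score matrix from [pc_scores()];
#'   genotypes are fixed under phenotype permutation, so PCA can be computed
#'   once and reused across replicates and permutations.
#' @return an object of class \code{"pc_adjustment"}: list with
#'   \code{n_pcs}, \code{pc_scores}, \code{residual_phenotype}.
#' @export
pc_adjust <- function(genotypes, phenotype, n_pcs = 10, scores = NULL) {
  if (n_pcs <= 0) {
    return(structure(list(n_pcs = 0L, pc_scores = NULL,
                          residual_phenotype = phenotype - mean(phenotype)),
                     class = "pc_adjustment"))
  }
  if (is.null(scores)) {
    if (n_pcs >= n_individuals(genotypes)) {
      stop("n_pcs must be smaller than the number of individuals")
    }
    scores <- pc_scores(genotypes, n_pcs)
  }
  scores <- scores[, seq_len(min(n_pcs, ncol(scores))), drop = FALSE]
  if (nrow(scores) != length(phenotype)) {
    stop("PC scores and phenotype lengths differ")
  }
  res <- stats::lm.fit(cbind(1, scores), phenotype)$residuals
  structure(list(n_pcs = as.integer(ncol(scores)), pc_scores = scores,
                 residual_phenotype = unname(res)),
            class = "pc_adjustment")
}
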