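#' Per-variant marginal effect sizes
#'
#' For a quantitative trait, the slope of the one-predictor least-squares
#' regression of the phenotype on the variant's allele count. For a binary
#' trait, the log odds ratio from the 2x2 carrier (count > 0) vs non-carrier
#' table, with 0.5 added to every cell when any cell is zero. Monomorphic
#' variants get effect 0, so they can never drive a score.
#'
#' @param genotypes a [genotype_matrix()].
#' @param phenotype numeric vector, one value per individual; must not be
#'   constant.
#' @param trait_type \code{"quantitative"} or \code{"binary"}.
#' @return numeric vector of per-variant effects.
#' @export
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2), ncol = 1))
#' marginal_effects(g, c(1, 3, 5))  # slope 2
marginal_effects <- function(genotypes, phenotype,
                             trait_type = c("quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  counts <- counts_filled(genotypes$counts)
  n <- nrow(counts)
  if (n < 3) stop("need at least 3 individuals")
  if (length(phenotype) != n) stop("phenotype length must match individuals")
  if (stats::var(phenotype) == 0) stop("phenotype is constant")
  if (trait_type == "quantitative") {
    yc <- phenotype - mean(phenotype)
    gc_sum <- colSums(counts)
    sgg <- colSums(counts^2) - gc_sum^2 / n
    sgy <- drop(crossprod(counts, yc))
    eff <- ifelse(sgg > 0, sgy / sgg, 0)
    return(unname(eff))
  }
  if (!all(phenotype %in% c(0, 1))) stop("binary trait must be coded 0/1")
  carrier <- counts > 0
  a <- colSums(carrier & phenotype == 1)        # carrier, case
  b <- colSums(carrier & phenotype == 0)        # carrier, control
  c_ <- colSums(!carrier & phenotype == 1)
  d <- colSums(!carrier & phenotype == 0)
  mono <- genotypes$maf == 0
  zero <- (a == 0 | b == 0 | c_ == 0 | d == 0)
  a <- a + 0.5 * zero; b <- b + 0.5 * zero
  c_ <- c_ + 0.5 * zero; d <- d + 0.5 * zero
  eff <- log((a * d) / (b * c_))
  eff[mono] <- 0
  unname(eff)
}

#' Per-variant weights for the three score statistics
#'
#' Three weighted-sum burden statistics are supported:
#' \describe{
#'   \item{LL}{unweighted: each variant contributes its minor-allele count
#'     (weight 1).}
#'   \item{MB}{each variant weighted by the inverse of its sample minor
#'     allele frequency, \code{1/maf}. With \code{mb_original = TRUE} the
#'     classical form \code{1/sqrt(n * q * (1 - q))} is used instead.}
#'   \item{ME}{each variant weighted by the absolute value of its marginal
#'     effect size (signed with \code{signed = TRUE}).}
#' }
#' Monomorphic variants receive weight 0 under MB (with a warning): they can
#' never contribute to a score and 1/0 is avoided.
#'
#' @param genotypes a [genotype_matrix()].
#' @param kind \code{"LL"}, \code{"MB"} or \code{"ME"}.
#' @param phenotype required for \code{kind = "ME"}.
#' @param trait_type passed to [marginal_effects()] for ME.
#' @param signed use signed marginal effects for ME (default unsigned).
#' @param mb_original use the classical inverse-variance allele-frequency
#'   weight for MB instead of plain \code{1/maf}.
#' @return an object of class \code{"weight_scheme"} with elements
#'   \code{kind} and \code{weights} (finite, and non-negative unless
#'   \code{signed}).
#' @export
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 1, 0, 1, 2), nrow = 3))
#' compute_weights(g, "MB")$weights
compute_weights <- function(genotypes, kind = c("LL", "MB", "ME"),
                            phenotype = NULL,
                            trait_type = "quantitative",
                            signed = FALSE, mb_original = FALSE) {
  kind <- match.arg(kind)
  m <- n_variants(genotypes)
  w <- switch(kind,
    LL = rep(1, m),
    MB = {
      maf <- genotypes$maf
      mono <- maf == 0
      if (any(mono)) {
        warning(sum(mono), " monomorphic variant(s) assigned MB weight 0")
      }
      if (mb_original) {
        n <- n_individuals(genotypes)
        ifelse(mono, 0, 1 / sqrt(n * maf * (1 - maf)))
      } else {
        ifelse(mono, 0, 1 / maf)
      }
    },
    ME = {
      if (is.null(phenotype)) stop("phenotype is required for kind = 'ME'")
      eff <- marginal_effects(genotypes, phenotype, trait_type)
      if (signed) eff else abs(eff)
    })
  if (any(!is.finite(w))) stop("non-finite weight computed")
  structure(list(kind = kind, weights = unname(w)), class = "weight_scheme")
}

#' Aggregated burden score for a variant subset
#'
#' The per-individual score is the weighted sum of minor-allele counts over
#' the subset's variants. Missing genotype entries contribute 0 (the
#' reference-homozygote convention).
#'
#' @param genotypes a [genotype_matrix()].
#' @param subset a [snp_subset()] (or plain index vector).
#' @param weights a \code{weight_scheme} covering all variants, or a numeric
#'   vector of per-variant weights.
#' @return numeric vector of per-individual scores.
#' @export
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2), nrow = 1))
#' aggregate_score(g, snp_subset(1:3), compute_weights(g, "LL"))  # 3
aggregate_score <- function(genotypes, subset, weights) {
  subset <- check_subset(subset, genotypes)
  w <- if (inherits(weights, "weight_scheme")) weights$weights else weights
  if (length(w) != n_variants(genotypes)) {
    stop("weights must cover all ", n_variants(genotypes), " variants")
  }
  counts <- counts_filled(genotypes$counts)
  idx <- subset$indices
  drop(counts[, idx, drop = FALSE] %*% w[idx])
}
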