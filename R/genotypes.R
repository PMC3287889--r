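#' Genotype matrix container
#'
#' Holds an individuals x variants matrix of minor-allele counts together
#' with per-variant metadata. Entries are 0, 1, 2 or \code{NA} (missing
#' genotype). The sample minor-allele frequency (MAF) is computed from the
#' counts and folded into \[0, 0.5\].
#'
#' @param counts numeric matrix, individuals in rows, variants in columns;
#'   entries in \{0, 1, 2, NA\}.
#' @param variant_ids character vector of unique variant identifiers; defaults
#'   to column names or \code{"snp<j>"}.
#' @param chromosome character vector (length 1, recycled, or one per
#'   variant).
#' @param position 1-based integer positions, one per variant.
#' @return an object of class \code{"genotype_matrix"} with elements
#'   \code{counts}, \code{variant_ids}, \code{chromosome}, \code{position},
#'   \code{maf}.
#' @export
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 0, 0, 1), nrow = 3))
#' g$maf
genotype_matrix <- function(counts, variant_ids = NULL, chromosome = "chr1",
                            position = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  ok <- counts %in% c(0, 1, 2) | is.na(counts)
  if (!all(ok)) {
    stop("genotype counts must be 0, 1, 2 or NA; offending values: ",
         paste(utils::head(unique(counts[!ok]), 5), collapse = ", "))
  }
  m <- ncol(counts)
  if (is.null(variant_ids)) {
    variant_ids <- colnames(counts)
    if (is.null(variant_ids)) variant_ids <- sprintf("snp%05d", seq_len(m))
  }
  if (anyDuplicated(variant_ids)) stop("variant_ids must be unique")
  if (length(variant_ids) != m) stop("variant_ids length must match columns")
  if (length(chromosome) == 1) chromosome <- rep(chromosome, m)
  if (length(chromosome) != m) stop("chromosome must have one entry per variant")
  if (is.null(position)) position <- seq_len(m)
  if (length(position) != m || any(position < 1)) {
    stop("position must be 1-based, one per variant")
  }
  colnames(counts) <- variant_ids
  structure(
    list(counts = counts, variant_ids = as.character(variant_ids),
         chromosome = as.character(chromosome),
         position = as.integer(position),
         maf = compute_maf(counts)),
    class = "genotype_matrix")
}

#' Sample minor-allele frequency from allele counts
#'
#' @param counts allele-count matrix (0/1/2/NA).
#' @return per-variant MAF in \[0, 0.5\] (allele frequency folded at 0.5);
#'   missing entries are excluded from the denominator.
#' @export
compute_maf <- function(counts) {
  af <- colMeans(counts, na.rm = TRUE) / 2
  af[is.nan(af)] <- 0
  unname(pmin(af, 1 - af))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$chromosome), collapse = ", ")))
  cat(sprintf("  MAF range [%.4g, %.4g]; %d monomorphic; %.2f%% missing\n",
              min(x$maf), max(x$maf), sum(x$maf == 0),
              100 * mean(is.na(x$counts))))
  invisible(x)
}

#' Number of individuals / variants
#' @param x a \code{genotype_matrix}.
#' @return integer count.
#' @export
n_individuals <- function(x) nrow(x$counts)

#' @rdname n_individuals
#' @export
n_variants <- function(x) ncol(x$counts)

#' Restrict a genotype matrix to one region
#'
#' @param x a \code{genotype_matrix}.
#' @param region chromosome name, or \code{"all"} for no filtering.
#' @return a \code{genotype_matrix} containing only that region's variants.
#' @export
subset_region <- function(x, region) {
  if (identical(region, "all")) return(x)
  keep <- x$chromosome == region
  if (!any(keep)) stop("no variants on region '", region, "'")
  genotype_matrix(x$counts[, keep, drop = FALSE], x$variant_ids[keep],
                  x$chromosome[keep], x$position[keep])
}

#' Fixed-size variant subset
#'
#' The unit the optimizers move through: a set of \code{k} distinct variant
#' column indices (1-based) into a genotype matrix. Indices are stored
#' sorted so two subsets with the same members compare equal.
#'
#' @param indices integer vector of distinct variant indices.
#' @param k subset size; must equal \code{length(indices)}.
#' @return an object of class \code{"snp_subset"}.
#' @export
#' @examples
#' snp_subset(c(4, 1, 9))
snp_subset <- function(indices, k = length(indices)) {
  indices <- as.integer(indices)
  if (length(indices) == 0) stop("subset must contain at least one variant")
  if (anyDuplicated(indices)) stop("subset indices must be distinct")
  if (length(indices) != k) stop("subset has ", length(indices),
                                 " indices but k = ", k)
  if (any(indices < 1)) stop("indices are 1-based")
  structure(list(indices = sort(indices), k = as.integer(k)),
            class = "snp_subset")
}

#' @export
print.snp_subset <- function(x, ...) {
  cat("snp_subset (k =", x$k, "):", x$indices, "\n")
  invisible(x)
}

# Validate a subset against a genotype matrix.
check_subset <- function(subset, genotypes) {
  if (!inherits(subset, "snp_subset")) subset <- snp_subset(subset)
  if (max(subset$indices) > n_variants(genotypes)) {
    stop("subset index out of range for genotype matrix")
  }
  subset
}
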