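# Genotype and phenotype file I/O.
#
# Coordinates: VCF positions are 1-based and preserved in all outputs;
# internal variant indexing into the count matrix is by column number.

GT_CODE <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1,
             "1|0" = 1, "1/1" = 2, "1|1" = 2, "./." = NA, ".|." = NA,
             "." = NA)

#' Read a genotype matrix from VCF or TSV
#'
#' VCF files are parsed with vcfR; allele counts are the number of ALT
#' alleles in the (unphased or phased) GT field, with \code{./.} read as
#' missing. Only biallelic records are accepted; multi-allelic records must
#' be split upstream. The TSV format is an individuals x variants matrix
#' with an \code{individual_id} column and variant-id header, accompanied by
#' a \code{<path>.meta.tsv} sidecar with columns \code{variant_id},
#' \code{chromosome}, \code{position}.
#'
#' @param path file path.
#' @param format \code{"vcf"} or \code{"tsv"}; guessed from the extension
#'   by default.
#' @return a [genotype_matrix()]; individual ids are kept as row names.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-record VCF
    multi <- grepl(",", fix[, "ALT"])
    if (any(multi)) {
      stop("non-biallelic record(s): ",
           paste(fix[multi, "ID"][seq_len(min(5, sum(multi)))],
                 collapse = ", "))
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    counts <- matrix(GT_CODE[gt], nrow = nrow(gt))
    bad <- !(gt %in% names(GT_CODE)) & !is.na(gt)
    if (any(bad)) {
      w <- which(bad, arr.ind = TRUE)[1, ]
      stop("unparseable GT '", gt[bad][1], "' at record ", fix[w[1], "ID"])
    }
    g <- genotype_matrix(t(counts), variant_ids = fix[, "ID"],
                         chromosome = fix[, "CHROM"],
                         position = as.integer(fix[, "POS"]))
    rownames(g$counts) <- colnames(gt)
    return(g)
  }
  mat <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- mat[[1]]
  counts <- as.matrix(mat[, -1, drop = FALSE])
  meta_path <- paste0(path, ".meta.tsv")
  if (file.exists(meta_path)) {
    meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    ord <- match(colnames(counts), meta$variant_id)
    if (anyNA(ord)) stop("metadata sidecar is missing variant(s)")
    g <- genotype_matrix(counts, colnames(counts),
                         meta$chromosome[ord], meta$position[ord])
  } else {
    g <- genotype_matrix(counts, colnames(counts))
  }
  rownames(g$counts) <- ids
  g
}

#' Write a genotype matrix to VCF or TSV
#'
#' The VCF output is minimal v4.2 with a GT-only FORMAT and unphased
#' genotypes (REF A, ALT C placeholders; the model only uses allele
#' counts). The TSV output writes the matrix plus the metadata sidecar.
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output path.
#' @param format \code{"vcf"} or \code{"tsv"}.
#' @param individual_ids optional ids; default row names or \code{ind<i>}.
#' @return the path, invisibly.
#' @export
write_genotypes <- function(genotypes, path, format = c("vcf", "tsv"),
                            individual_ids = NULL) {
  format <- match.arg(format)
  counts <- genotypes$counts
  n <- nrow(counts)
  if (is.null(individual_ids)) {
    individual_ids <- rownames(counts)
    if (is.null(individual_ids)) individual_ids <- sprintf("ind%04d",
                                                           seq_len(n))
  }
  if (format == "tsv") {
    df <- data.frame(individual_id = individual_ids, counts,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    meta <- data.frame(variant_id = genotypes$variant_ids,
                       chromosome = genotypes$chromosome,
                       position = genotypes$position,
                       maf = genotypes$maf)
    utils::write.table(meta, paste0(path, ".meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  gt_str <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##source=rvsearch",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", individual_ids), collapse = "\t"))
  body <- vapply(seq_len(ncol(counts)), function(j) {
    g <- counts[, j]
    gt <- ifelse(is.na(g), "./.", gt_str[g + 1])
    paste(c(genotypes$chromosome[j], genotypes$position[j],
            genotypes$variant_ids[j], "A", "C", ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read replicated phenotypes from TSV
#'
#' Expects an \code{individual_id} column followed by one column per trait
#' replicate. Rows are realigned to the genotype file's individual order;
#' unknown or missing individuals are an error.
#'
#' @param path TSV path.
#' @param individual_ids character vector giving the genotype individual
#'   order; if NULL the file order is kept.
#' @return list of phenotype objects (\code{values}, \code{replicate_id},
#'   \code{trait_name}).
#' @export
read_phenotypes <- function(path, individual_ids = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("phenotype file needs id column plus >= 1 trait")
  ids <- as.character(df[[1]])
  if (!is.null(individual_ids)) {
    missing <- setdiff(individual_ids, ids)
    extra <- setdiff(ids, individual_ids)
    if (length(missing) > 0 || length(extra) > 0) {
      stop("individual id mismatch; missing: [",
           paste(utils::head(missing, 5), collapse = ", "),
           "] unknown: [", paste(utils::head(extra, 5), collapse = ", "),
           "]")
    }
    df <- df[match(individual_ids, ids), , drop = FALSE]
  }
  vals <- df[, -1, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) {
    stop("non-numeric phenotype column(s): ",
         paste(names(vals)[bad], collapse = ", "))
  }
  lapply(seq_along(vals), function(r) {
    structure(list(values = vals[[r]], replicate_id = r,
                   trait_name = names(vals)[r]),
              class = "phenotype")
  })
}

#' Write replicated phenotypes to TSV
#'
#' @param phenotypes list of phenotype objects sharing individual order.
#' @param path output path.
#' @param individual_ids ids for the first column.
#' @return the path, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path, individual_ids = NULL) {
  n <- length(phenotypes[[1]]$values)
  if (is.null(individual_ids)) individual_ids <- sprintf("ind%04d",
                                                         seq_len(n))
  df <- data.frame(individual_id = individual_ids)
  for (p in phenotypes) {
    df[[paste0(p$trait_name, "_rep", p$replicate_id)]] <- p$values
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
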