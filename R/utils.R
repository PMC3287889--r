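#' Derive a reproducible substream seed
#'
#' One master seed drives every stochastic component of a run. Named
#' substreams (e.g. \code{"sim"}, \code{"mcmc"}, \code{"perm"}) are derived
#' deterministically so that components remain independently reproducible.
#' The result always fits in a 32-bit integer.
#'
#' @param seed master seed (integer).
#' @param stream substream name (character scalar).
#' @param index optional integer offset, e.g. a replicate or permutation
#'   number, so that each unit of work gets its own stream.
#' @return an integer seed in \[0, 2^31 - 2\].
#' @export
#' @examples
#' derive_seed(1, "mcmc")
#' derive_seed(1, "perm", 17)
derive_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  code <- utf8ToInt(stream)
  h <- sum(code * seq_along(code))
  v <- ((abs(seed) %% 2147483647) * 48271) %% 2147483647 +
    (h * 1009 + index * 7919) %% 1048573
  as.integer(v %% 2147483647)
}

# Set the RNG state locally for a function body when a seed is supplied;
# NULL means "use the current RNG stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Sample k distinct indices from 1..m with probability proportional to w
# (successive sampling without replacement).
sample_weighted <- function(m, k, w) {
  if (all(w == 0)) w <- rep(1, m)
  sort(sample.int(m, k, replace = FALSE, prob = w))
}

# NA allele counts contribute 0 (reference-homozygote convention).
counts_filled <- function(counts) {
  if (anyNA(counts)) counts[is.na(counts)] <- 0
  counts
}
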