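#' Fitness-proportional parent selection
#'
#' Draws two members (with replacement) with probability proportional to
#' their squared-correlation fitness (roulette-wheel selection). When every
#' member has zero fitness, selection is uniform.
#'
#' @param pop a \code{ga_population} (list with \code{members}, a list of
#'   [snp_subset()], and \code{fitnesses}, numeric r-squared per member).
#' @return list of two \code{snp_subset} parents.
#' @export
select_parents <- function(pop) {
  f <- pop$fitnesses
  if (length(f) == 0) stop("empty population")
  prob <- if (sum(f) > 0) f else rep(1, length(f))
  i <- sample.int(length(f), 2, replace = TRUE, prob = prob)
  list(pop$members[[i[1]]], pop$members[[i[2]]])
}

#' Recombine two variant subsets
#'
#' The child inherits every variant shared by both parents, then fills the
#' remaining slots with a uniform random draw from the symmetric difference,
#' so its size is exactly k. Identical parents reproduce themselves.
#'
#' @param parent_a,parent_b [snp_subset()] objects of equal size.
#' @return a \code{snp_subset} of the same size.
#' @export
crossover <- function(parent_a, parent_b) {
  k <- parent_a$k
  if (parent_b$k != k) stop("parents must have equal size")
  a <- parent_a$indices; b <- parent_b$indices
  shared <- intersect(a, b)
  pool <- setdiff(union(a, b), shared)
  need <- k - length(shared)
  child <- if (need > 0) c(shared, pool[sample.int(length(pool), need)])
           else shared
  snp_subset(child, k)
}

#' Mutate a variant subset
#'
#' Each member is independently replaced, with probability
#' \code{mutation_rate}, by a uniformly chosen variant currently outside the
#' subset. Size and distinctness are preserved.
#'
#' @param subset a [snp_subset()].
#' @param mutation_rate per-member replacement probability in \[0, 1\].
#' @param n_variants total number of variants in the search space.
#' @return the mutated \code{snp_subset}.
#' @export
mutate <- function(subset, mutation_rate, n_variants) {
  if (mutation_rate < 0 || mutation_rate > 1) {
    stop("mutation_rate must be in [0, 1]")
  }
  idx <- subset$indices
  k <- length(idx)
  hit <- which(stats::runif(k) < mutation_rate)
  if (length(hit) == 0 || n_variants <= k) return(subset)
  mem <- logical(n_variants); mem[idx] <- TRUE
  for (h in hit) {
    cand <- which(!mem)
    new <- cand[sample.int(length(cand), 1)]
    mem[idx[h]] <- FALSE; mem[new] <- TRUE
    idx[h] <- new
  }
  snp_subset(idx, k)
}

#' Genetic-algorithm search for the best variant subset
#'
#' Evolves a population of fixed-size variant subsets ("chromosomes") whose
#' fitness is the squared Pearson correlation between the subset's
#' aggregated burden score and the trait. Each generation keeps the
#' \code{elitism} best members and fills the remainder by
#' fitness-proportional selection, recombination and mutation. The initial
#' population is sampled with probability proportional to the association
#' kernel, as for the MCMC chains.
#'
#' @inheritParams init_chains
#' @param pop_size population size (default 100).
#' @param generations number of generations (default 200).
#' @param mutation_rate per-member mutation probability (default 0.05).
#' @param elitism number of best members carried over unchanged (default 1;
#'   makes the best-per-generation trace non-decreasing).
#' @return an object of class \code{"ga_result"}: \code{best_subset},
#'   \code{best_fitness}, \code{inclusion_freq} (membership frequency in the
#'   final generation, sums to k), \code{fitness_trace} (best r-squared per
#'   generation).
#' @export
run_ga <- function(genotypes, weights, phenotype, k = 20, pop_size = 100,
                   generations = 200, mutation_rate = 0.05, elitism = 1,
                   kernel_weights = NULL, rng_seed = NULL) {
  if (pop_size < 2) stop("pop_size must be at least 2")
  counts <- counts_filled(genotypes$counts)
  m <- ncol(counts); n <- nrow(counts)
  if (k > m) stop("k = ", k, " exceeds the number of variants (", m, ")")
  w <- if (inherits(weights, "weight_scheme")) weights$weights else weights
  if (is.null(kernel_weights)) {
    kernel_weights <- proposal_kernel(genotypes, phenotype)
  }
  yc <- phenotype - mean(phenotype)
  syy <- sum(yc^2)
  if (syy == 0) stop("phenotype is constant")
  eval_r2 <- function(idx) {
    s <- drop(counts[, idx, drop = FALSE] %*% w[idx])
    unname(r2_core(s, yc, syy)["r2"])
  }

  with_seed(rng_seed, {
    members <- lapply(seq_len(pop_size), function(i) {
      snp_subset(sample_weighted(m, k, kernel_weights))
    })
    fits <- vapply(members, function(s) eval_r2(s$indices), numeric(1))
    best_i <- which.max(fits)
    best_idx <- members[[best_i]]$indices; best_r2 <- fits[best_i]
    trace <- numeric(generations)

    for (g in seq_len(generations)) {
      ord <- order(fits, decreasing = TRUE)
      keep <- ord[seq_len(min(elitism, pop_size))]
      new_members <- members[keep]
      new_fits <- fits[keep]
      pop <- list(members = members, fitnesses = fits)
      while (length(new_members) < pop_size) {
        parents <- select_parents(pop)
        child <- mutate(crossover(parents[[1]], parents[[2]]),
                        mutation_rate, m)
        new_members[[length(new_members) + 1]] <- child
        new_fits <- c(new_fits, eval_r2(child$indices))
      }
      members <- new_members; fits <- new_fits
      gi <- which.max(fits)
      if (fits[gi] > best_r2) {
        best_r2 <- fits[gi]; best_idx <- members[[gi]]$indices
      }
      trace[g] <- max(fits)
    }

    incl <- numeric(m)
    for (s in members) incl[s$indices] <- incl[s$indices] + 1
    best_subset <- snp_subset(best_idx)
    best_fit <- fitness(aggregate_score(genotypes, best_subset, weights),
                        phenotype)
    structure(list(
      best_subset = best_subset, best_fitness = best_fit,
      inclusion_freq = incl / pop_size, fitness_trace = trace,
      k = k, pop_size = pop_size, generations = generations,
      mutation_rate = mutation_rate, elitism = elitism),
      class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf(
    "ga_result: pop %d, %d generations\n  best r2 = %.4f (k = %d)\n",
    x$pop_size, x$generations, x$best_fitness$r2, x$k))
  invisible(x)
}
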