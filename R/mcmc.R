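#' Association-weighted proposal kernel
#'
#' Per-variant proposal weights for the subset samplers: the marginal
#' trait association (squared Pearson correlation) of each variant, floored
#' by one hundredth of the largest marginal r-squared so that
#' zero-association variants remain reachable and the chain stays ergodic.
#' If every variant has zero association the kernel is uniform.
#'
#' @inheritParams marginal_association
#' @return non-negative numeric vector, one weight per variant.
#' @export
proposal_kernel <- function(genotypes, phenotype) {
  r2 <- marginal_association(genotypes, phenotype)
  mx <- max(r2)
  if (mx <= 0) rep(1, length(r2)) else r2 + mx / 100
}

# Temperature ladder T_j = 1 / (1 + delta * j), j = 0 .. n_chains - 1.
temperature_ladder <- function(n_chains, delta = 0.2) {
  1 / (1 + delta * (seq_len(n_chains) - 1))
}

# Build a chain state (subset + cached fitness/log-likelihood) at a given
# temperature.
chain_state <- function(subset, genotypes, weights, phenotype,
                        temperature = 1) {
  subset <- check_subset(subset, genotypes)
  fit <- fitness(aggregate_score(genotypes, subset, weights), phenotype)
  structure(list(subset = subset, fitness = fit,
                 log_lik = log_likelihood(fit),
                 temperature = temperature),
            class = "chain_state")
}

#' Initialize Metropolis-coupled chains
#'
#' Each chain's initial subset is \code{k} distinct variants sampled without
#' replacement with probability proportional to the proposal kernel weights.
#' Temperatures follow the ladder \eqn{T_j = 1/(1 + \delta j)} with
#' \eqn{\delta = 0.2} by default; chain 1 is the cold chain (T = 1).
#'
#' @param genotypes a [genotype_matrix()].
#' @param weights a \code{weight_scheme} (per-variant score weights).
#' @param phenotype numeric trait vector.
#' @param kernel_weights non-negative per-variant proposal weights, not all
#'   zero; defaults to [proposal_kernel()].
#' @param k subset size.
#' @param n_chains number of parallel tempered chains (default 5).
#' @param delta temperature-ladder spacing.
#' @param rng_seed optional integer seed.
#' @return list of \code{chain_state} objects.
#' @export
init_chains <- function(genotypes, weights, phenotype, kernel_weights = NULL,
                        k = 20, n_chains = 5, delta = 0.2, rng_seed = NULL) {
  m <- n_variants(genotypes)
  if (k > m) stop("k = ", k, " exceeds the number of variants (", m, ")")
  if (is.null(kernel_weights)) {
    kernel_weights <- proposal_kernel(genotypes, phenotype)
  }
  if (any(kernel_weights < 0) || all(kernel_weights == 0)) {
    stop("kernel_weights must be non-negative and not all zero")
  }
  temps <- temperature_ladder(n_chains, delta)
  with_seed(rng_seed, lapply(seq_len(n_chains), function(j) {
    idx <- sample_weighted(m, k, kernel_weights)
    chain_state(snp_subset(idx), genotypes, weights, phenotype, temps[j])
  }))
}

#' Propose a single-variant swap
#'
#' Removes one member of the subset uniformly at random and adds one
#' non-member sampled with probability proportional to its kernel weight.
#' The paired remove+add keeps the subset size fixed at \code{k}. Returns
#' the log Hastings correction \eqn{\log q(\mathrm{reverse}) -
#' \log q(\mathrm{forward})}, which is exactly 0 under a uniform kernel.
#'
#' @param state a \code{chain_state}.
#' @param kernel_weights per-variant proposal weights (already floored).
#' @return list with \code{candidate} (a [snp_subset()]),
#'   \code{log_hastings}, \code{removed}, \code{added}.
#' @export
propose_swap <- function(state, kernel_weights) {
  idx <- state$subset$indices
  k <- length(idx)
  m <- length(kernel_weights)
  removed <- idx[sample.int(k, 1)]
  mem <- logical(m); mem[idx] <- TRUE
  cand <- which(!mem)
  if (length(cand) == 0) stop("subset already contains every variant")
  wc <- kernel_weights[cand]
  total <- sum(wc)
  if (total <= 0) { wc <- rep(1, length(cand)); total <- length(cand) }
  added <- cand[sample.int(length(cand), 1, prob = wc)]
  total_rev <- total - kernel_weights[added] + kernel_weights[removed]
  log_h <- (log(kernel_weights[removed]) - log(total_rev)) -
    (log(kernel_weights[added]) - log(total))
  new_idx <- sort(c(idx[idx != removed], added))
  list(candidate = snp_subset(new_idx), log_hastings = log_h,
       removed = removed, added = added)
}

#' One Metropolis-Hastings step for a tempered chain
#'
#' Proposes a swap and accepts it with probability
#' \eqn{\min(1, \exp(T (\ell' - \ell) + \log H))}, where \eqn{T} is the
#' chain's temperature, \eqn{\ell} the profile log-likelihood of the current
#' subset, and \eqn{\log H} the Hastings correction.
#'
#' @param state a \code{chain_state}.
#' @inheritParams init_chains
#' @return the updated \code{chain_state} (with \code{accepted} attribute).
#' @export
mcmc_step <- function(state, genotypes, weights, phenotype, kernel_weights) {
  prop <- propose_swap(state, kernel_weights)
  fit <- fitness(aggregate_score(genotypes, prop$candidate, weights),
                 phenotype)
  ll_new <- log_likelihood(fit)
  log_alpha <- state$temperature * (ll_new - state$log_lik) +
    prop$log_hastings
  if (log(stats::runif(1)) < log_alpha) {
    state$subset <- prop$candidate
    state$fitness <- fit
    state$log_lik <- ll_new
    attr(state, "accepted") <- TRUE
  } else {
    attr(state, "accepted") <- FALSE
  }
  state
}

#' Attempt a state exchange between adjacent tempered chains
#'
#' Picks a uniformly random adjacent pair (j, j+1) and exchanges their
#' subsets with probability
#' \eqn{\min(1, \exp((T_j - T_{j+1})(\ell_{j+1} - \ell_j)))}. Temperatures
#' stay attached to chain positions. A single chain is a no-op.
#'
#' @param chains list of \code{chain_state}.
#' @return the (possibly exchanged) list, with attribute \code{swapped}.
#' @export
swap_move <- function(chains) {
  n <- length(chains)
  if (n < 2) { attr(chains, "swapped") <- FALSE; return(chains) }
  j <- sample.int(n - 1, 1)
  a <- chains[[j]]; b <- chains[[j + 1]]
  log_alpha <- (a$temperature - b$temperature) * (b$log_lik - a$log_lik)
  swapped <- log(stats::runif(1)) < log_alpha
  if (swapped) {
    for (f in c("subset", "fitness", "log_lik")) {
      tmp <- a[[f]]; a[[f]] <- b[[f]]; b[[f]] <- tmp
    }
    chains[[j]] <- a; chains[[j + 1]] <- b
  }
  attr(chains, "swapped") <- swapped
  chains
}

#' Metropolis-coupled MCMC search for the best variant subset
#'
#' Runs \code{n_chains} parallel tempered chains over the space of size-k
#' variant subsets, with one swap proposal per chain per iteration plus one
#' chain-exchange attempt per iteration. The cold chain (T = 1) targets the
#' Boltzmann distribution \eqn{\exp(\ell(S))/Z} of the profile
#' log-likelihood; its post-burn-in samples yield per-variant posterior
#' inclusion frequencies. The best subset ever visited by any chain is
#' recorded.
#'
#' @inheritParams init_chains
#' @param iterations total iterations (default 20000).
#' @param burn_in iterations discarded before accumulating inclusion
#'   frequencies (default 4000).
#' @param keep_samples if TRUE, also return the cold chain's post-burn-in
#'   subset samples as an (iterations - burn_in) x k matrix.
#' @return an object of class \code{"mcmc_result"}: \code{inclusion_freq}
#'   (per-variant, sums to k), \code{best_subset}, \code{best_fitness},
#'   \code{trace} (cold-chain log-likelihood per iteration),
#'   \code{acceptance_rates} (per chain, plus \code{swap}), and optionally
#'   \code{samples}.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_individuals = 60, n_variants = 15,
#'                                    n_replicates = 1, seed = 1))
#' w <- compute_weights(sim$genotypes, "LL")
#' res <- run_mc3(sim$genotypes, w, sim$phenotypes[[1]]$values, k = 3,
#'                iterations = 500, burn_in = 100, rng_seed = 1)
#' res$best_fitness
run_mc3 <- function(genotypes, weights, phenotype, k = 20, n_chains = 5,
                    iterations = 20000, burn_in = 4000,
                    kernel_weights = NULL, delta = 0.2, rng_seed = NULL,
                    keep_samples = FALSE) {
  if (!(iterations > burn_in && burn_in >= 0)) {
    stop("need iterations > burn_in >= 0")
  }
  counts <- counts_filled(genotypes$counts)
  m <- ncol(counts); n <- nrow(counts)
  if (k > m) stop("k = ", k, " exceeds the number of variants (", m, ")")
  w <- if (inherits(weights, "weight_scheme")) weights$weights else weights
  if (is.null(kernel_weights)) {
    kernel_weights <- proposal_kernel(genotypes, phenotype)
  }
  kw <- kernel_weights
  if (any(kw < 0) || all(kw == 0)) {
    stop("kernel_weights must be non-negative and not all zero")
  }
  yc <- phenotype - mean(phenotype)
  syy <- sum(yc^2)
  if (syy == 0) stop("phenotype is constant")
  temps <- temperature_ladder(n_chains, delta)

  with_seed(rng_seed, {
    # chain state kept in flat structures for speed
    idx_list <- lapply(seq_len(n_chains), function(j) {
      sample_weighted(m, k, kw)
    })
    mem <- matrix(FALSE, m, n_chains)
    scores <- matrix(0, n, n_chains)
    ll <- numeric(n_chains); r2s <- numeric(n_chains)
    for (j in seq_len(n_chains)) {
      mem[idx_list[[j]], j] <- TRUE
      scores[, j] <- drop(counts[, idx_list[[j]], drop = FALSE] %*%
                            w[idx_list[[j]]])
      v <- r2_core(scores[, j], yc, syy)
      r2s[j] <- v["r2"]
      ll[j] <- -(n / 2) * log1p(-min(r2s[j], 1 - 1e-12))
    }
    best_j <- which.max(r2s)
    best_r2 <- r2s[best_j]; best_idx <- idx_list[[best_j]]
    incl <- numeric(m)
    trace <- numeric(iterations)
    acc <- numeric(n_chains); swap_acc <- 0L
    n_keep <- iterations - burn_in
    samples <- if (keep_samples) matrix(0L, n_keep, k) else NULL

    for (it in seq_len(iterations)) {
      for (j in seq_len(n_chains)) {
        idx <- idx_list[[j]]
        rem <- idx[sample.int(k, 1)]
        cand <- which(!mem[, j])
        wc <- kw[cand]
        total <- sum(wc)
        add <- if (total > 0) {
          cand[sample.int(length(cand), 1, prob = wc)]
        } else cand[sample.int(length(cand), 1)]
        log_h <- if (total > 0) {
          (log(kw[rem]) - log(total - kw[add] + kw[rem])) -
            (log(kw[add]) - log(total))
        } else 0
        s_new <- scores[, j] - w[rem] * counts[, rem] +
          w[add] * counts[, add]
        v <- r2_core(s_new, yc, syy)
        ll_new <- -(n / 2) * log1p(-min(v["r2"], 1 - 1e-12))
        if (log(stats::runif(1)) < temps[j] * (ll_new - ll[j]) + log_h) {
          idx_list[[j]] <- sort(c(idx[idx != rem], add))
          mem[rem, j] <- FALSE; mem[add, j] <- TRUE
          scores[, j] <- s_new
          ll[j] <- ll_new; r2s[j] <- v["r2"]
          acc[j] <- acc[j] + 1
          if (r2s[j] > best_r2) {
            best_r2 <- r2s[j]; best_idx <- idx_list[[j]]
          }
        }
      }
      if (n_chains >= 2) {
        j <- sample.int(n_chains - 1, 1)
        if (log(stats::runif(1)) <
              (temps[j] - temps[j + 1]) * (ll[j + 1] - ll[j])) {
          tmp <- idx_list[[j]]; idx_list[[j]] <- idx_list[[j + 1]]
          idx_list[[j + 1]] <- tmp
          tmpv <- mem[, j]; mem[, j] <- mem[, j + 1]; mem[, j + 1] <- tmpv
          tmpv <- scores[, j]; scores[, j] <- scores[, j + 1]
          scores[, j + 1] <- tmpv
          tmp2 <- ll[j]; ll[j] <- ll[j + 1]; ll[j + 1] <- tmp2
          tmp2 <- r2s[j]; r2s[j] <- r2s[j + 1]; r2s[j + 1] <- tmp2
          swap_acc <- swap_acc + 1L
        }
      }
      trace[it] <- ll[1]
      if (it > burn_in) {
        incl[idx_list[[1]]] <- incl[idx_list[[1]]] + 1
        if (keep_samples) samples[it - burn_in, ] <- idx_list[[1]]
      }
    }

    best_subset <- snp_subset(best_idx)
    best_fit <- fitness(aggregate_score(genotypes, best_subset, weights),
                        phenotype)
    structure(list(
      inclusion_freq = incl / n_keep,
      best_subset = best_subset,
      best_fitness = best_fit,
      trace = trace,
      acceptance_rates = c(acc / iterations,
                           swap = if (n_chains >= 2)
                             swap_acc / iterations else NA_real_),
      samples = samples,
      k = k, n_chains = n_chains, iterations = iterations,
      burn_in = burn_in),
      class = "mcmc_result")
  })
}

#' @export
print.mcmc_result <- function(x, ...) {
  cat(sprintf(
    "mcmc_result: %d chains, %d iterations (burn-in %d)\n  best r2 = %.4f (k = %d); top inclusion freq = %.3f\n",
    x$n_chains, x$iterations, x$burn_in, x$best_fitness$r2, x$k,
    max(x$inclusion_freq)))
  invisible(x)
}
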