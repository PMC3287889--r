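---
title: "Subset-search burden tests: model, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subset-search burden tests: model, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvsearch)
```

## The problem

Burden (weighted-sum) statistics collapse the minor-allele counts of a set
of variants into one per-individual score and test that score for
association with a phenotype. They work well when the set is a small,
pre-specified unit — a gene — in which a reasonable fraction of variants is
trait-related. Over a region as large as a chromosome, almost all variants
are unrelated to the trait, the score is dominated by noise, and power
collapses. `rvsearch` makes the region choice agnostic by *searching* for
the subset of variants whose aggregated score best predicts the trait,
keeping the subset size fixed (default $k = 20$) to bound the model's
complexity, and paying for the search with a permutation test of the
optimized fit.

## Score statistics

For individual $I$ with allele counts $g_{Ii} \in \{0,1,2\}$ and a subset
$S$ of variants, the score is

$$\sigma_I(S) = \sum_{i \in S} w_i \, g_{Ii},$$

with three weight choices (`compute_weights()`):

* **LL** — $w_i = 1$: the plain count of minor alleles.
* **MB** — $w_i = 1/\mathrm{maf}_i$ with the minor-allele frequency
  computed in the sample, so rare alleles count for more. We implement the
  inverse-frequency weight literally; the classical inverse-variance form
  $1/\sqrt{n q (1-q)}$ is available as `mb_original = TRUE`. Variants that
  are monomorphic in sample get weight 0 (they can never contribute, and
  $1/0$ is avoided) with a warning.
* **ME** — $w_i = |\hat\beta_i|$, the absolute marginal effect of variant
  $i$: the univariate least-squares slope for a quantitative trait, or the
  carrier-vs-non-carrier log odds ratio (0.5 continuity correction on zero
  cells) for a binary one. The absolute value keeps all weights
  non-negative so the score remains a burden; `signed = TRUE` exposes the
  signed alternative. Marginal effects are estimated once per phenotype
  and held fixed during a search; under permutation they are re-estimated
  from each permuted phenotype, because the weights are part of the
  statistic and the null must re-derive them.

Missing genotypes contribute 0 to the score — the reference-homozygote
convention, the simplest conservative choice.

## Fitness and the likelihood approximation

Association between score and quantitative trait is measured by the square
of the sample Pearson correlation, $r^2$ (`fitness()`). A constant score
vector — easy to produce with $k$ rare variants in a small sample — is
assigned $r = 0$ rather than an error so the samplers remain ergodic.

The MCMC sampler needs a likelihood. Assuming a linear relationship
between score and mean trait with normal residuals, the profile
log-likelihood of the fitted simple regression is, up to an additive
constant that cancels in the Hastings ratio,

$$\ell(S) = -\tfrac{n}{2}\,\log\!\left(1 - r^2(S)\right),$$

implemented in `log_likelihood()` with $r^2$ clamped to $1 - 10^{-12}$.
Under the null, $2\ell \approx n r^2$ is approximately $\chi^2_1$, which
the test suite checks by simulation.

## The two optimizers

Both optimizers move through the space of size-$k$ subsets and share an
**association-weighted proposal kernel** (`proposal_kernel()`): per-variant
marginal $r^2$ with the trait, floored by $\max_i r^2_i / 100$ so that
zero-association variants remain reachable (without the floor the kernel
would trap the chain on the currently-associated variants). If all
marginal associations are zero the kernel is uniform.

**Metropolis-coupled MCMC** (`run_mc3()`). Five chains run in parallel at
temperatures $T_j = 1/(1 + 0.2 j)$, $j = 0,\dots,4$; the spacing 0.2 is a
mild ladder that keeps swap acceptance healthy at five chains. Each
iteration proposes, per chain, a paired remove-one/add-one swap — the only
size-preserving reading of "add or remove a SNP" when $|S| = k$ is fixed:
the removed member is uniform on $S$, the added one is kernel-weighted on
the complement, and the exact Hastings correction
$\log q(\text{reverse}) - \log q(\text{forward})$ is applied, so the cold
chain targets $\exp(\ell(S))/Z$ exactly (verified against full enumeration
on instances small enough to enumerate). Acceptance is
$\min\{1, \exp(T_j \Delta\ell + \log H)\}$. One uniformly chosen adjacent
pair attempts a state exchange per iteration with probability
$\min\{1, \exp((T_j - T_{j+1})(\ell_{j+1} - \ell_j))\}$; temperatures stay
attached to positions. Post burn-in cold-chain samples yield per-variant
posterior inclusion frequencies (summing to $k$), and the best subset ever
visited by *any* chain is recorded, since the hot chains legitimately
discover optima. Defaults — 20,000 iterations, 4,000 burn-in, one swap
attempt per iteration — are configuration choices sized so that the
enumerable-instance posterior checks pass; they are not claims about any
particular dataset.

**Genetic algorithm** (`run_ga()`). A population (default 100) of subsets
evolves for a default 200 generations: reproduction probability
proportional to $r^2$ (roulette selection), recombination that keeps all
variants shared by the two parents and fills the remainder uniformly from
their symmetric difference (the natural fixed-$k$ set crossover), and
per-member mutation to a uniform non-member at rate 0.05. One elite member
survives unchanged per generation, which makes the best-per-generation
trace non-decreasing — a testable invariant — and prevents losing the
optimum. The encoding, operators and parameters are our design; the
method's idea only requires fitness-proportional reproduction with
mutation and recombination over subset identity.

## Significance and diagnostics

`permutation_test()` reruns the *identical configured search* on the
observed phenotype and on each of $B$ (default 1,000) uniform permutations
of it, and reports

$$p = \frac{1 + \#\{b : \text{null}_b \ge \text{observed}\}}{1 + B} \in
\left[\tfrac{1}{1+B}, 1\right],$$

the add-one form that can never return 0. Exchangeability of observed and
null runs is what makes $p$ uniform under the null, so the search effort
must be the same on both sides; the `perm_effort` knob that shrinks null
search effort is a logged approximation and is off by default.
Permutation is applied to the PC-adjusted phenotype; the genotypes, and
hence the PCs, are fixed, so permuting the residual is equivalent under
the null and the PCA need not be recomputed per permutation.

`pc_adjust()` regresses the phenotype on an intercept and the leading
principal components (default 10) of the column-standardized genotype
matrix (sample-variance convention, $1/(n-1)$; monomorphic variants are
excluded from the PCA but stay in the search space; missing entries are
mean-filled for the PCA only). PCs are computed from all polymorphic
variants rather than common ones only — with mostly-rare data, restricting
to common variants can leave too few. The number of PCs is deliberately
not tuned per replicate.

`causal_enrichment()` pools, across replicates, all (variant, replicate)
pairs cross-classified by membership in that replicate's best subset and
by true causality, and applies the 1-df Pearson chi-square without
continuity correction (pooled counts are large; a `unique_snps` mode that
counts each variant once is exposed as an alternative reading).
`qq_data()` produces the usual $-\log_{10}$ expected/observed pairs with
$\mathrm{expected}_i = -\log_{10}(i/(m+1))$.

## The synthetic-data generator

No suitable benchmark genotype set is freely redistributable, so
`simulate_dataset()` generates one with the structure the method is
designed around, and every end-to-end claim in the test suite is made on
these synthetic conditions:

* **Scale** — 697 individuals (a realistic mini-exome cohort size) and 200
  variants per region (a small-chromosome count), split evenly over 2
  subpopulations.
* **Frequency spectrum** — ancestral MAFs from a truncated
  $\mathrm{Beta}(0.1, 10)$ on $[0.002, 0.5]$, putting roughly 80% of
  variants below MAF 0.05, echoing the rare-variant dominance of exome
  data.
* **Structure** — the Balding–Nichols model with $F_{st} = 0.10$
  (continental-scale divergence), the simplest standard model that
  produces genuine stratification confounding; an independent Hudson-style
  estimator confirms the realized divergence in tests. Coalescent or
  haplotype-level simulation (LD, recombination) is out of scope, so the
  generator cannot exhibit the proxy-selection behaviour that linkage
  disequilibrium produces in real data — passing tests say nothing about
  LD robustness.
* **Traits** — each replicate draws
  $y = \sum_c \beta_c g_c + s \cdot \mathrm{subpop} + N(0, 1)$ with fresh
  noise on the fixed genotypes, mirroring the replicate design of
  workshop-style benchmarks (default 200 replicates). Presets:
  `q1_like` (15 rare causal variants, ancestral MAF $\le 0.05$, effects
  0.5–1.1 giving a heritability near 0.35, mild structure), `q2_like`
  (8 weaker causal variants), and `q4_like` (no causal variants, trait
  shifted by 1.6 per subpopulation — about 40% of trait variance — a pure
  structured null on which an uncorrected analysis should, and does,
  grossly inflate).

## Numerical and reproducibility choices

* Constant-score detection uses an absolute variance tolerance of
  $10^{-12}$ (relative to the squared mean); ties in sampling are broken
  by R's `sample.int`.
* One master seed drives everything; named substreams
  (`derive_seed(seed, stream, index)`) make each component — simulation,
  each chain run, each permutation — independently reproducible, and all
  derived seeds stay below $2^{31}$.
* Identical configuration and seed give byte-identical pipeline output
  files.
* Subset indices are stored sorted, so subsets compare by membership.

## Problem sizes used in the checks

The enumerable-instance checks use 12 variants with $k=3$ (220 subsets)
for optimizer-vs-exhaustive-search equivalence and 8 variants with $k=2$
(28 subsets, 50,000 iterations) for posterior correctness. Calibration
and stratification checks run 60–100 trait replicates at $B$ = 100–200
permutations with a deliberately small search (2 chains, 50–60
iterations) applied identically to observed and permuted traits — the
calibration property depends on exchangeability, not on search effort.
Causal-recovery checks use 12–20 replicates at full five-chain effort.
These sizes are the package's own desk-scale choices; the method itself
is routinely run far longer via the configuration knobs.

## Limitations

* Fixed $k$ is a modelling convenience; nothing adapts the subset size.
* The likelihood approximation is specific to quantitative traits with
  roughly linear score–trait relationships; binary traits are supported
  only through the log-odds-ratio weight option, not as a search target.
* Searching a whole exome at once is not claimed to work — the region is
  a configuration choice, and chromosome-scale regions are the intended
  unit.
* Permutation tests rerun the full search $B$ times; that cost is
  intrinsic to the method, and the honest way to reduce it is to reduce
  the search effort on both sides, not only under the null.
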