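#' Monte-Carlo null confidence interval for delta(SNP-index)
#'
#' Under the no-QTL null every pooled individual carries the
#' tolerant-parent allele with probability 1/2 independently of phenotype,
#' so pool allele frequencies fluctuate only through the two-stage sampling
#' of (i) which homozygous lines enter each pool and (ii) which reads are
#' drawn from the pooled DNA. Each replicate draws, independently per pool,
#' a pool allele frequency `p = Binomial(pool_size, 1/2) / pool_size`, then
#' read counts `Binomial(depth, p)`, and records the resulting
#' delta(SNP-index). The interval is the pair of empirical
#' `(1 - confidence)/2` and `(1 + confidence)/2` quantiles.
#'
#' The interval tightens as pool size or sequencing depth grows: both
#' stages of sampling then estimate the latent frequency more precisely.
#'
#' @param pool_size individuals per pool (default 20, a typical
#'   extreme-pool design).
#' @param depth_T,depth_S mean read depth of the tolerant and sensitive
#'   pools.
#' @param confidence two-sided coverage of the interval (default 0.99).
#' @param n_sims Monte-Carlo replicates (default 10000); below 1000 the
#'   quantiles are noisy and a warning is raised.
#' @param seed integer seed; the result is deterministic given the seed.
#' @return list of class `"bsa_null_ci"` with elements `lower`, `upper`,
#'   `confidence`, `pool_size`, `depth_T`, `depth_S`, `n_sims`, `seed`,
#'   and `delta` (the simulated null draws, for coverage diagnostics).
#' @export
null_ci <- function(pool_size = 20L, depth_T, depth_S, confidence = 0.99,
                    n_sims = 10000L, seed = 1L) {
  if (pool_size < 1L) stop("pool_size must be >= 1")
  if (depth_T < 1L || depth_S < 1L) stop("pool depths must be >= 1")
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0, 1)")
  if (n_sims < 1000L) warning("n_sims < 1000 gives unstable quantiles")
  set.seed(seed)
  p_T <- rbinom(n_sims, pool_size, 0.5) / pool_size
  p_S <- rbinom(n_sims, pool_size, 0.5) / pool_size
  idx_T <- rbinom(n_sims, depth_T, p_T) / depth_T
  idx_S <- rbinom(n_sims, depth_S, p_S) / depth_S
  delta <- idx_T - idx_S
  alpha <- (1 - confidence) / 2
  bounds <- unname(quantile(delta, c(alpha, 1 - alpha)))
  structure(list(lower = bounds[1L], upper = bounds[2L],
                 confidence = confidence, pool_size = pool_size,
                 depth_T = depth_T, depth_S = depth_S,
                 n_sims = n_sims, seed = seed, delta = delta),
            class = "bsa_null_ci")
}

#' @export
print.bsa_null_ci <- function(x, ...) {
  cat(sprintf(
    "delta(SNP-index) null CI: [%.4f, %.4f] at %.1f%% (pools of %d, depths %g/%g, %d sims)\n",
    x$lower, x$upper, 100 * x$confidence, x$pool_size, x$depth_T, x$depth_S,
    x$n_sims))
  invisible(x)
}
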