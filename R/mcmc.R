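#' Gibbs update of the per-locus ancestry frequencies
#'
#' Draws each `q_x` from its conditional beta distribution, with shapes
#' formed by kernel-weighted sums of the latent ancestry counts over the
#' locus's neighbourhood: `Beta(alpha0 + sum_i z_i k(x,i), beta0 +
#' sum_i (2 n_i - z_i) k(x,i))`.
#'
#' @param zsum Integer vector of latent ancestry counts per locus
#'   (`0 .. 2n`).
#' @param n Admixed sample size per locus (scalar or vector).
#' @param cache A [kernel_cache()].
#' @param alpha0,beta0 Prior shapes.
#' @return Numeric vector of draws in `[0, 1]`.
#' @export
gibbs_update_q <- function(zsum, n, cache, alpha0 = 1, beta0 = 1) {
  n <- rep_len(n, length(zsum))
  sh <- kernel_shapes(zsum, n, cache, alpha0, beta0)
  rbeta(length(zsum), sh$alpha, sh$beta)
}

#' Gibbs update of individual latent ancestry at one locus
#'
#' Samples each individual's ancestry dosage from the categorical
#' distribution with mass proportional to
#' `Pr(s | z = g) * choose(2, g) * q^g * (1 - q)^(2 - g)` for
#' `g = 0, 1, 2`.
#'
#' @param lik Numeric `3 x n` matrix of ancestry-state likelihoods at the
#'   locus (rows are states 0, 1, 2).
#' @param q Ancestry frequency at the locus, in `[0, 1]`.
#' @return Integer vector of dosages in `{0, 1, 2}`.
#' @export
gibbs_update_z <- function(lik, q) {
  lik <- as.matrix(lik)
  if (nrow(lik) != 3) stop("`lik` must have 3 rows", call. = FALSE)
  if (q < 0 || q > 1) stop("`q` must lie in [0, 1]", call. = FALSE)
  prior <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  w <- lik * prior
  tot <- colSums(w)
  bad <- tot <= 0 | !is.finite(tot)
  if (any(bad)) { # total underflow: fall back to the binomial prior
    w[, bad] <- prior
    tot[bad] <- 1
  }
  u <- runif(ncol(lik)) * tot
  as.integer((u >= w[1, ]) + (u >= w[1, ] + w[2, ]))
}

#' Metropolis update of the kernel scale
#'
#' Proposes a new scale by a symmetric random walk on `log(sigma)` and
#' accepts with the ratio of beta likelihoods of the current ancestry
#' frequencies under the proposed versus current kernel-weighted shapes
#' (computed in log space). Proposals outside the uniform prior bounds are
#' rejected outright.
#'
#' @param q Current ancestry frequency vector.
#' @param zsum Latent ancestry counts per locus.
#' @param n Admixed sample size (scalar or per-locus vector).
#' @param sigma Current scale.
#' @param map A [locus_map()] (the kernel cache is rebuilt for the
#'   proposal).
#' @param config A [run_config()].
#' @return List with `sigma` (new value), `accepted` (logical) and
#'   `log_ratio`.
#' @export
metropolis_update_sigma <- function(q, zsum, n, sigma, map, config) {
  prop <- exp(log(sigma) + rnorm(1, 0, config$sigma_step))
  if (prop < config$sigma_min || prop > config$sigma_max) {
    return(list(sigma = sigma, accepted = FALSE, log_ratio = -Inf))
  }
  n <- rep_len(n, length(q))
  sh0 <- kernel_shapes(zsum, n, kernel_cache(map, sigma, config$eps),
    config$alpha0, config$beta0)
  sh1 <- kernel_shapes(zsum, n, kernel_cache(map, prop, config$eps),
    config$alpha0, config$beta0)
  lr <- sum(dbeta(q, sh1$alpha, sh1$beta, log = TRUE)) -
    sum(dbeta(q, sh0$alpha, sh0$beta, log = TRUE))
  acc <- log(runif(1)) < lr
  list(sigma = if (acc) prop else sigma, accepted = acc, log_ratio = lr)
}

#' Run the correlated beta process MCMC
#'
#' Runs one or more chains of the Gibbs sampler over latent individual
#' ancestry (`z`), population ancestry frequencies (`q`) and the kernel
#' scale (`sigma`). Each chain initialises `z` at the per-individual
#' maximum-likelihood state, `q` at the implied sample frequency, and
#' `sigma` at the geometric midpoint of its prior. Sweep order within an
#' iteration: all `z`, kernel rebuild if `sigma` changed, all `q`, then
#' `sigma`.
#'
#' @param lik A `3 x n_adm x L` likelihood array (see [likelihood_grid()]).
#' @param map A [locus_map()] with `L` rows.
#' @param config A [run_config()].
#' @param verbose Print per-chain progress.
#' @return An object of class `ancfreq_chains`: lists of per-chain thinned
#'   draw matrices `q` (L x kept), `zsum` (L x kept), `sigma` vectors,
#'   pooled per-individual mean dosage, and acceptance rates.
#' @export
run_mcmc <- function(lik, map, config = run_config(), verbose = FALSE) {
  stopifnot(length(dim(lik)) == 3, dim(lik)[1] == 3)
  L <- dim(lik)[3]
  nadm <- dim(lik)[2]
  if (nrow(map) != L) {
    stop("`map` must have one row per locus of the grid", call. = FALSE)
  }
  cb <- chrom_bounds(map)

  # ML initialisation from the grid
  flat <- matrix(lik, nrow = 3)
  zml <- matrix(max.col(t(flat), ties.method = "first") - 1L, nadm, L)
  z_init <- t(zml) # L x nadm
  q_init <- pmin(pmax(rowSums(z_init) / (2 * nadm), 1e-12), 1 - 1e-12)
  sigma_init <- sqrt(config$sigma_min * config$sigma_max)

  chains <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    if (verbose) message("chain ", ch, "/", config$chains)
    chains[[ch]] <- cpp_run_chain(
      as.numeric(lik), L, nadm, cb$start - 1L, cb$end - 1L,
      config$alpha0, config$beta0, config$sigma_min, config$sigma_max,
      config$sigma_step, config$iters, config$burnin, config$thin,
      config$eps, as.integer(t(z_init)), q_init, sigma_init
    )
    if (verbose) {
      message(
        "  sigma acceptance rate ",
        sprintf("%.2f", chains[[ch]]$accept_rate)
      )
    }
  }
  dosage <- Reduce(`+`, lapply(chains, `[[`, "dosage")) / config$chains
  structure(
    list(
      q = lapply(chains, `[[`, "q"),
      zsum = lapply(chains, `[[`, "zsum"),
      sigma = lapply(chains, function(x) as.numeric(x$sigma)),
      dosage = dosage,
      accept_rate = vapply(chains, `[[`, numeric(1), "accept_rate"),
      n_underflow = sum(vapply(chains, `[[`, numeric(1), "n_underflow")),
      n_adm = nadm, map = map, config = config
    ),
    class = "ancfreq_chains"
  )
}
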