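#' MCMC and model configuration
#'
#' Collects the tunable parameters of the discriminant step and the
#' correlated beta process sampler. Defaults follow the settings used for
#' the simulation study: two chains of 30,000 iterations with a 10,000
#' iteration burn-in and a thinning interval of 5, a uniform Beta(1, 1)
#' prior on ancestry frequencies, and a wide uniform prior on the kernel
#' scale.
#'
#' @param w Window half-width in SNPs: each focal SNP's window includes up
#'   to `w` neighbours on either side (same chromosome).
#' @param alpha0,beta0 Shape parameters of the beta prior on each locus's
#'   ancestry frequency.
#' @param sigma_min,sigma_max Bounds of the uniform prior on the
#'   squared-exponential kernel scale (squared marker-index units).
#' @param sigma_step Standard deviation of the log-scale random-walk
#'   proposal for the kernel scale.
#' @param chains Number of independent MCMC chains.
#' @param iters,burnin,thin Total iterations, burn-in iterations, and
#'   thinning interval per chain.
#' @param eps Kernel truncation tolerance: neighbours with weight below
#'   `eps` are dropped from the smoothing sums.
#' @param ridge Ridge scale for the within-group covariance: `ridge *
#'   mean(diag(Sw))` is added to the diagonal.
#' @param var_floor Variance floor scale for group score variances,
#'   relative to the pooled score variance.
#' @param lik_floor Lower floor on any evaluated ancestry likelihood.
#' @param n_het Number of synthetic inter-population heterozygote reference
#'   individuals; default `round((nA + nB) / 2)`.
#' @param seed Optional integer seed applied before estimation.
#'
#' @return A list of class `run_config`.
#' @export
run_config <- function(w = 10L, alpha0 = 1, beta0 = 1,
                       sigma_min = 0.01, sigma_max = 1000,
                       sigma_step = 0.3, chains = 2L,
                       iters = 30000L, burnin = 10000L, thin = 5L,
                       eps = 1e-6, ridge = 1e-6, var_floor = 1e-6,
                       lik_floor = 1e-300, n_het = NULL, seed = NULL) {
  w <- as.integer(w)
  if (is.na(w) || w < 1L) stop("`w` must be at least 1", call. = FALSE)
  if (alpha0 <= 0 || beta0 <= 0) {
    stop("prior shapes must be positive", call. = FALSE)
  }
  if (sigma_min <= 0 || sigma_min >= sigma_max) {
    stop("need 0 < sigma_min < sigma_max", call. = FALSE)
  }
  if (sigma_step <= 0) stop("`sigma_step` must be positive", call. = FALSE)
  chains <- as.integer(chains)
  iters <- as.integer(iters)
  burnin <- as.integer(burnin)
  thin <- as.integer(thin)
  if (chains < 1L) stop("need at least one chain", call. = FALSE)
  if (burnin >= iters) stop("`burnin` must be below `iters`", call. = FALSE)
  if (thin < 1L) stop("`thin` must be at least 1", call. = FALSE)
  if (eps <= 0 || eps >= 1) stop("`eps` must be in (0, 1)", call. = FALSE)
  if (ridge <= 0) stop("`ridge` must be positive", call. = FALSE)
  if (!is.null(n_het)) {
    n_het <- as.integer(n_het)
    if (n_het < 1L) stop("`n_het` must be at least 1", call. = FALSE)
  }
  structure(
    list(
      w = w, alpha0 = alpha0, beta0 = beta0, sigma_min = sigma_min,
      sigma_max = sigma_max, sigma_step = sigma_step, chains = chains,
      iters = iters, burnin = burnin, thin = thin, eps = eps, ridge = ridge,
      var_floor = var_floor, lik_floor = lik_floor, n_het = n_het,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat("  window half-width w =", x$w, "SNPs\n")
  cat("  prior Beta(", x$alpha0, ",", x$beta0, ")",
      "; sigma ~ U(", x$sigma_min, ",", x$sigma_max, ")\n")
  cat("  ", x$chains, " chain(s) x ", x$iters, " iterations (burn-in ",
      x$burnin, ", thin ", x$thin, ")\n", sep = "")
  invisible(x)
}
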