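#' Estimate local ancestry frequencies in an admixed population
#'
#' The full pipeline: per-locus SNP windows are built, synthetic
#' inter-population heterozygotes complete the three-group reference set,
#' a linear discriminant is fitted per window, the resulting ancestry-state
#' likelihoods feed the correlated beta process sampler, and the posterior
#' draws are summarised. The returned ancestry frequency `q` is the
#' frequency of gene copies inherited from the `sourceA` panel.
#'
#' @param geno A [genotype_matrix()] containing both source panels and the
#'   admixed panel.
#' @param w Window half-width in SNPs; overrides `config$w` when given.
#' @param config A [run_config()].
#' @param keep_draws Keep the raw thinned draw matrices in the fit (needed
#'   for [write_draws()]).
#' @param verbose Report per-stage progress.
#' @return An object of class `ancfreq_fit`. Use [tidy()] for the
#'   per-locus posterior summary tibble, [glance()] for a one-row run
#'   summary, and [autoplot()] to plot frequencies along the genome.
#' @examples
#' \donttest{
#' sim <- simulate_admixture(sim_preset("t20", n_markers = 300))
#' fit <- estimate_ancestry(sim$genotypes,
#'   w = 4,
#'   config = run_config(iters = 600, burnin = 200, chains = 2)
#' )
#' tidy(fit)
#' }
#' @export
estimate_ancestry <- function(geno, w = NULL, config = run_config(),
                              keep_draws = FALSE, verbose = FALSE) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (!is.null(w)) config$w <- as.integer(w)
  if (!is.null(config$seed)) set.seed(config$seed)
  t0 <- Sys.time()
  if (verbose) message("building reference set and likelihood grid")
  bl <- build_likelihoods(geno, config, verbose = verbose)
  if (verbose) message("running ", config$chains, " MCMC chain(s)")
  chains <- run_mcmc(bl$lik, geno$map, config, verbose = verbose)
  summ <- summarize_posterior(chains)
  structure(
    list(
      summary = summ, map = geno$map, config = config,
      n_het = bl$n_het, n_ref = bl$n_ref, n_adm = bl$nadm,
      n_floored = bl$n_floored,
      draws = if (keep_draws) chains else NULL,
      elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ),
    class = "ancfreq_fit"
  )
}

#' @export
print.ancfreq_fit <- function(x, ...) {
  cat(
    "<ancfreq_fit> ", nrow(x$map), " loci, ", x$n_adm,
    " admixed individuals, ", x$n_ref, " reference individuals (",
    x$n_het, " synthetic heterozygotes)\n",
    sep = ""
  )
  cat(
    "  window half-width ", x$config$w, " SNPs; ", x$config$chains,
    " chain(s) x ", x$config$iters, " iterations\n",
    sep = ""
  )
  cat(
    "  mean q = ", sprintf("%.3f", mean(x$summary$loci$q_mean)),
    "; sigma posterior mean = ", sprintf("%.2f", mean(x$summary$sigma)),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy per-locus posterior summary
#'
#' @param x An `ancfreq_fit`.
#' @param ... Unused.
#' @return A tibble with one row per locus: `chrom`, `pos`, posterior
#'   `q_mean`, `q_median`, the 95% ETPI (`q_low`, `q_high`) and, when
#'   computed, the beta-binomial interval (`bb_low`, `bb_high`).
#' @method tidy ancfreq_fit
#' @export
tidy.ancfreq_fit <- function(x, ...) {
  x$summary$loci
}

#' One-row summary of an ancestry-frequency fit
#'
#' @param x An `ancfreq_fit`.
#' @param ... Unused.
#' @return A one-row tibble with run dimensions, the posterior mean kernel
#'   scale, worst-case convergence diagnostics and the Metropolis
#'   acceptance rate.
#' @method glance ancfreq_fit
#' @export
glance.ancfreq_fit <- function(x, ...) {
  d <- x$summary$diagnostics
  tibble::tibble(
    n_loci = nrow(x$map),
    n_adm = x$n_adm,
    n_ref = x$n_ref,
    w = x$config$w,
    chains = x$config$chains,
    iters = x$config$iters,
    mean_q = mean(x$summary$loci$q_mean),
    sigma_mean = mean(x$summary$sigma),
    max_psrf_q = suppressWarnings(max(d$q$psrf)),
    min_ess_q = min(d$q$ess),
    sigma_psrf = d$sigma$psrf,
    accept_rate = mean(x$summary$accept_rate),
    elapsed_s = x$elapsed
  )
}

#' Plot ancestry frequencies along the genome
#'
#' Posterior mean with the 95% ETPI ribbon, faceted by chromosome.
#'
#' @param object An `ancfreq_fit`.
#' @param truth Optional numeric vector of true per-locus frequencies to
#'   overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ancfreq_fit
#' @export
autoplot.ancfreq_fit <- function(object, truth = NULL, ...) {
  d <- tidy(object)
  if (!is.null(truth)) d$q_true <- truth
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pos)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$q_low, ymax = .data$q_high),
      fill = "tan", alpha = 0.6
    ) +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$q_mean),
      colour = "darkorange3"
    ) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(
      x = "position (bp)",
      y = "source A ancestry frequency"
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_line(
      ggplot2::aes(y = .data$q_true),
      colour = "grey30", linetype = 2
    )
  }
  p
}
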