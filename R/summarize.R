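#' Summarise posterior draws
#'
#' Pools the retained draws from all chains and computes, per locus, the
#' posterior mean, median and 95% equal-tail probability interval (ETPI)
#' of the ancestry frequency, plus a beta-binomial 95% ETPI built by
#' drawing, for every retained latent ancestry count `z_x`, one value from
#' `Beta(z_x + alpha0, 2 n - z_x + beta0)`. The kernel-smoothed posterior
#' shares information across loci and can understate uncertainty; the
#' beta-binomial interval ignores the smoothing and is the wider, more
#' conservative choice.
#'
#' @param chains An `ancfreq_chains` object from [run_mcmc()].
#' @param bb_intervals Compute the beta-binomial fallback interval?
#' @return An object of class `ancfreq_summary`: list with `loci` (a tibble
#'   of per-locus summaries), `dosage` (loci x individuals posterior mean
#'   ancestry dosage), `sigma` (pooled draws), and `diagnostics` (per-locus
#'   PSRF/ESS for `q`, and for `sigma`).
#' @export
summarize_posterior <- function(chains, bb_intervals = TRUE) {
  stopifnot(inherits(chains, "ancfreq_chains"))
  qs <- chains$q
  if (length(qs) < 1 || ncol(qs[[1]]) < 2) {
    stop("need at least one chain with at least two retained draws",
      call. = FALSE
    )
  }
  cfg <- chains$config
  pooled <- do.call(cbind, qs)
  L <- nrow(pooled)
  qq <- row_quantiles(pooled, c(0.025, 0.5, 0.975))
  loci <- tibble::tibble(
    chrom = chains$map$chrom,
    pos = chains$map$pos,
    q_mean = rowMeans(pooled),
    q_median = qq[, 2],
    q_low = qq[, 1],
    q_high = qq[, 3]
  )
  if (bb_intervals) {
    n2 <- 2 * chains$n_adm
    bb <- lapply(chains$zsum, function(zs) {
      matrix(
        rbeta(length(zs), zs + cfg$alpha0, n2 - zs + cfg$beta0),
        nrow = nrow(zs)
      )
    })
    bbq <- row_quantiles(do.call(cbind, bb), c(0.025, 0.975))
    loci$bb_low <- bbq[, 1]
    loci$bb_high <- bbq[, 2]
  }

  ess_q <- Reduce(`+`, lapply(qs, ess_matrix))
  diag <- list(
    q = tibble::tibble(
      chrom = chains$map$chrom, pos = chains$map$pos,
      psrf = if (length(qs) >= 2) psrf_matrix(qs) else NA_real_,
      ess = ess_q
    ),
    sigma = tibble::tibble(
      psrf = if (length(qs) >= 2) {
        psrf(do.call(cbind, chains$sigma))
      } else {
        NA_real_
      },
      ess = sum(vapply(chains$sigma, ess, numeric(1)))
    )
  )
  structure(
    list(
      loci = loci, dosage = chains$dosage,
      sigma = unlist(chains$sigma), diagnostics = diag,
      accept_rate = chains$accept_rate, n_adm = chains$n_adm,
      config = cfg
    ),
    class = "ancfreq_summary"
  )
}

# row-wise quantiles (type 7) of a numeric matrix, returned as a matrix
# with one column per probability
row_quantiles <- function(m, probs) {
  n <- ncol(m)
  sorted <- matrix(m[order(row(m), m)], nrow(m), n, byrow = TRUE)
  h <- (n - 1) * probs + 1
  lo <- floor(h)
  hi <- ceiling(h)
  out <- sapply(seq_along(probs), function(j) {
    sorted[, lo[j]] + (h[j] - lo[j]) * (sorted[, hi[j]] - sorted[, lo[j]])
  })
  matrix(out, nrow(m), length(probs))
}
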