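#' Accuracy metrics for ancestry-frequency estimates
#'
#' Compares per-locus estimates against the simulated truth:
#' root-mean-square deviation, the coefficient of variation of the error
#' (mean over loci of `|q_hat - q| / q`, excluding loci with zero truth),
#' the Pearson correlation, and the fraction of loci whose true frequency
#' falls inside the supplied 95% interval.
#'
#' @param q_est,q_true Equal-length numeric vectors.
#' @param lower,upper Optional interval bounds per locus; coverage is `NA`
#'   when omitted.
#' @return A one-row tibble: `rmsd`, `cvrmsd`, `pearson_r`, `coverage`,
#'   `n_zero_truth` (loci excluded from the CV mean) and `r_defined`
#'   (FALSE when either vector is constant, in which case `pearson_r` is
#'   reported as 0).
#' @examples
#' accuracy_metrics(c(0.2, 0.4), c(0.4, 0.2))
#' @export
accuracy_metrics <- function(q_est, q_true, lower = NULL, upper = NULL) {
  if (length(q_est) != length(q_true)) {
    stop("`q_est` and `q_true` must have equal length", call. = FALSE)
  }
  err <- q_est - q_true
  rmsd <- sqrt(mean(err^2))
  nz <- q_true > 0
  cvrmsd <- mean(abs(err[nz]) / q_true[nz])
  r_defined <- sd(q_est) > 0 && sd(q_true) > 0
  r <- if (r_defined) cor(q_est, q_true) else 0
  coverage <- NA_real_
  if (!is.null(lower) && !is.null(upper)) {
    if (any(lower > upper)) {
      stop("interval bounds must be ordered", call. = FALSE)
    }
    coverage <- mean(q_true >= lower & q_true <= upper)
  }
  tibble::tibble(
    rmsd = rmsd, cvrmsd = cvrmsd, pearson_r = r, coverage = coverage,
    n_zero_truth = sum(!nz), r_defined = r_defined
  )
}

#' Genome-average null model
#'
#' The no-variation baseline: every locus is assigned the genome-average
#' ancestry frequency (the mean of the per-locus estimates).
#'
#' @param q Numeric vector of per-locus frequencies.
#' @return A constant vector of the same length.
#' @examples
#' null_model(c(0.2, 0.4, 0.6))
#' @export
null_model <- function(q) {
  if (length(q) == 0) stop("`q` must be non-empty", call. = FALSE)
  rep(mean(q), length(q))
}

#' Expected ancestry-block size from the breakpoint-density heuristic
#'
#' Assuming 1-Morgan chromosomes, a Poisson recombination process and that
#' half of all recombination events create ancestry breakpoints, the
#' breakpoint density for a pair of homologous chromosomes is `t` per
#' Morgan and blocks contain on average `L_snp / t` SNPs. Window
#' half-widths should stay below this. The heuristic slightly
#' underestimates realised block sizes, so it is conservative.
#'
#' @param l_snp Markers per chromosome.
#' @param t Generations since admixture.
#' @return Expected SNPs per ancestry block (`l_snp` when `t = 0`).
#' @examples
#' expected_block_size(10001, 20) # ~500
#' @export
expected_block_size <- function(l_snp, t) {
  if (t < 0) stop("`t` must be non-negative", call. = FALSE)
  if (t == 0) return(l_snp)
  l_snp / t
}

#' Contiguous regions of excess ancestry
#'
#' Flags loci whose estimated frequency lies strictly below the lower or
#' strictly above the upper empirical quantile of `q`, and merges runs of
#' consecutive flagged loci (same chromosome, same direction) into
#' regions.
#'
#' @param est A tibble with columns `chrom`, `pos` and `q` (for example
#'   `tidy(fit)` with `q_mean` renamed), in map order.
#' @param lower,upper Quantile probabilities, `0 < lower < upper < 1`.
#' @return A tibble with one row per region: `chrom`, `start`, `end`
#'   (positions), `n_snps` and `direction` (`"low"` or `"high"`).
#' @export
excess_regions <- function(est, lower = 0.0005, upper = 0.9995) {
  stopifnot(all(c("chrom", "pos", "q") %in% names(est)))
  if (!(lower > 0 && lower < upper && upper < 1)) {
    stop("need 0 < lower < upper < 1", call. = FALSE)
  }
  qlo <- quantile(est$q, lower, names = FALSE)
  qhi <- quantile(est$q, upper, names = FALSE)
  dir <- ifelse(est$q < qlo, "low", ifelse(est$q > qhi, "high", NA))
  flag <- !is.na(dir)
  if (!any(flag)) {
    return(tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      n_snps = integer(), direction = character()
    ))
  }
  grp <- cumsum(
    c(TRUE, flag[-1] != flag[-length(flag)] |
      est$chrom[-1] != est$chrom[-nrow(est)] |
      (flag[-1] & flag[-length(flag)] &
        !is.na(dir[-1]) & !is.na(dir[-length(dir)]) &
        dir[-1] != dir[-length(dir)]))
  )
  keep <- split(seq_len(nrow(est)), grp)
  out <- lapply(keep, function(i) {
    if (!flag[i[1]]) return(NULL)
    tibble::tibble(
      chrom = est$chrom[i[1]],
      start = est$pos[i[1]],
      end = est$pos[i[length(i)]],
      n_snps = length(i),
      direction = dir[i[1]]
    )
  })
  dplyr::bind_rows(out)
}

#' Run a replicated simulation-estimation accuracy experiment
#'
#' Simulates replicate admixed data sets under a named preset, runs the
#' full discriminant + correlated beta process pipeline on each, and
#' returns per-replicate accuracy metrics for the method, its
#' beta-binomial interval variant, and the genome-average null model.
#'
#' @param preset Preset name for [sim_preset()].
#' @param w Window half-width in SNPs.
#' @param n_reps Number of replicate data sets.
#' @param n_markers Markers per chromosome for the simulation.
#' @param config A [run_config()] for the sampler.
#' @param verbose Print per-replicate progress.
#' @return A tibble with one row per replicate: Pearson `r`, `rmsd`,
#'   `cvrmsd`, ETPI `coverage`, `bb_coverage`, the null model's `null_r`
#'   and `null_cvrmsd`, the posterior mean kernel scale and timing.
#' @export
run_accuracy_experiment <- function(preset, w, n_reps = 3, n_markers = 2000,
                                    config = run_config(
                                      iters = 6000, burnin = 2000,
                                      thin = 5, chains = 2
                                    ),
                                    verbose = FALSE) {
  rows <- lapply(seq_len(n_reps), function(rep) {
    sim <- simulate_admixture(sim_preset(preset, n_markers = n_markers))
    fit <- estimate_ancestry(sim$genotypes, w = w, config = config)
    td <- tidy(fit)
    m <- accuracy_metrics(td$q_mean, sim$truth$q_true, td$q_low, td$q_high)
    mb <- accuracy_metrics(td$q_mean, sim$truth$q_true, td$bb_low, td$bb_high)
    nul <- accuracy_metrics(null_model(td$q_mean), sim$truth$q_true)
    if (verbose) {
      message(
        preset, " w=", w, " rep ", rep, ": r=", sprintf("%.3f", m$pearson_r),
        " cvrmsd=", sprintf("%.3f", m$cvrmsd),
        " cov=", sprintf("%.3f", m$coverage)
      )
    }
    tibble::tibble(
      preset = preset, w = w, rep = rep,
      r = m$pearson_r, rmsd = m$rmsd, cvrmsd = m$cvrmsd,
      coverage = m$coverage, bb_coverage = mb$coverage,
      null_r = nul$pearson_r, null_cvrmsd = nul$cvrmsd,
      sigma_mean = mean(fit$summary$sigma),
      elapsed_s = fit$elapsed
    )
  })
  dplyr::bind_rows(rows)
}
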