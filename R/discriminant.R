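#' Simulate inter-population heterozygote reference individuals
#'
#' The discriminant step needs reference samples for all three ancestry
#' dosage states. The source panels provide the two homozygous states
#' (2 copies from A, 0 copies from A); individuals with exactly one gene
#' copy from each source are simulated by drawing, at every locus, one
#' allele from a randomly chosen source-A individual (Bernoulli with
#' probability `g/2` for genotype `g`) and one allele from a randomly
#' chosen source-B individual.
#'
#' @param refA,refB Numeric matrices of source-panel genotypes (loci x
#'   individuals, allele counts in `[0, 2]`, no missing values).
#' @param n_het Number of synthetic heterozygote individuals (`>= 1`).
#' @return A loci x `n_het` matrix of allele counts in `[0, 2]`.
#' @export
simulate_het_references <- function(refA, refB, n_het) {
  refA <- as.matrix(refA)
  refB <- as.matrix(refB)
  if (ncol(refA) == 0 || ncol(refB) == 0) {
    stop("both source panels must be non-empty", call. = FALSE)
  }
  if (nrow(refA) != nrow(refB)) {
    stop("source panels must cover the same loci", call. = FALSE)
  }
  n_het <- as.integer(n_het)
  if (is.na(n_het) || n_het < 1L) {
    stop("`n_het` must be at least 1", call. = FALSE)
  }
  L <- nrow(refA)
  out <- matrix(0, L, n_het)
  for (k in seq_len(n_het)) {
    ja <- sample.int(ncol(refA), L, replace = TRUE)
    jb <- sample.int(ncol(refB), L, replace = TRUE)
    ga <- refA[cbind(seq_len(L), ja)]
    gb <- refB[cbind(seq_len(L), jb)]
    out[, k] <- rbinom(L, 1L, ga / 2) + rbinom(L, 1L, gb / 2)
  }
  out
}

#' Fit the three-group discriminant function for one SNP window
#'
#' Columns are centred by the grand mean; the pooled within-group
#' covariance uses the group-centred cross-products divided by the total
#' reference count minus three, with a small ridge added to the diagonal.
#' The between-group scatter is the average outer product of the group mean
#' deviations. The discriminant coefficients are the leading eigenvector of
#' the canonical matrix (within-covariance inverse times between-scatter),
#' sign-fixed so that the mean score of the 2-copy group exceeds that of
#' the 0-copy group. Group score variances are floored at a small fraction
#' of the pooled score variance so that monomorphic windows still yield
#' finite likelihoods.
#'
#' @param x Numeric matrix of reference genotypes for the window,
#'   individuals x SNPs.
#' @param groups Integer vector of ancestry dosages (0, 1 or 2), one per
#'   row of `x`.
#' @param ridge Ridge scale relative to the mean diagonal of the
#'   within-group covariance.
#' @param var_floor Variance floor scale relative to the pooled score
#'   variance.
#' @return An object of class `discriminant_model`: list with `coef`
#'   (unit-norm coefficient vector), `offset` (grand mean used for
#'   centring), `means` and `vars` (score moments for dosage groups 0, 1,
#'   2) and `n_floored`.
#' @export
fit_discriminant <- function(x, groups, ridge = 1e-6, var_floor = 1e-6) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  groups <- as.integer(groups)
  if (length(groups) != nrow(x)) {
    stop("`groups` must label every row of `x`", call. = FALSE)
  }
  if (!all(groups %in% 0:2)) {
    stop("`groups` must contain only 0, 1, 2", call. = FALSE)
  }
  if (any(tabulate(groups + 1L, 3L) < 2L)) {
    stop("each reference group needs at least 2 members", call. = FALSE)
  }
  if (ncol(x) >= nrow(x)) {
    stop(
      "window of ", ncol(x), " SNPs needs more than ", nrow(x),
      " reference individuals",
      call. = FALSE
    )
  }
  if (anyNA(x)) stop("reference genotypes must be complete", call. = FALSE)
  f <- cpp_fit_da_window(x, groups, ridge, var_floor)
  structure(
    list(
      coef = as.numeric(f$coef), offset = as.numeric(f$offset),
      means = as.numeric(f$means), vars = as.numeric(f$vars),
      n_floored = f$n_floored
    ),
    class = "discriminant_model"
  )
}

#' Discriminant scores for a genotype block
#'
#' Projects individuals onto the discriminant axis of a fitted window
#' model: `d = coef . (g - offset)`.
#'
#' @param model A [fit_discriminant()] object.
#' @param x Numeric matrix, individuals x SNPs, with the model's window
#'   loci as columns.
#' @return Numeric vector of scores, one per row of `x`.
#' @export
score_individuals <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(model$coef)) {
    stop(
      "block has ", ncol(x), " loci but the model window has ",
      length(model$coef),
      call. = FALSE
    )
  }
  drop(sweep(x, 2, model$offset) %*% model$coef)
}

#' Ancestry-state likelihoods from discriminant scores
#'
#' Evaluates, for every locus and admixed individual, the likelihood of the
#' observed window genotypes under each ancestry dosage state: a normal
#' density of the individual's discriminant score at the reference group's
#' score mean and variance. Values are floored to avoid exact zeros.
#'
#' @param models List of [fit_discriminant()] objects, one per locus.
#' @param windows Window tibble from [build_windows()] aligned with
#'   `models`.
#' @param gadm Numeric matrix of admixed genotypes, loci x individuals.
#' @param lik_floor Lower floor applied to each density.
#' @return A list with `lik`, a `3 x n_individuals x n_loci` array of
#'   unnormalised likelihoods (states 0, 1, 2), and `scores`, the loci x
#'   individuals score matrix.
#' @export
likelihood_grid <- function(models, windows, gadm, lik_floor = 1e-300) {
  gadm <- as.matrix(gadm)
  L <- length(models)
  if (nrow(windows) != L) {
    stop("`windows` must have one row per model", call. = FALSE)
  }
  nadm <- ncol(gadm)
  lik <- array(NA_real_, c(3, nadm, L))
  scores <- matrix(NA_real_, L, nadm)
  for (x in seq_len(L)) {
    m <- models[[x]]
    d <- score_individuals(m, t(gadm[windows$start[x]:windows$end[x], ,
      drop = FALSE
    ]))
    if (any(!is.finite(d))) {
      stop(
        "non-finite discriminant score at locus ", x, ", individual ",
        which(!is.finite(d))[1],
        call. = FALSE
      )
    }
    scores[x, ] <- d
    for (g in 1:3) {
      f <- dnorm(d, m$means[g], sqrt(m$vars[g]))
      lik[g, , x] <- pmax(f, lik_floor)
    }
  }
  list(lik = lik, scores = scores)
}

# Build the full reference set and likelihood grid for an estimation run.
# Returns the 3 x n_adm x L likelihood array (C++ fast path), the scores,
# per-locus models when keep_models, and bookkeeping counts.
build_likelihoods <- function(geno, config, keep_models = FALSE,
                              verbose = FALSE) {
  geno <- impute_missing(geno, verbose = verbose)
  panels <- panel_split(geno)
  nA <- ncol(panels$sourceA)
  nB <- ncol(panels$sourceB)
  nadm <- ncol(panels$admixed)
  if (nA == 0 || nB == 0 || nadm == 0) {
    stop("all three panels must be non-empty", call. = FALSE)
  }
  n_het <- config$n_het %||% max(1L, as.integer(round((nA + nB) / 2)))
  het <- simulate_het_references(panels$sourceA, panels$sourceB, n_het)
  gref <- cbind(panels$sourceB, het, panels$sourceA)
  grp <- c(rep(0L, nB), rep(1L, n_het), rep(2L, nA))
  windows <- build_windows(geno$map, config$w, n_ref = length(grp))
  fit <- cpp_fit_da_all(
    gref, grp, cbind(windows$start - 1L, windows$end - 1L),
    panels$admixed, config$ridge, config$var_floor, config$lik_floor,
    keep_models
  )
  if (verbose && fit$n_floored > 0) {
    message(fit$n_floored, " group score variance(s) clamped to the floor")
  }
  list(
    lik = fit$lik, scores = fit$scores,
    models = if (keep_models) fit$models else NULL,
    windows = windows, n_het = n_het, n_ref = length(grp), nadm = nadm,
    n_floored = fit$n_floored
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
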