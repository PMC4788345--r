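#' Gelman-Rubin potential scale reduction factor
#'
#' The classic (split-free) between/within chain variance ratio:
#' `sqrt(((n - 1)/n * W + B/n) / W)` for chains of length `n`. Chains with
#' zero total variance are reported as exactly 1.
#'
#' @param draws A numeric matrix with one column per chain (iterations x
#'   chains), or a list of equal-length numeric vectors.
#' @return A scalar PSRF (`>= 1` up to floating point).
#' @export
psrf <- function(draws) {
  if (is.list(draws)) draws <- do.call(cbind, draws)
  draws <- as.matrix(draws)
  if (ncol(draws) < 2) stop("PSRF needs at least two chains", call. = FALSE)
  n <- nrow(draws)
  if (n < 2) stop("chains must have at least two draws", call. = FALSE)
  mu <- colMeans(draws)
  W <- mean(apply(draws, 2, var))
  B_over_n <- var(mu)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

# vectorised PSRF across many parameters: draws is a list of L x n matrices
psrf_matrix <- function(chain_mats) {
  n <- ncol(chain_mats[[1]])
  mus <- vapply(chain_mats, rowMeans, numeric(nrow(chain_mats[[1]])))
  vars <- vapply(
    chain_mats,
    function(m) rowSums((m - rowMeans(m))^2) / (n - 1),
    numeric(nrow(chain_mats[[1]]))
  )
  W <- rowMeans(vars)
  B_over_n <- apply(mus, 1, var)
  out <- sqrt(((n - 1) / n * W + B_over_n) / W)
  out[W <= 0] <- 1
  out
}

#' Effective sample size of one chain
#'
#' Uses the initial-positive-sequence estimator: autocovariances are summed
#' in consecutive pairs until a pair sum turns negative, and the effective
#' size is the chain length divided by the resulting integrated
#' autocorrelation time.
#'
#' @param x Numeric vector of draws from one chain.
#' @return A scalar effective sample size in `(0, length(x)]`.
#' @export
ess <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) stop("need at least two draws", call. = FALSE)
  v <- var(x)
  if (v <= 0) return(n)
  drop(ess_matrix(matrix(x, nrow = 1)))
}

# Initial-positive-sequence ESS for each row of an L x n draw matrix,
# with autocovariances computed through the FFT.
ess_matrix <- function(draws) {
  draws <- as.matrix(draws)
  n <- ncol(draws)
  L <- nrow(draws)
  centred <- draws - rowMeans(draws)
  npad <- nextn(2L * n)
  padded <- cbind(centred, matrix(0, L, npad - n))
  f <- t(mvfft(t(padded)))
  ac <- Re(t(mvfft(t(f * Conj(f)), inverse = TRUE))) / npad / n
  gamma0 <- ac[, 1]
  out <- numeric(L)
  for (r in seq_len(L)) {
    if (gamma0[r] <= 0) {
      out[r] <- n
      next
    }
    rho <- ac[r, seq_len(n)] / gamma0[r]
    tau <- -1 # pairs include lag 0; total = 2 * sum(pairs) - 1
    k <- 1L
    while (k + 1L <= n) {
      pair <- rho[k] + rho[k + 1L]
      if (pair <= 0) break
      tau <- tau + 2 * pair
      k <- k + 2L
    }
    out[r] <- min(n, n / max(tau, 1e-12))
  }
  out
}
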