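#' Squared-exponential kernel weight between two loci
#'
#' `k(x, i) = exp(-(x - i)^2 / sigma)` with distance measured in marker
#' index units. Loci on different chromosomes share no information: their
#' weight is 0.
#'
#' @param x,i Marker indices (any numeric; vectors recycle).
#' @param sigma Kernel scale in squared marker-index units (`> 0`).
#' @param chrom_x,chrom_i Optional chromosome identifiers; when supplied
#'   and unequal the weight is 0.
#' @return Numeric vector of weights in `[0, 1]`.
#' @examples
#' kernel_weight(5, 3, sigma = 4) # exp(-1)
#' @export
kernel_weight <- function(x, i, sigma, chrom_x = NULL, chrom_i = NULL) {
  if (any(sigma <= 0)) stop("`sigma` must be positive", call. = FALSE)
  w <- exp(-(x - i)^2 / sigma)
  if (!is.null(chrom_x) && !is.null(chrom_i)) {
    w[chrom_x != chrom_i] <- 0
  }
  w
}

#' Truncated kernel neighbourhoods for every locus
#'
#' Lists, for each locus, the same-chromosome neighbours whose kernel
#' weight is at least `eps`, together with the weights. The cache is
#' symmetric (locus `i` appears in `x`'s list iff `x` appears in `i`'s) and
#' always contains the locus itself with weight 1.
#'
#' @param map A [locus_map()].
#' @param sigma Kernel scale (`> 0`).
#' @param eps Truncation tolerance in `(0, 1)`.
#' @return A list with one element per locus, each a list with integer
#'   `idx` (1-based locus numbers) and numeric `w`.
#' @export
kernel_cache <- function(map, sigma, eps = 1e-6) {
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  h <- floor(sqrt(max(0, sigma * log(1 / eps))))
  cb <- chrom_bounds(map)
  out <- vector("list", nrow(map))
  for (r in seq_len(nrow(cb))) {
    for (x in cb$start[r]:cb$end[r]) {
      lo <- max(cb$start[r], x - h)
      hi <- min(cb$end[r], x + h)
      idx <- lo:hi
      out[[x]] <- list(idx = idx, w = exp(-(idx - x)^2 / sigma))
    }
  }
  out
}

# kernel-weighted ancestry count and total mass for each locus, given the
# per-locus latent counts zsum and per-locus sample sizes n (2n trials)
kernel_shapes <- function(zsum, n, cache, alpha0, beta0) {
  L <- length(zsum)
  alpha <- beta <- numeric(L)
  for (x in seq_len(L)) {
    idx <- cache[[x]]$idx
    w <- cache[[x]]$w
    a <- sum(zsum[idx] * w)
    tot <- sum(2 * n[idx] * w)
    alpha[x] <- alpha0 + a
    beta[x] <- beta0 + tot - a
  }
  if (any(!is.finite(alpha)) || any(!is.finite(beta))) {
    stop("non-finite beta shape in the ancestry-frequency update",
      call. = FALSE
    )
  }
  list(alpha = alpha, beta = beta)
}
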