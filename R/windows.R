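#' Define per-locus SNP windows
#'
#' Every marker gets a window of up to `w` neighbouring SNPs on either side
#' of the focal SNP. Windows never span chromosome boundaries; windows at
#' chromosome ends are truncated, not shifted, so the focal SNP keeps its
#' place and each locus maps to exactly one window. Because the discriminant
#' analysis requires more observations than variables, the largest window
#' must stay below the total reference sample count.
#'
#' @param map A [locus_map()].
#' @param w Window half-width in SNPs (`>= 1`).
#' @param n_ref Optional total number of reference individuals (both source
#'   panels plus synthetic heterozygotes); when given, an error is raised if
#'   any window would reach this size.
#'
#' @return A tibble with one row per locus: `locus` (1-based row in the
#'   map), `chrom`, `start`, `end` (1-based bounds of the window, inclusive)
#'   and `size`.
#' @examples
#' m <- locus_map(rep("chr1", 5), c(10L, 20L, 30L, 40L, 50L))
#' build_windows(m, w = 1)
#' @export
build_windows <- function(map, w, n_ref = NULL) {
  w <- as.integer(w)
  if (is.na(w) || w < 1L) stop("`w` must be at least 1", call. = FALSE)
  cb <- chrom_bounds(map)
  locus <- seq_len(nrow(map))
  cstart <- rep(cb$start, cb$end - cb$start + 1L)
  cend <- rep(cb$end, cb$end - cb$start + 1L)
  start <- pmax(locus - w, cstart)
  end <- pmin(locus + w, cend)
  size <- end - start + 1L
  if (!is.null(n_ref) && any(size >= n_ref)) {
    stop(
      "window of ", max(size), " SNPs with only ", n_ref, " reference ",
      "individuals: the window cannot include more SNPs than reference ",
      "individuals (reduce `w` or add reference samples)",
      call. = FALSE
    )
  }
  tibble::tibble(
    locus = locus, chrom = map$chrom, start = start, end = end, size = size
  )
}
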