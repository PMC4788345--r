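#' Build a locus map
#'
#' A locus map records, for every marker, the chromosome it sits on, its
#' physical position, and its 0-based marker index within the chromosome.
#' Markers must be supplied in map order: positions strictly increasing
#' within each chromosome. All windowing and kernel smoothing in the package
#' treats chromosomes as fully independent units.
#'
#' @param chrom Character vector of chromosome identifiers, one per marker.
#' @param pos Integer vector of 1-based physical positions (base pairs).
#'
#' @return A tibble with columns `chrom`, `pos`, and `idx` (0-based index
#'   within chromosome), one row per marker, carrying class `locus_map`.
#' @examples
#' locus_map(c("chr1", "chr1", "chr2"), c(100L, 200L, 50L))
#' @export
locus_map <- function(chrom, pos) {
  if (length(chrom) != length(pos)) {
    stop("`chrom` and `pos` must have the same length", call. = FALSE)
  }
  if (length(pos) < 1L) {
    stop("a locus map needs at least one marker", call. = FALSE)
  }
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  if (anyNA(chrom) || anyNA(pos)) {
    stop("locus map fields must not be missing", call. = FALSE)
  }
  if (any(pos < 0L)) {
    stop("positions must be non-negative", call. = FALSE)
  }
  # chromosomes must form contiguous blocks so marker order is map order
  r <- rle(chrom)
  if (anyDuplicated(r$values)) {
    stop("markers of each chromosome must be contiguous in the map",
      call. = FALSE
    )
  }
  idx <- unlist(lapply(r$lengths, function(n) seq_len(n) - 1L),
    use.names = FALSE
  )
  bad <- tapply(pos, factor(chrom, levels = r$values), function(p) {
    any(diff(p) <= 0)
  })
  if (any(bad)) {
    stop(
      "positions must be strictly increasing within chromosome(s): ",
      paste(names(bad)[bad], collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::tibble(chrom = chrom, pos = pos, idx = idx)
  class(out) <- c("locus_map", class(out))
  out
}

#' Read a locus map from a tab-separated file
#'
#' The file must have a header line and two columns, `chrom` and `pos`.
#'
#' @param path Path to the map TSV.
#' @return A [locus_map()] tibble.
#' @export
read_locus_map <- function(path) {
  if (!file.exists(path)) stop("map file not found: ", path, call. = FALSE)
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos") %in% names(d))) {
    stop("map file must have columns 'chrom' and 'pos'", call. = FALSE)
  }
  locus_map(d$chrom, d$pos)
}

# contiguous 1-based [start, end] locus ranges per chromosome, in map order
chrom_bounds <- function(map) {
  r <- rle(map$chrom)
  end <- cumsum(r$lengths)
  tibble::tibble(
    chrom = r$values,
    start = end - r$lengths + 1L,
    end = end
  )
}
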