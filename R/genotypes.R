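#' Construct a genotype matrix with panel labels
#'
#' Genotypes are allele counts in `[0, 2]` (integer calls or posterior-mean
#' dosages), stored as a loci x individuals matrix alongside a [locus_map()]
#' and a panel label for every individual. The three panels are the two
#' source-population reference panels (`sourceA`, `sourceB`) and the admixed
#' panel whose ancestry frequencies are to be estimated. Missing genotypes
#' are allowed (`NA`); they are mean-imputed per locus within the relevant
#' panel when a model is fitted, never silently at read time.
#'
#' @param values Numeric matrix, loci x individuals, entries in `[0, 2]` or
#'   `NA`.
#' @param map A [locus_map()] with one row per row of `values`.
#' @param ids Character vector of individual identifiers (column names used
#'   if missing).
#' @param panels Character vector with one of `"sourceA"`, `"sourceB"`,
#'   `"admixed"` per individual.
#'
#' @return An object of class `genotype_matrix`: a list with elements `G`,
#'   `map`, `ids`, `panels`.
#' @export
genotype_matrix <- function(values, map, ids = colnames(values), panels) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!inherits(map, "locus_map")) map <- locus_map(map$chrom, map$pos)
  if (nrow(values) != nrow(map)) {
    stop(
      "genotype matrix has ", nrow(values), " loci but the map has ",
      nrow(map), " markers",
      call. = FALSE
    )
  }
  if (is.null(ids)) ids <- paste0("ind", seq_len(ncol(values)))
  ids <- as.character(ids)
  if (length(ids) != ncol(values) || length(panels) != ncol(values)) {
    stop("`ids` and `panels` must have one entry per individual",
      call. = FALSE
    )
  }
  panels <- as.character(panels)
  bad <- setdiff(unique(panels), c("sourceA", "sourceB", "admixed"))
  if (length(bad) > 0) {
    stop(
      "unknown panel label(s): ", paste(bad, collapse = ", "),
      " (expected sourceA, sourceB or admixed)",
      call. = FALSE
    )
  }
  rng <- range(values, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    stop("genotype values must lie in [0, 2]", call. = FALSE)
  }
  structure(
    list(G = values, map = map, ids = ids,
         panels = factor(panels, levels = c("sourceA", "sourceB", "admixed"))),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  tab <- table(x$panels)
  cat(
    "<genotype_matrix> ", nrow(x$G), " loci x ", ncol(x$G), " individuals (",
    paste(names(tab), tab, sep = ": ", collapse = ", "), ")\n",
    sep = ""
  )
  cat(
    "  chromosomes: ", paste(unique(x$map$chrom), collapse = ", "),
    "; missing entries: ", sum(is.na(x$G)), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$G)

#' Read genotypes, locus map and panel labels from TSV files
#'
#' The genotype file has loci as rows and individuals as columns, tab
#' separated, with a header row of individual ids. The map file has columns
#' `chrom` and `pos` (one row per genotype row) and the panel file has
#' columns `id` and `label` (`sourceA`, `sourceB` or `admixed`).
#'
#' @param genotype_path,map_path,panel_path File paths.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(genotype_path, map_path, panel_path) {
  if (!file.exists(genotype_path)) {
    stop("genotype file not found: ", genotype_path, call. = FALSE)
  }
  g <- read.delim(genotype_path, check.names = FALSE)
  map <- read_locus_map(map_path)
  if (nrow(g) != nrow(map)) {
    stop(
      "genotype file has ", nrow(g), " loci but the map has ", nrow(map),
      " markers",
      call. = FALSE
    )
  }
  if (!file.exists(panel_path)) {
    stop("panel file not found: ", panel_path, call. = FALSE)
  }
  p <- read.delim(panel_path, stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(p))) {
    stop("panel file must have columns 'id' and 'label'", call. = FALSE)
  }
  ids <- names(g)
  miss <- setdiff(ids, p$id)
  if (length(miss) > 0) {
    stop(
      "no panel label for individual(s): ", paste(head(miss, 5), collapse = ", "),
      call. = FALSE
    )
  }
  panels <- p$label[match(ids, p$id)]
  genotype_matrix(as.matrix(g), map, ids = ids, panels = panels)
}

#' Read genotypes from a VCF
#'
#' Biallelic SNPs only; the GT field is converted to the count of the
#' alternate allele (unphased and phased genotypes are both accepted).
#' Sites with more than one alternate allele are dropped with a message.
#'
#' @param vcf_path Path to a VCF (may be bgzipped).
#' @param panel_path Panel TSV with columns `id` and `label`, as in
#'   [read_genotypes()].
#' @return A [genotype_matrix()].
#' @export
read_vcf_genotypes <- function(vcf_path, panel_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  biallelic <- !grepl(",", fix[, "ALT"], fixed = TRUE) & fix[, "ALT"] != "."
  if (!all(biallelic)) {
    message("dropping ", sum(!biallelic), " non-biallelic site(s)")
  }
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  counts <- apply(gt, 2, function(col) {
    alleles <- strsplit(col, "[/|]")
    vapply(alleles, function(a) {
      if (length(a) == 0 || anyNA(a) || any(a == ".")) return(NA_real_)
      sum(a == "1")
    }, numeric(1))
  })
  counts <- matrix(counts,
    nrow = sum(biallelic),
    dimnames = list(NULL, colnames(gt))
  )
  map <- locus_map(fix[biallelic, "CHROM"], as.integer(fix[biallelic, "POS"]))
  p <- read.delim(panel_path, stringsAsFactors = FALSE)
  panels <- p$label[match(colnames(counts), p$id)]
  genotype_matrix(counts, map, ids = colnames(counts), panels = panels)
}

# Mean-impute missing genotypes per locus within each panel. DA and the
# discriminant projection need complete vectors; the imputed count is
# reported via message() when verbose.
impute_missing <- function(geno, verbose = FALSE) {
  n_missing <- sum(is.na(geno$G))
  if (n_missing == 0) return(geno)
  for (p in levels(geno$panels)) {
    cols <- which(geno$panels == p)
    if (length(cols) == 0) next
    sub <- geno$G[, cols, drop = FALSE]
    if (!anyNA(sub)) next
    mu <- rowMeans(sub, na.rm = TRUE)
    mu[!is.finite(mu)] <- 1 # locus entirely missing in this panel
    idx <- which(is.na(sub), arr.ind = TRUE)
    sub[idx] <- mu[idx[, 1]]
    geno$G[, cols] <- sub
  }
  if (verbose) message("mean-imputed ", n_missing, " missing genotype(s)")
  geno
}

# split a genotype_matrix into the three panel sub-matrices
panel_split <- function(geno) {
  lapply(
    setNames(nm = c("sourceA", "sourceB", "admixed")),
    function(p) geno$G[, geno$panels == p, drop = FALSE]
  )
}
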