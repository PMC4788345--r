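#' Write a per-locus posterior summary track
#'
#' One data row per locus: chromosome, position, posterior mean, median,
#' the 95% ETPI and, when present, the beta-binomial interval. Numbers are
#' written at 10 significant digits so that a write-read round trip is
#' lossless at that precision.
#'
#' @param fit An `ancfreq_fit` or `ancfreq_summary`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(fit, path) {
  loci <- if (inherits(fit, "ancfreq_fit")) fit$summary$loci else fit$loci
  d <- as.data.frame(loci)
  num <- vapply(d, is.numeric, logical(1)) & names(d) != "pos"
  d[num] <- lapply(d[num], function(x) sprintf("%.10g", x))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ok <- tryCatch(
    {
      write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
      TRUE
    },
    error = function(e) FALSE
  )
  if (!ok) stop("cannot write summary to ", path, call. = FALSE)
  invisible(path)
}

#' Read a posterior summary track
#'
#' @param path A TSV written by [write_summary()].
#' @return A tibble.
#' @export
read_summary <- function(path) {
  if (!file.exists(path)) stop("summary file not found: ", path, call. = FALSE)
  tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
}

#' Persist raw thinned MCMC draws
#'
#' Writes one plain-text matrix per chain and parameter block
#' (`q_chain<k>.tsv`, `zsum_chain<k>.tsv`, `sigma.tsv`) under `dir`, keyed
#' by chain. Reading back reproduces the draw arrays exactly at the stored
#' 17-digit precision.
#'
#' @param fit An `ancfreq_fit` created with `keep_draws = TRUE`, or an
#'   `ancfreq_chains` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_draws <- function(fit, dir) {
  chains <- if (inherits(fit, "ancfreq_fit")) fit$draws else fit
  if (is.null(chains)) {
    stop("fit was created without `keep_draws = TRUE`", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in seq_along(chains$q)) {
    qf <- file.path(dir, sprintf("q_chain%d.tsv", ch))
    write.table(
      format(chains$q[[ch]], digits = 17, scientific = TRUE, trim = TRUE),
      qf,
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
    zf <- file.path(dir, sprintf("zsum_chain%d.tsv", ch))
    write.table(chains$zsum[[ch]], zf,
      sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE
    )
  }
  sig <- data.frame(
    chain = rep(seq_along(chains$sigma), lengths(chains$sigma)),
    sigma = sprintf("%.17g", unlist(chains$sigma))
  )
  write.table(sig, file.path(dir, "sigma.tsv"),
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(dir)
}

#' Read back raw draws written by [write_draws()]
#'
#' @param dir Directory containing the draw files.
#' @return A list with `q` and `zsum` (lists of matrices, one per chain)
#'   and `sigma` (list of numeric vectors).
#' @export
read_draws <- function(dir) {
  qf <- sort(list.files(dir, "^q_chain[0-9]+\\.tsv$", full.names = TRUE))
  if (length(qf) == 0) stop("no draw files under ", dir, call. = FALSE)
  q <- lapply(qf, function(f) as.matrix(read.delim(f, header = FALSE)))
  zf <- sort(list.files(dir, "^zsum_chain[0-9]+\\.tsv$", full.names = TRUE))
  zsum <- lapply(zf, function(f) as.matrix(read.delim(f, header = FALSE)))
  sig <- read.delim(file.path(dir, "sigma.tsv"))
  list(
    q = lapply(q, unname), zsum = lapply(zsum, unname),
    sigma = unname(split(sig$sigma, sig$chain))
  )
}

#' Write a simulated data set as TSV files
#'
#' Emits the genotype/map/panel TSV trio accepted by [read_genotypes()],
#' a truth TSV (per-locus true ancestry frequency plus the per-individual
#' true dosage), and a JSON provenance record of the configuration and
#' seed.
#'
#' @param sim An [simulate_admixture()] result (with genotypes).
#' @param dir Output directory.
#' @param seed The seed used, recorded in the provenance JSON.
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir, seed = NULL) {
  stopifnot(inherits(sim, "admixture_sim"))
  if (is.null(sim$genotypes)) {
    stop("simulation was run without genotype emission", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- as.data.frame(sim$genotypes$G)
  names(g) <- sim$genotypes$ids
  write.table(g, file.path(dir, "genotypes.tsv"),
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  write.table(
    data.frame(chrom = sim$map$chrom, pos = sim$map$pos),
    file.path(dir, "map.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  write.table(
    data.frame(
      id = sim$genotypes$ids,
      label = as.character(sim$genotypes$panels)
    ),
    file.path(dir, "panels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  truth <- cbind(
    as.data.frame(sim$truth),
    setNames(
      as.data.frame(sim$z),
      paste0("dosage_", seq_len(ncol(sim$z)))
    )
  )
  write.table(truth, file.path(dir, "truth.tsv"),
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  prov <- c(
    unclass(sim$config),
    list(seed = seed, package_version = as.character(utils::packageVersion("ancfreq")))
  )
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(dir)
}
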