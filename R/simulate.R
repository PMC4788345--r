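#' Configure a tract-based admixture simulation
#'
#' The simulator is individual-based and tracks ancestry tracts rather
#' than markers. An admixed population of `N` diploids is founded by
#' hybridisation between two source populations and then evolves for `t`
#' discrete Wright-Fisher generations with exactly one crossover per
#' chromosome per meiosis (uniform position on a 1-Morgan map), genetic
#' drift, optional multiplicative underdominant selection against
#' inter-population ancestry, and optional replacement of a fraction `m`
#' of each generation by unadmixed immigrants.
#'
#' @param N Diploid admixed population size.
#' @param t Generations since admixture (`>= 0`).
#' @param n_chrom Number of chromosomes (each of map length `chrom_length`
#'   Morgans).
#' @param chrom_length Map length per chromosome in Morgans.
#' @param n_markers Equally spaced markers per chromosome.
#' @param m Migration rate: proportion of the admixed population replaced
#'   by unadmixed immigrants each generation, in `[0, 1)`.
#' @param s Underdominance selection coefficient in `[0, 1)`; fitness is
#'   `(1 - s)^l` with `l` the number of selected loci at which an
#'   individual carries one gene copy from each source.
#' @param sel_chrom,sel_pos Chromosome index (1-based) and map position
#'   (Morgans) of each selected locus.
#' @param n_adm Number of admixed individuals sampled at the end.
#' @param n_ref Reference individuals sampled per source population.
#' @param founders `"pure"` founds the admixed population as an equal mix
#'   of unadmixed A and B individuals (hybridisation then happens in the
#'   first generation); `"f1"` founds it entirely with F1s.
#' @param f_formula Inbreeding-style drift coefficient for within-ancestry
#'   allele frequencies: `"tN"` uses `F = 1 - exp(-t/N)`, `"t2N"` uses
#'   `F = 1 - exp(-t/(2N))`.
#' @param p_range Bounds of the uniform distribution for source allele
#'   frequencies.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(N = 500L, t = 20L, n_chrom = 2L, chrom_length = 1,
                       n_markers = 10001L, m = 0, s = 0,
                       sel_chrom = integer(), sel_pos = numeric(),
                       n_adm = 50L, n_ref = 50L,
                       founders = c("pure", "f1"),
                       f_formula = c("tN", "t2N"),
                       p_range = c(0.05, 0.95)) {
  founders <- match.arg(founders)
  f_formula <- match.arg(f_formula)
  N <- as.integer(N)
  t <- as.integer(t)
  if (N < 2L) stop("`N` must be at least 2", call. = FALSE)
  if (t < 0L) stop("`t` must be non-negative", call. = FALSE)
  if (m < 0 || m >= 1) stop("`m` must lie in [0, 1)", call. = FALSE)
  if (s < 0 || s >= 1) stop("`s` must lie in [0, 1)", call. = FALSE)
  if (length(sel_chrom) != length(sel_pos)) {
    stop("`sel_chrom` and `sel_pos` must have equal length", call. = FALSE)
  }
  if (length(sel_pos) > 0 &&
    (any(sel_pos < 0) || any(sel_pos > chrom_length) ||
      any(sel_chrom < 1) || any(sel_chrom > n_chrom))) {
    stop("selected loci must lie on the simulated map", call. = FALSE)
  }
  if (n_adm > N) {
    stop("cannot sample more admixed individuals than the population holds",
      call. = FALSE
    )
  }
  structure(
    list(
      N = N, t = t, n_chrom = as.integer(n_chrom),
      chrom_length = chrom_length, n_markers = as.integer(n_markers),
      m = m, s = s, sel_chrom = as.integer(sel_chrom), sel_pos = sel_pos,
      n_adm = as.integer(n_adm), n_ref = as.integer(n_ref),
      founders = founders, f_formula = f_formula, p_range = p_range
    ),
    class = "sim_config"
  )
}

#' Simulation presets for the accuracy study
#'
#' Named presets covering the simulation grid: time since admixture
#' `t` in 20, 50, 200 generations; no, diffuse (`s = 0.03`, 20 loci, 10
#' per chromosome) or strong (`s = 0.3`, 2 loci on chromosome 1 at 1/3 and
#' 2/3 of its length) underdominant selection; and ongoing migration at
#' `m = 0.005` or `m = 0.05` for `t = 200`. All use `N = 500` and two
#' 1-Morgan chromosomes.
#'
#' @param name One of `"t20"`, `"t50"`, `"t200"`, `"t50_diffuse"`,
#'   `"t50_strong"`, `"t200_m005"`, `"t200_m05"`.
#' @param ... Overrides passed on to [sim_config()] (for example
#'   `n_markers`).
#' @return A [sim_config()].
#' @export
sim_preset <- function(name, ...) {
  base <- switch(name,
    t20 = list(t = 20L),
    t50 = list(t = 50L),
    t200 = list(t = 200L),
    t50_diffuse = list(
      t = 50L, s = 0.03,
      sel_chrom = rep(1:2, each = 10),
      sel_pos = rep(seq(0.05, 0.95, length.out = 10), 2)
    ),
    t50_strong = list(
      t = 50L, s = 0.3, sel_chrom = c(1L, 1L), sel_pos = c(1 / 3, 2 / 3)
    ),
    t200_m005 = list(t = 200L, m = 0.005),
    t200_m05 = list(t = 200L, m = 0.05),
    stop("unknown preset: ", name, call. = FALSE)
  )
  do.call(sim_config, utils::modifyList(base, list(...)))
}

#' Multiplicative underdominance fitness
#'
#' `w = (1 - s)^l` where `l` counts selected loci at which an individual
#' has one gene copy from each source population.
#'
#' @param l_het Number of ancestry-heterozygous selected loci (vectorised).
#' @param s Selection coefficient.
#' @return Relative fitness in `(0, 1]`.
#' @examples
#' underdominance_fitness(2, 0.3) # 0.49
#' @export
underdominance_fitness <- function(l_het, s) {
  if (s < 0 || s >= 1) stop("`s` must lie in [0, 1)", call. = FALSE)
  (1 - s)^l_het
}

#' Drift a source allele frequency within ancestry segments
#'
#' Within-ancestry allele frequencies in the admixed population drift away
#' from the source values. New frequencies are drawn from the
#' Balding-Nichols beta distribution `Beta(p * gamma, (1 - p) * gamma)`
#' with `gamma = (1 - F) / F` and `F = 1 - exp(-t/N)` (or `-t/(2N)`),
#' which preserves the mean `p` and has variance `p (1 - p) F`.
#'
#' @param p Source allele frequency (vectorised, in `[0, 1]`).
#' @param t Generations since admixture.
#' @param N Diploid admixed population size.
#' @param f_formula `"tN"` or `"t2N"` (see [sim_config()]).
#' @return Drifted frequencies; `p` is returned unchanged when `t = 0` or
#'   when `p` is 0 or 1.
#' @export
drift_allele_freq <- function(p, t, N, f_formula = c("tN", "t2N")) {
  f_formula <- match.arg(f_formula)
  if (t < 0 || N < 1) stop("need t >= 0 and N >= 1", call. = FALSE)
  if (t == 0) return(p)
  FF <- 1 - exp(-t / (if (f_formula == "tN") N else 2 * N))
  gam <- (1 - FF) / FF
  out <- p
  inner <- p > 0 & p < 1
  out[inner] <- rbeta(sum(inner), p[inner] * gam, (1 - p[inner]) * gam)
  out
}

#' Emit SNP genotypes for a simulated admixed sample
#'
#' Source-panel individuals draw allele counts from
#' `Binomial(2, p_source)` with the original source frequencies; admixed
#' individuals draw each gene copy `Bernoulli(p')` where `p'` is the
#' drifted within-ancestry frequency matching the copy's true local
#' ancestry.
#'
#' @param hap1,hap2 Integer matrices (loci x admixed individuals) of true
#'   per-haplotype ancestry (1 = source A).
#' @param marker_model Tibble with per-locus `p_A`, `p_B` (source
#'   frequencies) and `p_A_drift`, `p_B_drift`.
#' @param n_ref Reference individuals per source panel.
#' @return A list with matrices `adm`, `refA`, `refB` of allele counts.
#' @export
emit_genotypes <- function(hap1, hap2, marker_model, n_ref) {
  L <- nrow(marker_model)
  nadm <- ncol(hap1)
  pr1 <- ifelse(hap1 == 1L, marker_model$p_A_drift, marker_model$p_B_drift)
  pr2 <- ifelse(hap2 == 1L, marker_model$p_A_drift, marker_model$p_B_drift)
  adm <- matrix(
    rbinom(L * nadm, 1L, pr1) + rbinom(L * nadm, 1L, pr2), L, nadm
  )
  refA <- matrix(rbinom(L * n_ref, 2L, marker_model$p_A), L, n_ref)
  refB <- matrix(rbinom(L * n_ref, 2L, marker_model$p_B), L, n_ref)
  list(adm = adm, refA = refA, refB = refB)
}

#' Simulate an admixed population and emit genotypes
#'
#' Runs the tract simulator, samples admixed and reference individuals,
#' draws per-marker source allele frequencies from
#' `Uniform(p_range[1], p_range[2])`, drifts the within-ancestry
#' frequencies, and emits genotypes for all three panels.
#'
#' @param config A [sim_config()].
#' @param genotypes Emit genotypes? When `FALSE` only the ancestry truth
#'   is generated (faster; used for block-size and fixation summaries).
#' @return An object of class `admixture_sim`: list with `genotypes` (a
#'   [genotype_matrix()], or `NULL`), `truth` (per-locus tibble with
#'   `q_true`), `z` (true dosage, loci x sampled individuals), `hap1` and
#'   `hap2` (per-haplotype ancestry), `tracts` (per-individual ancestry
#'   tract lists), `marker_model` and `config`.
#' @export
simulate_admixture <- function(config = sim_config(), genotypes = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  res <- cpp_simulate_tracts(
    config$N, config$t, config$n_chrom, config$chrom_length,
    config$m, config$s, config$sel_chrom, config$sel_pos,
    config$founders == "f1", config$n_adm, config$n_markers, FALSE
  )
  L <- config$n_chrom * config$n_markers
  map <- locus_map(
    rep(paste0("chr", seq_len(config$n_chrom)), each = config$n_markers),
    rep(100L * (seq_len(config$n_markers) - 1L) + 1L, config$n_chrom)
  )
  truth <- tibble::tibble(
    chrom = map$chrom, pos = map$pos, q_true = as.numeric(res$q_true)
  )
  geno <- NULL
  marker_model <- NULL
  if (genotypes) {
    p_A <- runif(L, config$p_range[1], config$p_range[2])
    p_B <- runif(L, config$p_range[1], config$p_range[2])
    marker_model <- tibble::tibble(
      p_A = p_A, p_B = p_B,
      p_A_drift = drift_allele_freq(p_A, config$t, config$N, config$f_formula),
      p_B_drift = drift_allele_freq(p_B, config$t, config$N, config$f_formula)
    )
    em <- emit_genotypes(res$hap1, res$hap2, marker_model, config$n_ref)
    G <- cbind(em$refA, em$refB, em$adm)
    ids <- c(
      paste0("A", seq_len(config$n_ref)),
      paste0("B", seq_len(config$n_ref)),
      paste0("adm", seq_len(config$n_adm))
    )
    panels <- rep(
      c("sourceA", "sourceB", "admixed"),
      c(config$n_ref, config$n_ref, config$n_adm)
    )
    geno <- genotype_matrix(G, map, ids = ids, panels = panels)
  }
  structure(
    list(
      genotypes = geno, truth = truth, z = res$z,
      hap1 = res$hap1, hap2 = res$hap2, tracts = res$tracts,
      marker_model = marker_model, map = map, config = config
    ),
    class = "admixture_sim"
  )
}

#' @export
print.admixture_sim <- function(x, ...) {
  cat(
    "<admixture_sim> N = ", x$config$N, ", t = ", x$config$t,
    " generations, ", x$config$n_chrom, " chromosome(s) x ",
    x$config$n_markers, " markers\n",
    sep = ""
  )
  cat(
    "  sampled ", ncol(x$z), " admixed individuals; mean q_true = ",
    sprintf("%.3f", mean(x$truth$q_true)), "\n",
    sep = ""
  )
  invisible(x)
}

#' Per-generation ancestry variance summaries
#'
#' Tracks, through time, the variance in genome-average ancestry among
#' individuals, the variance in local ancestry frequencies among loci, and
#' the realised proportion of (individual, locus) pairs carrying one gene
#' copy from each source population (inter-population ancestry). For an
#' admixed population these illustrate how individual-level variance
#' decays quickly while locus-level frequency variance keeps growing.
#'
#' @param config A [sim_config()]; `founders = "f1"` reproduces the
#'   classic all-F1 starting point where the inter-population proportion
#'   begins at 1.
#' @return A tibble with columns `generation` (0 = founders),
#'   `var_genome_avg`, `var_q`, `prop_interpop`.
#' @export
ancestry_summaries <- function(config = sim_config(
                                 N = 100L, t = 1000L, n_chrom = 1L,
                                 n_markers = 100L, founders = "f1"
                               )) {
  stopifnot(inherits(config, "sim_config"))
  res <- cpp_simulate_tracts(
    config$N, config$t, config$n_chrom, config$chrom_length,
    config$m, config$s, config$sel_chrom, config$sel_pos,
    config$founders == "f1", min(config$n_adm, config$N),
    config$n_markers, TRUE
  )
  tibble::tibble(
    generation = 0:config$t,
    var_genome_avg = res$series[, 1],
    var_q = res$series[, 2],
    prop_interpop = res$series[, 3]
  )
}

#' Mean ancestry-block size in SNPs
#'
#' Measures the realised size of ancestry blocks among the sampled
#' individuals as runs of constant ancestry dosage along each chromosome
#' (a breakpoint on either homologue ends a block). Each
#' individual-chromosome contributes the mean length of its runs; these
#' are averaged. The per-haplotype variant (runs of single-haplotype
#' ancestry) is also returned for reference.
#'
#' @param sim An [simulate_admixture()] result.
#' @return A one-row tibble with `mean_block_snps` (diploid dosage runs),
#'   `mean_block_snps_hap` (per-haplotype runs) and `n_blocks`.
#' @export
true_block_size <- function(sim) {
  stopifnot(inherits(sim, "admixture_sim"))
  nm <- sim$config$n_markers
  nc <- sim$config$n_chrom
  dip <- hap <- nb <- 0
  ndip <- nhap <- 0
  for (j in seq_len(ncol(sim$z))) {
    for (c in seq_len(nc)) {
      rows <- ((c - 1) * nm + 1):(c * nm)
      rd <- rle(sim$z[rows, j])$lengths
      dip <- dip + mean(rd)
      nb <- nb + length(rd)
      ndip <- ndip + 1
      r1 <- rle(sim$hap1[rows, j])$lengths
      r2 <- rle(sim$hap2[rows, j])$lengths
      hap <- hap + mean(r1) + mean(r2)
      nhap <- nhap + 2
    }
  }
  tibble::tibble(
    mean_block_snps = dip / ndip,
    mean_block_snps_hap = hap / nhap,
    n_blocks = nb
  )
}
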