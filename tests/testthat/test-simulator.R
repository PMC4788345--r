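test_that("F1 founding gives dosage one everywhere at t = 0", {
  set.seed(22)
  sim <- simulate_admixture(
    sim_config(N = 20, t = 0, n_chrom = 2, n_markers = 50, n_adm = 10,
               founders = "f1"),
    genotypes = FALSE
  )
  expect_true(all(sim$z == 1L))
  expect_true(all(sim$truth$q_true == 0.5))
  expect_equal(true_block_size(sim)$mean_block_snps, 50)
})

test_that("pure founding gives unadmixed individuals at t = 0", {
  set.seed(23)
  sim <- simulate_admixture(
    sim_config(N = 20, t = 0, n_markers = 40, n_adm = 20),
    genotypes = FALSE
  )
  expect_true(all(sim$z %in% c(0L, 2L)))
  expect_equal(mean(sim$truth$q_true), 0.5)
})

test_that("tract lists stay well-formed after evolution", {
  set.seed(24)
  sim <- simulate_admixture(
    sim_config(N = 40, t = 15, n_chrom = 2, n_markers = 30, n_adm = 15),
    genotypes = FALSE
  )
  for (ind in sim$tracts) {
    for (ch in ind) {
      for (h in c("h1", "h2")) {
        bp <- ch[[paste0(h, "_bp")]]
        anc <- ch[[paste0(h, "_anc")]]
        expect_equal(bp[length(bp)], 1) # full coverage to chromosome end
        expect_true(all(diff(bp) > 0)) # strictly increasing breakpoints
        if (length(anc) > 1) {
          expect_true(all(diff(anc) != 0)) # adjacent tracts differ
        }
        expect_true(all(anc %in% 0:1))
      }
    }
  }
})

test_that("one generation from F1 parents yields exactly one breakpoint", {
  set.seed(25)
  sim <- simulate_admixture(
    sim_config(N = 60, t = 1, n_chrom = 1, n_markers = 200, n_adm = 60,
               founders = "f1"),
    genotypes = FALSE
  )
  nb <- vapply(sim$tracts, function(ind) {
    length(ind[[1]]$h1_bp)
  }, numeric(1))
  expect_true(all(nb == 2)) # two tracts = one ancestry breakpoint
})

test_that("neutral closed simulations conserve mean ancestry", {
  set.seed(26)
  qbar <- replicate(12, {
    sim <- simulate_admixture(
      sim_config(N = 100, t = 15, n_chrom = 1, n_markers = 60, n_adm = 30),
      genotypes = FALSE
    )
    mean(sim$truth$q_true)
  })
  expect_equal(mean(qbar), 0.5, tolerance = 0.06)
})

test_that("underdominance fitness is multiplicative in het loci", {
  expect_equal(underdominance_fitness(0, 0.3), 1)
  expect_equal(underdominance_fitness(2, 0.3), 0.49)
  expect_equal(underdominance_fitness(20, 0.03), 0.97^20)
  expect_error(underdominance_fitness(1, 1.2))
})

test_that("strong selection removes inter-population ancestry at the target", {
  set.seed(27)
  sim <- simulate_admixture(
    sim_preset("t50_strong", n_markers = 301, N = 300),
    genotypes = FALSE
  )
  # ancestry frequency variance should be inflated near the selected loci
  sel_idx <- round(301 * c(1 / 3, 2 / 3))
  dev_sel <- mean(abs(sim$truth$q_true[sel_idx] - 0.5))
  dev_all <- mean(abs(sim$truth$q_true[302:602] - 0.5)) # neutral chrom 2
  expect_gt(dev_sel, dev_all)
})

test_that("drift preserves the mean and has Balding-Nichols variance", {
  expect_equal(drift_allele_freq(0.37, 0, 500), 0.37)
  expect_equal(drift_allele_freq(c(0, 1), 200, 500), c(0, 1))
  set.seed(28)
  p <- 0.3
  FF <- 1 - exp(-200 / 500) # 0.3297
  draws <- drift_allele_freq(rep(p, 1e5), 200, 500)
  expect_equal(mean(draws), p, tolerance = 0.01)
  expect_equal(var(draws), p * (1 - p) * FF, tolerance = 0.01)
  # the alternative 2N clock drifts less
  d2 <- drift_allele_freq(rep(p, 1e5), 200, 500, f_formula = "t2N")
  expect_lt(var(d2), var(draws))
  # near-complete fixation for very old admixture
  old <- drift_allele_freq(rep(0.5, 1e4), 5e4, 500)
  expect_gt(mean(old < 0.05 | old > 0.95), 0.9)
})

test_that("fully diagnostic markers emit genotype = dosage", {
  set.seed(29)
  sim <- simulate_admixture(
    sim_config(N = 30, t = 10, n_chrom = 1, n_markers = 40, n_adm = 10,
               n_ref = 5),
    genotypes = FALSE
  )
  mm <- tibble::tibble(
    p_A = rep(1, 40), p_B = rep(0, 40),
    p_A_drift = rep(1, 40), p_B_drift = rep(0, 40)
  )
  em <- emit_genotypes(sim$hap1, sim$hap2, mm, n_ref = 5)
  expect_equal(em$adm, matrix(as.numeric(sim$z), 40, 10))
  expect_true(all(em$refA == 2) && all(em$refB == 0))
})

test_that("admixed allele frequencies follow the mixture expectation", {
  set.seed(30)
  sim <- simulate_admixture(sim_config(N = 200, t = 20, n_chrom = 2,
                                       n_markers = 1500, n_adm = 200))
  g <- sim$genotypes
  adm <- g$G[, g$panels == "admixed"]
  obs <- rowMeans(adm) / 2
  # per-locus sample ancestry frequency, not the population one
  qs <- rowMeans(sim$z) / 2
  expected <- qs * sim$marker_model$p_A_drift +
    (1 - qs) * sim$marker_model$p_B_drift
  expect_equal(mean(obs - expected), 0, tolerance = 0.005)
  expect_gt(cor(obs, expected), 0.97)
})

test_that("ancestry summaries show decay of individual-level variance", {
  set.seed(31)
  ser <- ancestry_summaries(sim_config(N = 100, t = 120, n_chrom = 1,
                                       n_markers = 100, founders = "f1"))
  expect_equal(ser$var_genome_avg[1], 0) # all F1s identical
  expect_equal(ser$prop_interpop[1], 1)
  # genome-average variance rises then decays; q variance grows
  late <- mean(tail(ser$var_genome_avg, 20))
  peak <- max(ser$var_genome_avg)
  expect_lt(late, peak / 2)
  expect_gt(mean(tail(ser$var_q, 10)), mean(ser$var_q[2:11]))
  expect_lt(mean(tail(ser$prop_interpop, 10)), 0.5)
})

test_that("block size bookkeeping conserves markers", {
  set.seed(32)
  sim <- simulate_admixture(
    sim_config(N = 50, t = 25, n_chrom = 2, n_markers = 120, n_adm = 20),
    genotypes = FALSE
  )
  # per-haplotype runs partition each chromosome's markers
  runs <- 0
  tot <- 0
  for (j in seq_len(ncol(sim$z))) {
    for (c in 1:2) {
      rows <- ((c - 1) * 120 + 1):(c * 120)
      r <- rle(sim$hap1[rows, j])$lengths
      runs <- runs + length(r)
      tot <- tot + sum(r)
    }
  }
  expect_equal(tot, 20 * 2 * 120)
  bs <- true_block_size(sim)
  expect_gt(bs$mean_block_snps, 1)
  expect_lte(bs$mean_block_snps, 120)
})

test_that("seeded simulations are fully reproducible", {
  cfg <- sim_config(N = 40, t = 10, n_markers = 60, n_adm = 12)
  set.seed(123)
  s1 <- simulate_admixture(cfg)
  set.seed(123)
  s2 <- simulate_admixture(cfg)
  expect_identical(s1$z, s2$z)
  expect_identical(s1$genotypes$G, s2$genotypes$G)
  expect_identical(s1$truth$q_true, s2$truth$q_true)
})

test_that("sampling more individuals than the population errors", {
  expect_error(sim_config(N = 10, n_adm = 20), "cannot sample")
})
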