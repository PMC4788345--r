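test_that("windows truncate at chromosome ends and never span chromosomes", {
  m5 <- tiny_map(5)
  w <- build_windows(m5, 1)
  expect_equal(w$size, c(2L, 3L, 3L, 3L, 2L))
  expect_true(all(w$start <= w$locus & w$locus <= w$end))

  m32 <- two_chrom_map(3, 2)
  w2 <- build_windows(m32, 2)
  expect_true(all(w2$end[1:3] <= 3))
  expect_true(all(w2$start[4:5] >= 4))

  big <- locus_map(rep("chr1", 101), seq(1L, by = 10L, length.out = 101))
  w3 <- build_windows(big, 10)
  expect_equal(w3$size[51], 21L)

  expect_error(
    build_windows(m5, 2, n_ref = 5),
    "cannot include more SNPs than reference individuals"
  )
})

test_that("synthetic heterozygotes combine one allele from each source", {
  refA <- matrix(2, 5, 4)
  refB <- matrix(0, 5, 4)
  expect_equal(simulate_het_references(refA, refB, 3),
               matrix(1, 5, 3))
  expect_equal(simulate_het_references(refA + 0, refA, 2), matrix(2, 5, 2))
  expect_error(simulate_het_references(refA, refB, 0), "at least 1")

  set.seed(4)
  pA <- 0.8
  pB <- 0.2
  refA <- matrix(rbinom(2000, 2, pA), 2, 1000)
  refB <- matrix(rbinom(2000, 2, pB), 2, 1000)
  het <- simulate_het_references(refA, refB, 500)
  expect_equal(mean(het), pA + pB, tolerance = 0.03)
})

test_that("discriminant puts weight on the separating SNP and orders groups", {
  set.seed(5)
  grp <- rep(0:2, each = 10)
  x <- cbind(grp + rnorm(30, sd = 0.01), rep(0.5, 30))
  f <- fit_discriminant(x, grp)
  expect_gt(abs(f$coef[1]), 0.999)
  expect_true(f$means[1] < f$means[2] && f$means[2] < f$means[3])

  # duplicating every reference individual leaves the model unchanged
  f2 <- fit_discriminant(rbind(x, x), c(grp, grp))
  expect_equal(abs(sum(f$coef * f2$coef)), 1, tolerance = 1e-6)
  expect_equal(f$means, f2$means, tolerance = 1e-8)
})

test_that("coefficients match a dense generalized-eigenproblem oracle", {
  set.seed(6)
  for (k in 1:100) {
    wd <- random_window(p = sample(2:6, 1), n_per_group = sample(10:30, 1))
    f <- fit_discriminant(wd$x, wd$grp)
    v <- oracle_da_coef(wd$x, wd$grp)
    expect_equal(abs(sum(f$coef * v)), 1, tolerance = 1e-8)
  }
})

test_that("scores are centred dot products and reproduce stored moments", {
  set.seed(7)
  wd <- random_window(p = 2)
  f <- fit_discriminant(wd$x, wd$grp)
  gm <- colMeans(wd$x)
  expect_equal(score_individuals(f, matrix(gm, 1)), 0, tolerance = 1e-12)

  xnew <- matrix(c(1.3, -0.4), 1)
  expect_equal(
    score_individuals(f, xnew),
    sum((xnew - gm) * f$coef),
    tolerance = 1e-12
  )

  sc <- score_individuals(f, wd$x)
  for (g in 0:2) {
    expect_equal(mean(sc[wd$grp == g]), f$means[g + 1], tolerance = 1e-10)
    expect_equal(var(sc[wd$grp == g]), f$vars[g + 1], tolerance = 1e-6)
  }
  expect_error(score_individuals(f, matrix(0, 1, 5)), "window")
})

test_that("likelihoods are floored normal densities of the scores", {
  set.seed(8)
  geno <- tiny_genotypes(L = 8)
  bl <- ancfreq:::build_likelihoods(geno, run_config(w = 2),
                                    keep_models = TRUE)
  # independent check at one locus/individual against dnorm
  for (x in c(1, 5, 8)) {
    m <- bl$models[[x]]
    d <- bl$scores[x, ]
    for (g in 1:3) {
      expect_equal(
        bl$lik[g, , x],
        pmax(dnorm(d, m$means[g], sqrt(m$vars[g])), 1e-300),
        tolerance = 1e-12
      )
    }
  }
  # mode of the normal: density at the group mean
  m <- bl$models[[3]]
  expect_equal(
    dnorm(m$means[2], m$means[2], sqrt(m$vars[2])),
    1 / sqrt(2 * pi * m$vars[2])
  )
  expect_true(all(bl$lik > 0) && all(is.finite(bl$lik)))
})

test_that("equal group variances put the midpoint at equal likelihood", {
  f <- structure(
    list(coef = 1, offset = 0, means = c(-1, 0, 1), vars = c(1, 1, 1),
         n_floored = 0),
    class = "discriminant_model"
  )
  w <- tibble::tibble(locus = 1L, chrom = "chr1", start = 1L, end = 1L,
                      size = 1L)
  lg <- likelihood_grid(list(f), w, matrix(0, 1, 1))
  expect_equal(lg$lik[1, 1, 1], lg$lik[3, 1, 1])
})

test_that("adding a constant to one SNP changes no scores", {
  set.seed(9)
  wd <- random_window(p = 4)
  adm <- matrix(rnorm(20 * 4), 20, 4)
  f1 <- fit_discriminant(wd$x, wd$grp)
  s1 <- score_individuals(f1, adm)
  shifted <- wd$x
  shifted[, 2] <- shifted[, 2] + 0.7
  adm2 <- adm
  adm2[, 2] <- adm2[, 2] + 0.7
  f2 <- fit_discriminant(shifted, wd$grp)
  s2 <- score_individuals(f2, adm2)
  expect_equal(f2$coef, f1$coef, tolerance = 1e-8)
  expect_equal(s2, s1, tolerance = 1e-8)
  expect_equal(f2$means, f1$means, tolerance = 1e-8)
  expect_equal(f2$vars, f1$vars, tolerance = 1e-8)
})

test_that("diagnostic windows recover true dosage almost everywhere", {
  set.seed(10)
  L <- 200
  nadm <- 20
  map <- locus_map(rep("chr1", L), seq(100L, by = 100L, length.out = L))
  # block-structured truth: constant dosage per individual, as windows assume
  z <- matrix(rep(rbinom(nadm, 2, 0.5), each = L), L, nadm)
  geno <- genotype_matrix(
    cbind(matrix(2, L, 10), matrix(0, L, 10), z), map,
    ids = c(paste0("A", 1:10), paste0("B", 1:10), paste0("m", 1:nadm)),
    panels = rep(c("sourceA", "sourceB", "admixed"), c(10, 10, nadm))
  )
  bl <- ancfreq:::build_likelihoods(geno, run_config(w = 4))
  ml <- apply(bl$lik, c(2, 3), which.max) - 1L # individuals x loci
  interior <- 5:(L - 4)
  agree <- mean(t(ml)[interior, ] == z[interior, ])
  expect_gte(agree, 0.99)
})
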