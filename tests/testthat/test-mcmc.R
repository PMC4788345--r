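test_that("kernel weight follows the squared-exponential form", {
  expect_equal(kernel_weight(7, 7, 0.5), 1)
  expect_equal(kernel_weight(5, 3, 4), exp(-1))
  expect_equal(kernel_weight(1, 100, 1e12), 1, tolerance = 1e-6)
  expect_equal(kernel_weight(1, 2, 3, chrom_x = "chr1", chrom_i = "chr2"), 0)
  expect_error(kernel_weight(1, 2, -1), "positive")
})

test_that("kernel cache is symmetric and self-inclusive", {
  map <- two_chrom_map(6, 4)
  cache <- kernel_cache(map, sigma = 5)
  for (x in seq_len(nrow(map))) {
    expect_true(x %in% cache[[x]]$idx)
    expect_equal(cache[[x]]$w[cache[[x]]$idx == x], 1)
    expect_true(all(map$chrom[cache[[x]]$idx] == map$chrom[x]))
    for (i in cache[[x]]$idx) expect_true(x %in% cache[[i]]$idx)
  }
})

test_that("point-mass kernel gives the closed-form beta posterior for q", {
  set.seed(11)
  map <- tiny_map(1)
  cache <- kernel_cache(map, sigma = 1e-4) # truncates to the locus itself
  expect_equal(length(cache[[1]]$idx), 1L)
  draws <- replicate(4000, gibbs_update_q(10L, 25, cache, 1, 1))
  expect_equal(mean(draws), 11 / 52, tolerance = 0.01)
  expect_equal(var(draws), (11 * 41) / (52^2 * 53), tolerance = 0.15)
})

test_that("large sigma equalises shapes at adjacent loci", {
  map <- tiny_map(2)
  cache <- kernel_cache(map, sigma = 1e9)
  sh <- ancfreq:::kernel_shapes(c(0L, 50L), c(25, 25), cache, 1, 1)
  expect_equal(sh$alpha[1], sh$alpha[2], tolerance = 1e-6)
  expect_equal(sh$beta[1], sh$beta[2], tolerance = 1e-6)
  # hand-summed weighted counts: both loci see 0 + 50 successes
  expect_equal(sh$alpha[1], 1 + 50 * cache[[1]]$w[2] + 0, tolerance = 1e-9)
})

test_that("z update matches the enumerated categorical distribution", {
  set.seed(12)
  lik <- matrix(c(0.2, 0.5, 0.3), 3, 20000)
  z <- gibbs_update_z(lik, 0.5)
  p <- c(0.2 * 0.25, 0.5 * 0.5, 0.3 * 0.25)
  p <- p / sum(p)
  freq <- tabulate(z + 1L, 3) / length(z)
  expect_equal(freq, p, tolerance = 0.02)

  # equal likelihoods, q = 1/2: the Binomial(2, 1/2) prior
  zu <- gibbs_update_z(matrix(1, 3, 20000), 0.5)
  expect_equal(tabulate(zu + 1L, 3) / 20000, c(0.25, 0.5, 0.25),
               tolerance = 0.02)

  # prior degeneracy: q = 1 forces dosage 2
  expect_true(all(gibbs_update_z(matrix(1, 3, 100), 1) == 2L))
})

test_that("sigma log acceptance ratio equals the summed log-beta difference", {
  set.seed(13)
  map <- tiny_map(3)
  q <- c(0.2, 0.5, 0.7)
  zsum <- c(10L, 25L, 40L)
  cfg <- run_config(sigma_step = 0.4)
  sigma <- 2.5
  res <- withr::with_seed(99, metropolis_update_sigma(q, zsum, 25, sigma,
                                                      map, cfg))
  prop <- withr::with_seed(99, exp(log(sigma) + rnorm(1, 0, cfg$sigma_step)))
  sh_cur <- ancfreq:::kernel_shapes(zsum, rep(25, 3),
                                    kernel_cache(map, sigma, cfg$eps), 1, 1)
  sh_prop <- ancfreq:::kernel_shapes(zsum, rep(25, 3),
                                     kernel_cache(map, prop, cfg$eps), 1, 1)
  lr <- sum(dbeta(q, sh_prop$alpha, sh_prop$beta, log = TRUE)) -
    sum(dbeta(q, sh_cur$alpha, sh_cur$beta, log = TRUE))
  expect_equal(res$log_ratio, lr, tolerance = 1e-10)

  # out-of-bounds proposals are rejected outright
  res2 <- metropolis_update_sigma(q, zsum, 25, 999.9,
                                  map, run_config(sigma_step = 50))
  if (!res2$accepted) expect_equal(res2$sigma, 999.9)
  expect_true(res2$sigma >= cfg$sigma_min && res2$sigma <= cfg$sigma_max)
})

test_that("a perfectly diagnostic grid forces q to one", {
  set.seed(14)
  L <- 12
  nadm <- 25
  lik <- array(1e-12, c(3, nadm, L))
  lik[3, , ] <- 1 # state 2 overwhelmingly likely for everyone
  map <- locus_map(rep("chr1", L), seq(100L, by = 100L, length.out = L))
  ch <- run_mcmc(lik, map, run_config(iters = 400, burnin = 100, chains = 1))
  s <- summarize_posterior(ch, bb_intervals = FALSE)
  expect_true(all(s$loci$q_mean > 0.93))
  expect_gt(mean(s$loci$q_mean), 0.96)
})

test_that("a flat grid is governed by the smoothed binomial prior", {
  set.seed(15)
  L <- 20
  nadm <- 10
  lik <- array(1, c(3, nadm, L))
  map <- locus_map(rep("chr1", L), seq(100L, by = 100L, length.out = L))
  ch <- run_mcmc(lik, map, run_config(iters = 4000, burnin = 1300, chains = 2))
  s <- summarize_posterior(ch, bb_intervals = FALSE)
  expect_equal(mean(s$loci$q_mean), 0.5, tolerance = 0.06)
  expect_lt(max(s$diagnostics$q$psrf), 1.1)
})

test_that("with fixed z and point-mass kernel q draws are independent betas", {
  set.seed(16)
  L <- 6
  nadm <- 25
  z_true <- rep(c(0L, 1L, 2L), length.out = nadm)
  lik <- array(1e-30, c(3, nadm, L))
  for (j in seq_len(nadm)) lik[z_true[j] + 1, j, ] <- 1
  map <- locus_map(rep("chr1", L), seq(100L, by = 100L, length.out = L))
  cfg <- run_config(
    iters = 2500, burnin = 500, thin = 2, chains = 1,
    sigma_min = 0.0099, sigma_max = 0.0101 # kernel collapses to the locus
  )
  ch <- run_mcmc(lik, map, cfg)
  zs <- sum(z_true)
  for (x in c(1, 4)) {
    ks <- suppressWarnings(
      stats::ks.test(ch$q[[1]][x, ], stats::pbeta, zs + 1, 2 * nadm - zs + 1)
    )
    expect_gt(ks$p.value, 0.001)
  }
})

test_that("retained draws respect domain bounds", {
  set.seed(17)
  geno <- tiny_genotypes(L = 15)
  fit <- estimate_ancestry(
    geno,
    config = run_config(w = 3, iters = 300, burnin = 100, chains = 2),
    keep_draws = TRUE
  )
  for (ch in seq_len(2)) {
    q <- fit$draws$q[[ch]]
    expect_true(all(q >= 0 & q <= 1))
    zs <- fit$draws$zsum[[ch]]
    expect_true(all(zs >= 0 & zs <= 2 * fit$n_adm))
    sg <- fit$draws$sigma[[ch]]
    expect_true(all(sg >= 0.01 & sg <= 1000))
  }
  expect_true(all(fit$summary$dosage >= 0 & fit$summary$dosage <= 2))
  expect_true(all(fit$summary$loci$q_low <= fit$summary$loci$q_high))
  expect_true(all(fit$summary$loci$bb_low <= fit$summary$loci$bb_high))
})

test_that("increasing sigma never roughens the posterior mean surface", {
  set.seed(18)
  L <- 40
  nadm <- 12
  z_true <- matrix(rbinom(L * nadm, 2, rep(c(0.15, 0.85), each = L / 2)),
                   L, nadm, byrow = FALSE)
  lik <- array(1e-12, c(3, nadm, L))
  for (x in seq_len(L)) {
    for (j in seq_len(nadm)) lik[z_true[x, j] + 1, j, x] <- 1
  }
  map <- locus_map(rep("chr1", L), seq(100L, by = 100L, length.out = L))
  vars <- sapply(c(0.05, 2, 20, 200), function(sig) {
    cfg <- run_config(
      iters = 600, burnin = 200, chains = 1,
      sigma_min = sig * 0.999, sigma_max = sig * 1.001
    )
    ch <- run_mcmc(lik, map, cfg)
    var(rowMeans(do.call(cbind, ch$q)))
  })
  expect_true(all(diff(vars) <= 1e-4))
})
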