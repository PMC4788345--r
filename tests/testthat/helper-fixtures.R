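# Shared fixture builders. Everything is generated in code under a caller
# controlled seed; nothing is read from disk.

tiny_map <- function(n = 6, chrom = "chr1") {
  locus_map(rep(chrom, n), seq(100L, by = 100L, length.out = n))
}

two_chrom_map <- function(n1 = 3, n2 = 2) {
  locus_map(
    rep(c("chr1", "chr2"), c(n1, n2)),
    c(seq(100L, by = 100L, length.out = n1),
      seq(100L, by = 100L, length.out = n2))
  )
}

# small genotype_matrix with all three panels drawn from given allele
# frequencies (fixed differences by default make windows diagnostic)
tiny_genotypes <- function(L = 20, nA = 8, nB = 8, nadm = 6,
                           pA = 0.9, pB = 0.1, q = 0.5) {
  map <- locus_map(rep("chr1", L), seq(100L, by = 100L, length.out = L))
  GA <- matrix(rbinom(L * nA, 2, pA), L, nA)
  GB <- matrix(rbinom(L * nB, 2, pB), L, nB)
  z <- matrix(rbinom(L * nadm, 2, q), L, nadm)
  Gad <- matrix(
    rbinom(L * nadm, 1, ifelse(z >= 1, pA, pB)) +
      rbinom(L * nadm, 1, ifelse(z == 2, pA, pB)),
    L, nadm
  )
  genotype_matrix(
    cbind(GA, GB, Gad), map,
    ids = c(paste0("A", 1:nA), paste0("B", 1:nB), paste0("m", 1:nadm)),
    panels = rep(c("sourceA", "sourceB", "admixed"), c(nA, nB, nadm))
  )
}

# random reference window data for DA oracle checks
random_window <- function(p = 5, n_per_group = 30) {
  grp <- rep(0:2, each = n_per_group)
  mu <- outer(grp / 2, runif(p, -1, 1))
  x <- mu + matrix(rnorm(3 * n_per_group * p, sd = 0.7), ncol = p)
  list(x = x, grp = grp)
}

# independent dense oracle: pooled within covariance + between scatter by
# the textbook formulas, leading generalized eigenvector via base eigen()
oracle_da_coef <- function(x, grp, ridge = 1e-6) {
  n <- nrow(x)
  xc <- sweep(x, 2, colMeans(x))
  Sw <- matrix(0, ncol(x), ncol(x))
  mug <- matrix(0, 3, ncol(x))
  for (g in 0:2) {
    xg <- xc[grp == g, , drop = FALSE]
    mug[g + 1, ] <- colMeans(xg)
    cg <- sweep(xg, 2, colMeans(xg))
    Sw <- Sw + crossprod(cg)
  }
  Sw <- Sw / (n - 3)
  diag(Sw) <- diag(Sw) + ridge * mean(diag(Sw))
  SB <- crossprod(mug) / 3
  e <- eigen(solve(Sw) %*% SB)
  v <- Re(e$vectors[, which.max(Re(e$values))])
  v / sqrt(sum(v^2))
}

# minimal ancfreq_chains object for summariser tests
fake_chains <- function(q_draws_list, zsum_list, n_adm, map,
                        sigma = lapply(q_draws_list, function(m) {
                          rep(1, ncol(m))
                        })) {
  structure(
    list(
      q = q_draws_list, zsum = zsum_list, sigma = sigma,
      dosage = matrix(1, nrow(q_draws_list[[1]]), n_adm),
      accept_rate = 0.3, n_underflow = 0, n_adm = n_adm, map = map,
      config = run_config(iters = 100, burnin = 50)
    ),
    class = "ancfreq_chains"
  )
}
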