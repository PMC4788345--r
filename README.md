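# ancfreq

Population-level **local ancestry frequency** inference for admixed
populations, from un-phased SNP genotypes.

## Why

When two populations hybridise and the admixed population then evolves
in isolation, variation in genome-average ancestry among individuals
decays within tens of generations, but the frequency `q_x` of, say,
population-A ancestry at each locus keeps diverging along the genome
through drift and selection until ancestry blocks fix. Local-ancestry
HMMs assume `q_x` is constant across the genome; tree-based methods
assume fixation. `ancfreq` serves the regime in between — isolated
admixed populations still segregating for local ancestry — which is
where hybrid zones, homoploid hybrid lineages, and historically admixed
populations (tens to a couple of hundred generations old) typically sit.
It needs only un-phased allele counts (integer calls or posterior-mean
dosages, e.g. from genotyping-by-sequencing), reference panels from the
two sources, and a marker map.

## How

At locus `x`, the count of A gene copies among `n` sampled admixed
diploids is binomial with parameter `q_x`. A **continuous correlated
beta process** shares these counts across linked loci, giving the
conditional posterior

    q_x | z  ~  Beta( α₀ + Σᵢ zᵢ k(x,i),  β₀ + Σᵢ (2nᵢ − zᵢ) k(x,i) ),

with squared-exponential kernel `k(x,i) = exp(−(x−i)²/σ)` on marker
index distance (never across chromosomes). Latent individual ancestry
`z_xj ∈ {0,1,2}` is sampled from its 3-state conditional, combining the
`Binomial(2, q_x)` prior with a likelihood from **linear discriminant
analysis of SNP windows**: the two source panels anchor the 0- and
2-copy groups, simulated inter-population heterozygotes anchor the
1-copy group, and the likelihood of state `g` is a normal density of an
individual's discriminant score at group `g`'s reference score moments.
The kernel scale `σ` gets a Metropolis update under a uniform prior.
Because the kernel smoothing narrows the 95% equal-tail intervals below
nominal coverage, a beta-binomial interval
(`Beta(z_x + α₀, 2n − z_x + β₀)` over retained draws) is reported
alongside as the calibrated alternative.

The package also ships the study's **tract-based Wright–Fisher
simulator** (drift, underdominant selection `w = (1−s)^l`, migration,
Balding–Nichols within-ancestry allele-frequency drift), accuracy
metrics (RMSD, CVRMSD, Pearson r, interval coverage, a genome-average
null model), MCMC diagnostics (PSRF, ESS), and extraction of contiguous
regions of excess ancestry.

## Worked example

```r
library(ancfreq)
set.seed(7)
sim <- simulate_admixture(sim_preset("t20", n_markers = 2000))
fit <- estimate_ancestry(sim$genotypes, w = 20,
  config = run_config(iters = 6000, burnin = 2000, thin = 5))
tidy(fit)
accuracy_metrics(tidy(fit)$q_mean, sim$truth$q_true,
                 tidy(fit)$q_low, tidy(fit)$q_high)
```

```
#> # A tibble: 4,000 × 8
#>   chrom   pos q_mean q_median q_low q_high bb_low bb_high
#>   <chr> <int>  <dbl>    <dbl> <dbl>  <dbl>  <dbl>   <dbl>
#> 1 chr1      1  0.370    0.370 0.308  0.432  0.282   0.466
#> 2 chr1    101  0.369    0.370 0.315  0.426  0.275   0.465
#> 3 chr1    201  0.371    0.371 0.321  0.424  0.280   0.469
#> # ℹ 3,997 more rows
#> # A tibble: 1 × 6
#>     rmsd cvrmsd pearson_r coverage n_zero_truth r_defined
#>    <dbl>  <dbl>     <dbl>    <dbl>        <int> <lgl>
#> 1 0.0469 0.0805     0.824    0.752            0 TRUE
```

The first tibble is the per-locus posterior: mean/median and 95%
equal-tail interval for the frequency of source-A ancestry, plus the
wider beta-binomial interval. The second compares the posterior means
against the simulator's true frequencies: the estimates correlate with
truth at r ≈ 0.82 with a root-mean-square error of ~0.05 — typical for
20 generations since admixture with ±20-SNP windows at this marker
density. `autoplot(fit, truth = sim$truth$q_true)` draws the estimated
and true frequency tracks along both chromosomes, and `glance(fit)`
gives one row of run-level diagnostics (kernel scale, worst PSRF,
acceptance rate).

A command-line interface with `estimate`, `simulate`, `evaluate` and
`regions` subcommands is installed under `inst/scripts/ancfreq`, reading
the TSV trio (genotypes, map, panel labels) or VCF and writing per-locus
summary tracks.

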