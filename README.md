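# phclust

Model-based clustering of microbiome features (ASVs/OTUs) with mixtures of
**Poisson hurdle** distributions.

Microbiome count tables are sparse and unevenly sequenced: many zeros (a
blend of true absence and undersampling) and large depth differences between
samples. `phclust` groups features by their *pattern of change across
treatments* using a mixture model whose components handle the zero and
positive parts of each count separately, so both zero-inflated and
non-inflated features fit naturally.

## The model

For feature *g* in cluster *k*, count *N<sub>gij</sub>* (treatment *i*,
replicate *j*) follows a hurdle distribution

```
P(N = 0)     = 1 − q_kij
P(N = n), n>0 = q_kij · λ^n e^{−λ} / ( n! (1 − e^{−λ}) )      (zero-truncated Poisson)

log λ_kgij = s_ij + α_gk + μ_ki          Σ_i μ_ki = 0
q_kij      = logit⁻¹(γ0_ki + γ1_ki s_ij)  γ1_ki ≥ 0
```

with `s_ij` a fixed log upper-quartile sequencing-depth offset, `α_gk` the
feature's log abundance, `μ_ki` the cluster's treatment effects and `q` the
probability of a positive count. Fitting maximizes the mixture likelihood
`Π_g Σ_k p_k f(N_g | k)` by a generalized EM algorithm whose M step takes
one guarded Newton pass per parameter block (monotone in the likelihood by
construction), optionally with a simulated-annealing E step to escape local
maxima. Kendall's-τ seeding with multiple starts initializes the fit, and
the number of clusters is chosen by hierarchical merging with likelihood
ratio stopping (AIC/BIC baselines included). A fully specified zero-inflated
negative-binomial simulator with compositional resampling and the standard
external metrics (purity, adjusted Rand index, normalized mutual
information) round out the toolkit.

## Worked example

```r
library(phclust)

sim <- simulate_dataset(simulation_config(G = 300, K = 4, eta_mu = 2,
                                          phi = 0.6, seed = 1))
sim$counts
#> count_matrix: 300 features x 15 samples, 3 treatment group(s)
#> zero fraction: 0.465

fit <- multi_start(sim$counts, K = 4, n_starts = 5, seed = 1)
fit
#> phclust_fit: K = 4, loglik = -12959.773, 10 iterations (converged)
#> cluster sizes: 74 28 109 89

round(c(purity = purity(fit$assignments, sim$labels),
        ari    = adjusted_rand_index(fit$assignments, sim$labels),
        nmi    = nmi(fit$assignments, sim$labels)), 3)
#> purity    ari    nmi
#>  0.837  0.708  0.739
```

The simulator drew 300 features in 4 true clusters (46.5% zeros at gate
rate φ = 0.6); the five-start EM fit recovers the grouping with purity 0.84
and ARI 0.71 against the generating labels — the deliberately misspecified
generator (negative-binomial noise, abundance-dependent gating,
compositional resampling) keeps this below 1 even at moderate separation.

Choosing the number of clusters:

```r
ck <- choose_k(sim$counts, k_max = 8, n_starts = 2, seed = 1)
ck$K
#> [1] 4
ck$path[, c("K", "statistic", "df", "p_value", "rejected")]
#>   K statistic  df p_value rejected
#> 1 8      0.00 154       1    FALSE
#> 2 7     14.16 160       1    FALSE
#> 3 6     24.82 160       1    FALSE
#> 4 5     37.18 164       1    FALSE
#> 5 4   3110.86 306       0     TRUE
```

Merging from 8 clusters down is essentially free until the merge 4 → 3
would destroy real structure (statistic 3111 on 306 degrees of freedom),
so the procedure stops and reports K\* = 4, the true value.

A thin command-line front end over the same functions ships in
`inst/scripts/phclust.R` with subcommands `simulate`, `cluster`,
`choose-k`, `evaluate` and `experiment`.

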