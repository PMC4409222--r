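# nidge — robust Bayesian differential expression with normal/independent errors

`nidge` identifies differentially expressed genes from log-scale
expression matrices (bulk microarray/RNA intensity data, two or more
sample groups) when replicates are few and outliers are a fact of life.
It is aimed at statisticians and computational biologists who want a fully
Bayesian screen whose error model can be swapped between the normal,
Student t, slash, contaminated normal and Laplace distributions — the
normal/independent (N/I) family of scale mixtures of normals — and who
want calibrated posterior quantities rather than p-values.

## Model

For gene *i*, group *s*, replicate *r*:

    Y_isr = mu_is + e_isr / sqrt(u_isr),   e_isr ~ N(0, 1/tau_i),   u_isr ~ g(u; nu_i)

The latent scale `u_isr` down-weights outlying observations
observation-by-observation; choosing `g` selects the error family.
Differential expression is a mixture prior over equality patterns of the
group means — for two groups, a spike `mu_i1 = mu_i2` with probability
`1 - p` versus independent zero-mean normal slabs with probability `p`;
for k groups, all set partitions of the groups with a Dirichlet prior over
pattern probabilities, and a gene is DE when at least one pair of groups
separates (union–intersection test). All precisions carry diffuse
Gamma(1, 0.005) priors; family shapes are sampled per gene.

A collapsed Metropolis-within-Gibbs sampler (C++ core) integrates the
means out of the pattern update, so spike–slab moves mix freely. Output
per gene is the posterior DE probability `pi_i = P(not all means equal |
data)`, pairwise-separation probabilities for k > 2, and posterior mean
differences. Decisions at a threshold kappa come with Bayesian error
rates (bFDR, bFPR, bTPR, bTNR, bFNR), posterior-weighted ROC/AUC curves,
and — for simulation studies with known truth — frequentist TPR/FPR/TDR
and Mann–Whitney AUC.

## Worked example

Simulate a two-group study with contaminated-normal noise (10% of
observations with four-fold variance), 400 genes of which 20 are shifted
by 3 units in group 1, then fit the contaminated-normal model:

```r
library(nidge)
cfg <- simulation_config(
  N = 400, M = 1, delta = 3,
  error_family = nid_family("cn", c(0.1, 0.25)),
  mcmc = mcmc_config(n_iter = 4000, n_burnin = 2000, n_chains = 2),
  seed = 8)
gen  <- generate_dataset(cfg, 1)
fit  <- run_chains(gen$data, nid_family("cn"), cfg$mcmc)
post <- de_probability(fit)
bayes_rates(post, kappa = 0.5)
#> <decision_report> kappa=0.5: 20 called; bFDR=0.0039 bFPR=0.0002 bTPR=0.9441 bTNR=0.9998 bFNR=0.0559
replication_metrics(gen$truth, post$pi > 0.5, post$pi, cfg)
#> TPR FPR TDR AUC
#>   1   0   1   1
```

Reading the output: 20 genes exceed the 0.5 posterior threshold — exactly
the 20 truly shifted ones (TPR = 1, FPR = 0, truth-based AUC = 1). The
Bayesian rates are computed from the posterior probabilities alone (no
truth needed): the expected false-discovery proportion among the 20 calls
is 0.4%, and the posterior-weighted true-positive rate is 0.944 —
slightly below 1 because a little posterior DE mass sits on genes left
uncalled. The fit prints a Gelman–Rubin summary (`max R-hat: 1.06` here);
values above 1.1 trigger a warning to run longer chains.

Real data enter through `read_dataset(matrix.tsv, groups.tsv)` (genes ×
samples, log-transformed, tab- or comma-separated) and leave through
`write_results()`, which emits per-gene results, a decision table over
kappa ∈ {0.5, 0.7, 0.9, 0.95}, ROC points and a JSON manifest. A thin
command-line front end with `fit` / `simulate` / `roc` / `check`
subcommands is installed at `inst/cli/nidge.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/nidge.R", package="nidge"))')" \
    fit --matrix expr.tsv --groups groups.tsv --family laplace --out results/
```

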