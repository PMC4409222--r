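---
title: "Robust Bayesian differential expression with normal/independent errors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust Bayesian differential expression with normal/independent errors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nidge)
```

## The problem

Expression studies with a handful of replicates per condition routinely
contain outlying measurements: a single aberrant chip, a saturated spot, a
mis-hybridized probe. Under a Gaussian error model one such observation
inflates the gene's variance estimate, drags its group means, and can
silently flip the differential-expression call. `nidge` replaces the
Gaussian error with any member of the *normal/independent* (N/I) family of
scale mixtures of normals, letting the data down-weight suspect
observations instead of absorbing them.

## The model

For gene $i = 1,\dots,N$, group $s = 1,\dots,k$ and replicate
$r = 1,\dots,n_s$, the observed log-expression is

$$Y_{isr} = \mu_{is} + \varepsilon_{isr}/\sqrt{u_{isr}}, \qquad
  \varepsilon_{isr} \mid \tau_{\varepsilon i} \sim N(0,
  \tau_{\varepsilon i}^{-1}), \qquad u_{isr} \sim g(u;\nu_i),$$

so that conditional on the latent scale $u_{isr}$ the observation is
normal with variance $\sigma_i/u_{isr}$ (we write $\sigma_i =
\tau_{\varepsilon i}^{-1}$). The mixing law $g$ selects the family:

| family | mixing law | shape | marginal |
|---|---|---|---|
| normal | $u \equiv 1$ | — | normal |
| t | $u \sim \Gamma(v/2, v/2)$ | $v$ = df | Student t |
| slash | $u \sim \mathrm{Beta}(v, 1)$ | exponent $v$ | slash (polynomial tails) |
| contaminated normal | $u \in \{\gamma, 1\}$, $P(u = \gamma) = \lambda$ | $(\lambda, \gamma)$ | 2-component normal mixture |
| Laplace | $1/u \sim \mathrm{Exp}(v)$ | rate $v$ | double exponential |

Every non-normal member has heavier-than-normal tails; the latent
$u_{isr}$ acts as an observation-specific precision multiplier, so an
outlier is explained by a small $u$ rather than by distorting
$\mu_{is}$ or $\sigma_i$.

Differential expression enters through a mixture prior over *equality
patterns* of the group means. For two groups,

$$\boldsymbol\mu_i \sim (1-p)\, N(\mu_{i1}; 0, \tau_{\mu 12}^{-1})\,
  I[\mu_{i1} = \mu_{i2}] + p\, N(\mu_{i1}; 0, \tau_{\mu 1}^{-1})\,
  N(\mu_{i2}; 0, \tau_{\mu 2}^{-1})\, I[\mu_{i1} \ne \mu_{i2}],$$

i.e. a spike on exact equality and a slab of independent means. For $k$
groups the patterns are all set partitions of $\{1,\dots,k\}$ (5 patterns
for $k=3$, 15 for $k=4$; `enumerate_partitions()` orders them with the
all-equal partition first). A gene is differentially expressed when at
least one group pair lands in different blocks — the union–intersection
view of the $k$-group test — and the per-pair posterior probabilities are
reported alongside the global one. We support $2 \le k \le 5$; Bell-number
growth makes the full pattern mixture impractical beyond that.

Priors: every precision ($\tau_{\varepsilon i}$, and the mean-prior
precisions) carries $\Gamma(1, 0.005)$ (shape–rate; mean 200, very
diffuse — appropriate for log-scale expression data whose residual
variances are $O(1)$); the pattern probabilities carry a symmetric
Dirichlet with unit concentration; shapes are per gene, with $v \sim
U(0,100)$ (t), $v \sim \Gamma(1, 0.005)$ (slash, Laplace),
$\lambda_i, \gamma_i \sim U(0,1)$ (contaminated normal). For $k > 2$ each
multi-group block shares one zero-mean normal prior with the shared
precision $\tau_{\mu 12}$ and each singleton block for group $s$ uses
$\tau_{\mu s}$; this is the minimal generalization of the two-group prior
and is our choice, not something the two-group formulation dictates.

## Posterior computation

`run_chains()` is a Metropolis-within-Gibbs sampler (C++ core). Per sweep:

1. **Patterns and means, collapsed.** Each gene's pattern indicator is
   drawn from its full conditional with the block means integrated out
   analytically — the pattern marginal likelihood is a product of
   conjugate Gaussian block factors
   $\sqrt{\tau_B/(\tau_B + A_B)}\exp\{C_B^2 / 2(\tau_B + A_B)\}$ with
   $A_B = \tau_{\varepsilon i}\sum_B u$, $C_B = \tau_{\varepsilon
   i}\sum_B u\,y$. Means are then drawn from their Gaussian full
   conditionals. Collapsing avoids the near-absorbing states that plague
   naive spike-slab samplers, in which a gene cannot leave the spike until
   an independently drawn slab mean happens to land near its data.
2. **Latent scales.** $u_{isr}$ has kernel $u^{1/2}e^{-u\tau e^2/2}
   g(u;\nu)$: gamma for t, truncated gamma on $(0,1)$ for slash
   (rejection samplers with a log-space inverse-cdf fallback — exact in
   all regimes), a two-point draw for the contaminated normal, and an
   inverse-Gaussian for the Laplace (sampled by the Michael–Schucany–Haas
   method in its cancellation-free larger-root form).
3. **Precisions.** Conjugate gamma updates for $\tau_{\varepsilon i}$ and
   for each mean-prior precision, pooled over the block means currently
   assigned to it.
4. **Shapes.** Conjugate gamma updates for slash and Laplace; for the t
   degrees of freedom a Gaussian random walk on $\log v$ (step 0.5, no
   adaptation) against the $U(0,100)$ prior; for the contaminated normal
   $\lambda_i \sim \mathrm{Beta}(1+m_i, 1+n_i-m_i)$ with $m_i$ the count
   of contaminated draws and $\gamma_i$ from its truncated-gamma
   conditional, after which the contaminated $u$ entries are refreshed to
   the new $\gamma_i$ (the latent variable is really the contamination
   indicator, $u = \gamma^b$).
5. **Mixing probabilities.** Dirichlet posterior from pattern counts.

Chains are deterministic given the seed (chain $c$ seeds the R RNG with
`seed + c`). Initialization: group sample means (jittered $N(0, 0.1^2)$
for chains beyond the first), $u \equiv 1$, inverse pooled residual
variances for $\tau_{\varepsilon i}$ floored at $10^{-8}$ and capped at
$10^8$ so zero-variance genes cannot produce infinite precisions, the
all-equal pattern for every gene, uniform mixing probabilities, and
family-default shapes (t: 5, slash: 2, CN: (0.5, 0.5), Laplace: 1).
Defaults are two chains of 20,000 iterations with 15,000 burn-in for real
data; the simulation driver uses single 15,000/10,000 chains. Convergence
is monitored by the Gelman–Rubin $\hat R$ on the DE proportion, a random
1% of the $\tau_{\varepsilon i}$, and the conditional deviance; $\hat R >
1.1$ warns rather than fails, since in a screening context a mildly
under-converged chain is information the analyst should see, not a fatal
error.

### Validation strategy

Correctness of every full conditional is established two ways, both in the
test suite: one-gene pattern probabilities agree with brute-force
quadrature to $10^{-8}$, and each scale kernel's draws pass
Kolmogorov–Smirnov tests against quadrature-normalized kernels. The whole
transition operator is then checked by successive-conditional (Geweke-style)
simulation: alternating a posterior sweep with an exact redraw of the data
must preserve the prior marginals of $\tau_{\varepsilon i}$ and the mixing
probabilities. Two practical notes. First, distribution tests on a Markov
chain require thinning until the trace decorrelates; untreated
autocorrelation shows up as spurious KS failures. Second, we run this test
under a $\Gamma(1,1)$ precision hyperprior: under the $\Gamma(1, 0.005)$
default the prior-predictive data are so informative (precisions near 200)
that pattern indicators almost never flip and no feasible run length
decorrelates the mixing-probability trace. The property being tested holds
for any hyperprior value, and the code path exercised is identical.

## Decision rules

With $\pi_i$ the posterior DE probability (fraction of retained draws, all
chains pooled, in which gene $i$'s pattern is not the all-equal one),
calls are $r_i = I(\pi_i > \kappa)$ and the Bayesian rates weight genes by
their posterior class probabilities:

$$\mathrm{bFPR} = \frac{\sum (1-\pi_i) r_i}{\sum (1-\pi_i)}, \quad
  \mathrm{bTPR} = \frac{\sum \pi_i r_i}{\sum \pi_i}, \quad
  \mathrm{bFDR} = \frac{\sum (1-\pi_i) r_i}{\sum r_i},$$

with $\mathrm{bTNR} = 1-\mathrm{bFPR}$, $\mathrm{bFNR} = 1-\mathrm{bTPR}$;
an empty call set reports bFDR as 0 with a flag. bFDR is the
posterior-expected false-discovery proportion — the standard Bayesian FDR
companion to these rates, and the definition consistent with published
decision tables in which bTNR and bFNR do not sum to one. Two ROC notions
coexist and are deliberately distinct: `roc_auc()` weights by the
posterior itself (usable on real data, where truth is unknown), while
`truth_roc_auc()` is the frequentist Mann–Whitney area against known
labels (used by the simulation studies). The posterior-weighted curve is
evaluated on the grid $\{0, \text{each distinct } \pi_i, 1\}$ with both
endpoints appended (calls are strict, so $\kappa = 0$ does not call
$\pi_i = 0$ genes) and integrated by trapezoid; identical probabilities
give a flagged degenerate curve with AUC 0.5.

## The synthetic-data generator

`simulation_config()`/`generate_dataset()` emulate a two-group spotted
study: $N = 1000$ genes, groups of 27 and 11 replicates, baseline location
14 (log scale), unit error variance, and errors from a chosen N/I member —
contaminated normal with $\lambda = 0.1$ and $\gamma \in \{0.10, 0.25\}$,
or t with 2 df. Exactly $\mathrm{round}(N \times 0.05)$ genes, redrawn
each replication, have their group-1 location shifted by $\delta \in
\{3, 5\}$; the exact count (rather than Bernoulli thinning) keeps the
$N p$ and $N(1-p)$ denominators of the per-replication TPR/FPR exact. Per
replication $k$: $\mathrm{TPR}_k$, $\mathrm{FPR}_k$, $\mathrm{TDR}_k$
(undefined and excluded, with a count, when nothing is called) at the
$\pi_i > 0.5$ rule, and $\mathrm{AUC}_k$ against the truth; all averaged
over $M$ replications with Monte-Carlo standard errors.

What the generator does *not* emulate: normalization artifacts, probe
effects, correlated genes, batch structure, or intensity-dependent
variance. Passing simulation tests therefore demonstrates correct recovery
under the model's own sampling assumptions (plus misspecification across
N/I members), not robustness to everything real arrays do.

The acceptance/test runs use a reduced scale — $N = 300$, $M = 10$, 6,000
iterations with 4,000 burn-in, one chain per fit (about 0.5–7 s per
replication and family on one core) — chosen as the smallest design whose
Monte-Carlo standard errors on TPR and AUC are a few hundredths, i.e.
small against the tolerances used to compare against published values.
The monotonicity suite uses $N = 150$, $M = 4$, 3,000/2,000 for the same
reason.

## Numerical choices

* Truncated $\Gamma(a,b)$ on $(0,1)$ (slash scales, CN $\gamma_i$): three
  exact rejection regimes — Beta$(a,1)$ proposal accepted with $e^{-bu}$
  when $b \le 2$; rejection from the untruncated gamma when enough mass
  lies below 1; an exponential-tilt envelope from $\log u \le u - 1$ when
  the mode sits above 1 — with a log-space inverse cdf as the fallback.
  The log-space form matters: at slash exponents in the hundreds,
  $P(X < 1)$ underflows linear-scale arithmetic entirely.
* Inverse-Gaussian draws use the larger Michael–Schucany–Haas root plus
  $x_1 x_2 = \mu^2$; the textbook smaller-root formula cancels
  catastrophically when $\mu y \gg \lambda$, which Laplace fits hit
  whenever a residual is tiny.
* Pattern weights are computed in log space with max-subtraction;
  degenerate residual/zero-variance cases are guarded by the
  $\tau$ floor/cap at initialization.
* The slash marginal density uses its incomplete-gamma closed form rather
  than quadrature (identical values, stable in the far tails).

## Design choices in open territory

* Shapes $\nu_i$ are per gene, following the subscripting of the model
  statement; pooling across genes would be a one-line change but is not
  exposed.
* The t-df proposal step (0.5 on the log scale) gives acceptance rates in
  the 0.3–0.7 range across our simulation regimes; persistent acceptance
  outside (0.05, 0.95) is logged as a tuning warning.
* DE genes are redrawn each replication (`redraw_de = FALSE` preserves the
  fixed-set alternative).
* The headline multi-group decision uses the global any-pair probability;
  pairwise probabilities are reported but not multiplicity-adjusted (no
  concrete adjustment is standard here; Bonferroni on pairwise calls is
  left to the analyst).

## Known limitations

* The posterior DE ranking is not a monotone transform of the two-sample
  $|t|$ ranking: strong genes saturate at $\pi_i = 1$, and the learned
  slab scales shrink genes adaptively, so rank agreement with $|t|$ plateaus
  around Spearman $\rho \approx 0.8$ on continuum-effect synthetic data.
  That is a feature of the model (evidence is weighed against the
  population of effect sizes), but worth knowing when comparing against
  t-test screens.
* Under the stated contaminated-normal simulation regimes with shifts of
  3–5 noise standard deviations and 38 samples, the per-gene evidence is
  strong enough that even the Gaussian fit attains high power in our
  implementation; the contrast among families is sharper under t(2)
  errors, whose variance is infinite. Conclusions about the normal model's
  fragility should therefore lean on the heavy-tailed generator.
* One gene's sweep is $O(\text{samples} \times \text{patterns})$; the
  pattern mixture over all set partitions restricts the implementation to
  $k \le 5$ groups.
* Missing values are rejected, not modeled; paired designs, covariates and
  dye-swap structures are out of scope.
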