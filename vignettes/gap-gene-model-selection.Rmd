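---
title: "Bayesian model selection for the gap gene network: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian model selection for the gap gene network: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapbayes)
```

## The model

The zygotic gap genes Hunchback (Hb), Kruppel (Kr), Knirps (Kni) and Giant
(Gt) form broad expression domains along the anterior-posterior (A-P) axis of
the early Drosophila embryo, activated by maternal gradients (Bicoid, Caudal,
maternal Hb, the terminal factor Tailless) and sharpened by mutual
repression.  `gapbayes` models each gap gene concentration $u_i(x,t)$ on the
unit interval as a reaction-diffusion equation

$$\partial_t u_i = \alpha\, P_i^A (1 - P_i^B) - \beta\, u_i
  + D\, \partial_x^2 u_i, \qquad u_i'(0,t) = u_i'(L,t) = 0,$$

integrated from cleavage cycle 14.1 (zygotic Hb initialized at the maternal
Hb profile, the others at zero; maternal/terminal inputs held constant) to
cycle 14.4 ($T = 1$ after nondimensionalization).

Regulation is fractional occupancy: a regulator at concentration $u$ with
log10 affinity $\log K_a$, cooperativity $C_o \ge 1$ and $N_s$ binding sites
occupies its sites with probability $S/(1+S)$, where
$S = \sum_{j=1}^{N_s} \binom{N_s}{j} C_o^{j-1} (u\,10^{\log K_a})^j$ is the
bound part of a single-locus partition function.  Multiple activators
(respectively repressors) combine by independence (noisy-OR):
$P^A = 1 - \prod_r (1 - \phi_r)$.  The dual action of Hb on Kr is represented
by the same partition function: the ordinary occupancy activates, while the
fully-bound configuration (weight $C_o^{N_s-1} v^{N_s}$) represses, so low
Hb activates Kr and saturating Hb shuts it off.  The exact occupancy algebra
behind the published model lives in supplementary material we do not
reproduce; both the occupancy and the combination rule are isolated behind
`site_occupancy()` / `regulatory_input()` so either can be swapped without
touching the solver or samplers.

Observations are the solver output plus iid Gaussian noise,
$Y_i = U_i(x,T) + \varepsilon$, $\varepsilon \sim N(0, \sigma^2 I)$, with the
likelihood restricted to per-gene trust domains (Hb 30-70, Kni 40-90, Kr
20-80, Gt 10-90 % egg length, boundaries inclusive).

### The six variants

All four gap genes share $\alpha$, $\beta$, $C_o$, $N_s$, $D$ and a global
affinity $K$; variants differ in which regulatory edges get their own
affinity.  A6 is the base model (6 free parameters: K, K1, Co, Ns, alpha, D,
with K1 the Hb-as-repressor affinity that A6 also assigns to
Kr-as-repressor).  B7 gives Kr-as-repressor its own K2; B7r instead gives
Bicoid-as-activator its own K3; C8 has both; D7 and D8 add a Bcd -> Kr
activation edge to B7 and C8.  Free-parameter counts: 6, 7, 7, 8, 7, 8.
The network topology is shipped as a YAML data file
(`system.file("extdata", "gap_topology.yaml", package = "gapbayes")`), so
edges can be corrected against other sources without code changes.  The
targets of the Bicoid-as-repressor and Hb-as-activator edge classes are not
fully pinned down by the published table; the default topology omits them,
and adding such edges to the YAML makes them resolve to the global K.

### Synthesis/decay: one open parameter

The published parameter table counts synthesis and decay as a single open
parameter and fixes the maximum concentration at 50.  Tying them as
$\alpha = \beta$ would cap the steady state $\alpha P / \beta$ at 1,
irreconcilable with concentrations of order 50 and a noise sd of 5.  We
therefore tie them through the fixed maximum concentration:
$\beta = \alpha / u_{\max}$, so the saturated steady state is exactly
$u_{\max} = 50$ and there is still exactly one open synthesis/decay
parameter.  `gap_params(beta = ...)` decouples them if desired.

## Solver

The linear part $D\Delta_N - \beta I$ is stiff; we integrate by exponential
Euler (a semigroup / variation-of-constants scheme): per step,
$u \leftarrow e^{\Delta t A} u + \Delta t\,\varphi_1(\Delta t A) f(u)$ with
the production field $f$ frozen at the current state.  The zero-flux
Laplacian on a *cell-centred* grid ($x_i = (i - \tfrac12)L/n$) is
diagonalized exactly by the DCT-II cosine modes with eigenvalues
$-(2/\Delta x^2)(1 - \cos(k\pi/n))$, so the linear propagation is exact and
unconditionally stable, and when $f$ is state-independent the scheme is the
exact solution (this is tested against an independent eigendecomposition).
The cell-centred choice matters: vertex-centred one-sided Neumann rows are
only first-order accurate at the boundary and distort the slowest decay
rate by ~2% at n = 100, whereas the cell-centred operator's error is
$O(n^{-2})$ (~1e-4).  Percent-egg-length positions are therefore
$(i - \tfrac12) \cdot 100/n$.

Numerical choices: default $\Delta t = 10^{-3} T$ with automatic halving and
retry on blow-up (any $|u| > 10 u_{\max}$); persistent instability raises an
error naming the parameter values.  Negative undershoots from the explicit
nonlinear term are clipped to zero and counted (`$clipped`); the count is
zero in all nominal regimes exercised by the tests.  Observed
self-convergence order in $\Delta t$ exceeds 1.  The inner loop is compiled
(RcppArmadillo); a pure-R stepper (`rd_step()`) is kept as the audited
reference and the two paths agree to ~1e-13.

## Inference

The posterior kernel is $L(\theta,Y)^t\,\pi(\theta)$ with bounded uniform
priors.  Defaults (configuration, not code): log10 affinities on (-4, 0),
$C_o$ on (1, 10), $N_s$ uniform on the integers 1..10, $\alpha$ on
(0.01, 10), $D$ on (0, 1); $\sigma$ is a fixed configuration value
(default 5, i.e. 10% of the maximum concentration), not sampled.

The Metropolis-Hastings proposal is mixed: with probability 1/10 the
discrete site count moves by $\pm 1$ (equal probability; boundary proposals
are rejected by the prior, which keeps the proposal symmetric), otherwise
all continuous coordinates receive independent Gaussian increments of
variance 0.1 on their working scale.  The published text says "probability
p < 1/10"; we read this as the fixed mixture weight p = 1/10 and expose it
(`p_ns`).

Parallel tempering runs one chain per temperature on the exponential ladder
$t_i = (i/N)^5$, $i = 1..N$ (default N = 10), alternating one MH sweep with
one exchange sweep of N proposed swaps.  A swap of chains $i$ and $j = i \pm
1$ is accepted with probability $\min\{1, \exp[(t_i - t_j)(\log L_j - \log
L_i)]\}$.  The pair-selection Hastings factor is exactly 1 — the probability
of proposing a given index pair depends only on the indices, which the swap
does not change — so no correction for the edge chains' deterministic
neighbour choice is needed.  Chains are initialized from the prior;
the posterior is read from the $t = 1$ (untempered) chain.  (The published
algorithm says "lowest temperature"; with likelihood tempering the $t = 1$
chain is the target chain, and the printed acceptance ratio and ladder are
only consistent with that reading.)  Burn-in defaults to 50% with no
thinning; both are configuration values.

## Evidence and Bayes factors

Thermodynamic integration: $\log p(Y) = \int_0^1 E_t[\log L]\,dt$,
approximated by trapezoid quadrature over the ladder.  The sampled ladder
starts at $10^{-5}$, not 0; by default we prepend the $t = 0$ node with
$E_0$ estimated from cheap prior draws (no MCMC needed), because $E_t$ can
be steep near 0.  `augment_zero = FALSE` reproduces the nodes-only variant.
`estimate_evidence()` repeats the whole run (default 10 times) with distinct
seeds; the reported `se` is the run-to-run standard deviation.  On a
conjugate-Gaussian toy with an analytic evidence, the estimator is unbiased
within the run spread and the residual trapezoid bias of the N = 10 ladder
is ~0.04 nats (covered by the test tolerance).

Bayes factors are differences of log evidences; $2\ln B$ is categorized by
the Kass-Raftery bands, implemented left-closed: [0,2) not worth more than a
bare mention, [2,6) substantial, [6,10) strong, [10, Inf) very strong.
Negative values are classified by magnitude and reported as favouring the
other model.

## Convergence and over-fitting checks

Convergence is monitored on the scalar log-likelihood traces (parameter
posteriors are confounded — notably binding-site count against affinity —
which makes per-parameter diagnostics misleading).  `gelman_rubin()` is the
classic PSRF with the (m+1)/m sampling-variability correction (the
uncorrected value is attached as an attribute); `shrink_evolution()`
recomputes it on the first 50 samples and then bins of 10, flagging where R
settles below 1.2.

`sequential_cv()` implements the spatially structured cross-validation:
training sets grow from the anterior-most 60% of positions per gene in 5%
steps (8 folds on 100 positions, test bins tiling 60-100% exactly;
orientation flippable), each fold refits by PT-MCMC on the training
positions intersected with the trust domains, draws 100 posterior samples,
and scores the next 5% by mean predictive log density per point.  The fold
means are compared with the per-draw predictive means of a full-data fit by
a Welch t-test; p > 0.05 indicates no over-fitting.  Whether the original
analysis refitted the full sampler per fold is not stated; we refit with a
configurable (reduced) iteration count.

## The synthetic-data generator

`maternal_inputs()` builds FlyEx-like static profiles on a 100-point grid
scaled to a maximum of 50: an exponential anterior Bicoid gradient (decay
length 0.2 embryo lengths), a posterior Caudal sigmoid, an anterior maternal
Hb step, and two terminal Tailless domains.  Whether Caudal was an input to
the original fits alongside Tailless is ambiguous in the source; we include
it, matching the network diagram.  `simulate_dataset()` adds iid
$N(0, \sigma^2)$ noise, reproducibly from a seed, and round-trips through
the `gene,position_percent_el,value` CSV format.

The default ground truth is mid-prior with two deliberate exceptions, chosen
once and not revisited: the node-specific Bicoid affinity K3 sits one log10
unit above the global K (the contrast the ranking experiments probe), and
D = 0.05 rather than the prior midpoint 0.5, because a diffusion length
$\sqrt{DT} \approx 0.7$ embryo lengths erases all spatial pattern and the
generator is meant to emulate gap-gene geography (anterior Hb domain,
central Kr, posterior Kni).  What the generator does *not* emulate: image
processing artifacts of real FlyEx profiles, nucleus-level variability,
non-Gaussian or spatially correlated noise, and time-dependent inputs.  A
green test therefore establishes correctness of the machinery under the
stated statistical model, not fidelity to real embryos, and no test depends
on matching real FlyEx curves.

Within the stated world ($T = 1$, $\alpha \le 10$), purely zygotic genes
accumulate at most ~10 concentration units by gastrulation, so their
signal-to-noise against $\sigma = 5$ is modest; Hb, seeded by its maternal
profile, carries most of the information.  This is a property of the
nondimensionalized defaults, not of the method.

## Scale of the shipped experiments

The test suite runs everything at reduced scale — 32-point grids, solver
step $10^{-2}$ inside likelihoods, hundreds-to-thousands of PT iterations,
single evidence runs per replicate in the ranking experiment — to stay
within a CI budget; the defaults embedded in the functions are the
full-scale published settings (100 points, N = 10 ladder, 10 evidence runs,
100 posterior draws).  Headline numbers from the original real-data analysis
(absolute evidence values, CV means) are not reproduced: they depend on the
FlyEx profiles, which this package deliberately does not download.

## Known limitations

One-dimensional geometry only; no nuclear divisions between cleavage-cycle
time classes; a single shared noise sd across genes (per-gene sd via
configuration); no adaptive proposal tuning or HMC (the discrete site count
rules out plain HMC); the exact occupancy algebra of the published
supplement may differ in detail from the partition-function default, which
is why it is pluggable.
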