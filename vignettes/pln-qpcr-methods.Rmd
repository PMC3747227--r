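---
title: "Poisson-lognormal mixed models for qRT-PCR: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Poisson-lognormal mixed models for qRT-PCR: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plnqpcr)
```

This vignette is the package's own account of the statistics it
implements: the observation model and its hierarchy, how Cq values become
counts, what the priors mean, how the sampler works and why it is built
the way it is, what the synthetic-data generator does and does not
emulate, and the known limitations a user should keep in mind.

## From quantification cycles to counts

qPCR reports the cycle `Cq` at which fluorescence crosses a threshold.
Under exponential amplification with per-cycle efficiency `E`
(`1 < E <= 2.2`; `E = 2` is perfect doubling), a reaction that started
from `n` molecules crosses the threshold `log_E(n)` cycles earlier than a
reaction started from one molecule, so

```
count = round( E^(Cq1 - Cq) ),
```

where `Cq1` is the quantification cycle of a single molecule.
`cq_to_counts()` applies this with three policies for `Cq1`:

* `uniform` (default, 37 cycles for every gene): the simplest choice, and
  empirically the inference is nearly insensitive to it except for
  zero-bounded genes;
* `empirical`: the linear calibration `Cq1 = 79 - 21.5 E`, which pins
  `Cq1 = 36` at `E = 2` (`estimate_cq1()`; the idealized
  single-efficiency model `36 log 2 / log E` is also available);
* `per_gene`: measured values supplied in the efficiency table.

Two deterministic rules matter. Detected trials are clamped to a count of
at least 1 — an observed amplification implies at least one template
molecule, and without the clamp high-Cq detections would alias with true
zeros. Failed amplifications (the `"ND"` token in input tables) become
counts of exactly 0, which the Poisson likelihood treats as data; empty
cells mean *not measured* and are dropped. Keeping these two states
distinct is essential: one is an observation, the other is missingness.

The log-scale route (`cq_to_log_abundance()`) computes
`la = -Cq * log(E)`, the natural-log relative abundance up to a per-gene
additive constant (the constant would be `Cq1 * log(E)`; every downstream
use — normalization, within-gene contrasts, treatment effects — is
invariant to per-gene constants, so it is omitted), plus the
efficiency-corrected cycle count `Cq * log2(E)`.

## The model

With subscripts g = gene, i = treatment combination, j = grouping level,
k = biological sample, r = technical replicate:

```
y_gijkr ~ Poisson(lambda),   log lambda = I_g + B_ig + t_k + a_jg + s_kg + e_gijkr,
e_gijkr ~ N(0, v_g)
```

Marginally over `e` each count is Poisson-lognormal with mean
`mu = exp(eta + v/2)` and variance `mu + mu^2 (exp(v) - 1)`: Poisson in
the limit `v -> 0`, overdispersed otherwise. This is the right
mean-variance family for PCR: at low abundance the Poisson term dominates
(shot noise), at high abundance the lognormal term does (pipetting,
chemistry).

* `I_g` — baseline log abundance of gene g at the reference combination
  of the fixed factors (default reference: lexicographically first level
  of each factor, overridable).
* `B_ig` — gene-specific fixed effects under treatment (dummy) coding:
  one coefficient per gene per non-reference factor level and per
  declared interaction cell. These are natural-log fold changes.
* `t_k` — the loading effect: samples differ in cDNA quantity/quality in
  a way that multiplies *all* genes, so one random effect per sample,
  shared across genes, with a single variance. This term is why the model
  needs no normalization step. (The description of this term's variance
  structure is genuinely ambiguous between "one variance" and
  "gene-linked"; a shared scalar variance is used here, since a
  gene-specific variance on a gene-shared effect is not meaningful.)
* `a_jg` — gene-specific random effects of grouping factors (genotype,
  block, ...), one variance per gene per factor.
* `s_kg` — gene-specific sample effect with per-gene variance. Its
  variance is separable from the residual only when technical replicates
  exist; `build_design()` detects replicate structure and drops the block
  otherwise, merging the variation into `e`.
* `v_g` — gene-specific residual (technical) log-variance by default; a
  single shared variance is available (`gene_specific_residual = FALSE`)
  and is also what the scale-location diagnostic is good at auditing.

## Priors and the control-gene regimes

Fixed effects get independent N(0, 1e8) priors — operationally flat.
Designated control genes' treatment effects instead get N(0, sigma_c^2),
where the stability parameter `m >= 1` states "controls may vary m-fold
on average across conditions". "On average" is made precise as the prior
mean absolute log fold change: `E|B| = log(m)` for a centered normal
gives `sigma_c = log(m) * sqrt(pi/2)` (about 0.229 at the default
m = 1.2). The alternative reading `sigma_c = log(m)` is selectable
(`stability_scale = "sd"`); the two differ by ~25% in sigma and are
indistinguishable in practice at m near 1. The regimes:

* **naive** — no control genes; all effects diffuse;
* **informed** — controls shrunk by the stability prior;
* **fixed** — `fix_control_fixed_effects = TRUE`, variance 1e-6:
  controls pinned to perfect stability (unrealistic in gene expression,
  but exactly right when the "control" is, e.g., host DNA against which a
  pathogen is quantified);
* optionally, `fix_control_variances = v` also pins the controls'
  grouping and sample variance components.

Variance components get inverse-gamma(1e-3, 1e-3) priors — proper but
near-flat, so their posteriors track the likelihood (approximately the
ML estimates) while guaranteeing a proper joint posterior; truly improper
flat priors are deliberately not offered. Sampled variances are floored
at 1e-10 for numerical safety.

## The sampler

There is no closed-form Poisson-lognormal density, so the model is fitted
in its augmented hierarchical form: each observation carries a latent
log-rate `psi_i ~ N(eta_i, v_g(i))` and `y_i ~ Poisson(exp(psi_i))`.
One MCMC iteration is:

1. **Latents.** Each `psi_i` has an independent conditional, so a full
   vectorized random-walk Metropolis sweep updates all of them at once
   (two sweeps per iteration). Proposal SDs are tuned per observation by
   Robbins-Monro toward 44% acceptance during burn-in only, preserving
   detailed balance afterwards.
2. **All location effects jointly.** Given `psi` the model is
   linear-Gaussian, and beta and *all* random-effect blocks are drawn in
   one Gaussian block from the sparse mixed-model (Henderson) equations,
   using a sparse Cholesky factorization whose symbolic analysis is
   reused across iterations. This is the one place the implementation
   deliberately departs from textbook per-block Gibbs: the loading
   effects `t_k` are strongly posterior-correlated with the
   gene-by-treatment effects (they compete to explain condition-level
   shifts), and updating them in separate blocks mixes catastrophically
   slowly — effective sample sizes below 20 on the standard preset,
   versus several hundred with the joint update, at similar cost.
3. **Variance components.** Conjugate inverse-gamma updates from the
   random-effect sums of squares and the latent residuals; components
   declared fixed are skipped.

The Gaussian (lognormal) family sets `psi` equal to the observed log
abundance and skips step 1, leaving a fully conjugate Gibbs sampler.

Defaults `nitt = 13000, burnin = 3000, thin = 10` retain M = 1000 draws —
the natural scale for tail-area p-values with a 2/M floor. Initialization
is least squares of `log(y + 0.5)` on the fixed design, latents at the
data, variances at 1. Runs are bitwise reproducible under a fixed seed.
`fit_pln_glmm()` reports effective sample sizes (via coda) and warns
below 100; zero-count-heavy parameters mix slowest and are the usual
subjects of such warnings. A known hard regime: residual variances fixed
at extremely small values glue the latents to the linear predictor and
slow the shared random walk — not a practical setting, but worth knowing.

## Inference outputs

For every (gene, term): the posterior mean; a 95% highest-posterior-
density interval (shortest interval at the given mass — quantile
intervals are selectable; for the near-symmetric posteriors here the two
rarely differ visibly); the tail-area p-value `p_mcmc = max(2k/M, 2/M)`
(k = draws across zero from the mean); the z-test p-value from
mean/SD against a standard normal, which can resolve below the 2/M
floor and agrees with `p_mcmc` on approximately normal posteriors; and
Benjamini-Hochberg adjusted `p_z`. The FDR family is all treatment-effect
tests of one fit; intercepts are reported without adjusted p-values
(baseline abundance is not a null hypothesis), and contrasts are adjusted
within their own family. `pairwise_contrasts()` and
`predict_abundances()` assemble draw-wise linear combinations of the
fixed effects for arbitrary factor combinations, so factors with more
than two levels can be compared directly.

## The classic model

`fit_classic()` reproduces the traditional pipeline as a single Bayesian
model: per (sample, technical replicate) trial group, subtract the mean
control-gene log abundance (= division by their geometric mean), then fit
the lognormal GLMM *without* `t_k` — normalization already removed
loading, including technical-replicate loading noise, which is why
normalization is per trial group rather than per sample. Control genes
stay in the fit with diffuse priors; their estimated "effects" should
hover near zero and act as sanity indicators (shrinking them with the
stability prior would defeat that purpose, so classic mode does not).
No-amplification trials cannot enter a log-scale model and are dropped
with a warning — if you have many of them, the count model is the right
tool. The classic route is the remedy of choice when loading varies
*systematically* with condition: the count models must attribute a
condition-correlated loading shift to biology, the normalized model
subtracts it (both behaviours are verified in the test suite).

## What self-normalization can and cannot do

The loading block makes the count models self-normalizing for anything
*exchangeable* across samples, but one caveat is structural and worth
stating precisely. Within a factor cell of m samples, the cell-mean of
`t_k` is not identified against the gene-specific fixed effects: adding
delta to every gene's effect for that cell and subtracting delta from its
samples' `t_k` leaves the likelihood unchanged. The prior resolves the
ridge, and the algebra gives an exact answer: perturbing one sample by
delta moves the affected fixed effects by delta/m (we confirmed the same
delta/m to four decimals in REML fits of the equivalent Gaussian model).
So a 15% pipetting error on one of eight samples moves fold-change
estimates by under 2% on the log scale — invisible next to Monte-Carlo
error — while a 4-fold error moves them by log(4)/8 ≈ 0.17. The
posterior *intervals* already carry this uncertainty (the ridge inflates
them); only the point estimates shift. Condition-correlated loading is
the m-samples-at-once version of the same arithmetic, which is why it
needs controls (informed/fixed/classic) rather than self-normalization.

## Diagnostics

`compute_diagnostics()` (requires `retain_latents = TRUE`) returns one
bundle with four checks: lognormal residuals (`log(y + 0.5) - eta`,
standardized by the gene residual SD) against predictions (linearity);
sqrt-absolute standardized residuals against predictions with a fitted
trend slope and its p-value (homoscedasticity — sensitive, e.g., to
forcing a shared residual variance onto heteroscedastic genes);
a normal QQ of the standardized residuals; and, for count fits,
randomized probability-integral-transform values
`F(y-1; lambda) + U f(y; lambda)` of each count under its sampled
Poisson rate for one retained draw, paired with uniform quantiles. Under
a correct model the PIT values are exactly uniform; their uniformity on
real data is the direct check that low-abundance variance inflation is
Poisson shot noise and nothing else. The cited construction for "Poisson
residual probabilities" is under-specified in the literature this
follows; the randomized-PIT reading reproduces the intended behaviour
(uniform under the model, draw-conditional) and is the standard modern
tool for count residuals. The `log(y + 0.5)` proxy is zero-safe and only
used for residual displays, never for fitting.

## The synthetic-data generator

`simulate_dataset()` draws every term of the hierarchy from a declared
`simulation_truth` and back-converts counts to Cq through the same
amplification model the converter inverts (integer counts round-trip
exactly; zeros become no-amplification trials). `coral_truth()` is the
standard preset: a 2x2 factorial (condition x timepoint, with
interaction) over 8 genotype groups, one sample per cell per group
(32 samples), 2 technical replicates, 15 genes with baselines
log-spaced from 5 to 5000 molecules so that the lowest genes are
zero-bounded, two mid-abundance genes designated as stable controls,
E = 2 and Cq1 = 37 throughout. Dispersion defaults, chosen once as
realistic for a protocol that equalizes cDNA input across samples:
loading SD 0.3 (samples typically within ~35% of each other, 2-fold at
the extreme), grouping SD 0.3, sample SD 0.2, residual log-variance 0.04
(about a quarter-cycle of technical scatter).

What the generator does **not** emulate: efficiency mis-estimation (the
truth's E is also the converter's E), inhibition and other
amplification-curve pathologies, plate/batch layout effects, primer-dimer
artefacts at high Cq, and between-run calibration drift. Passing tests
therefore demonstrate correctness of the inference machinery under the
model's own assumptions — not robustness to assay pathologies, which on
real data should be audited with the diagnostics bundle.

`make_null_dataset()` implements subtract-and-shuffle: efficiency-correct
the Cq values to the `E = 2` scale, remove each trial's inferred fixed
effects (posterior means divided by log 2 to convert natural-log effects
to cycles), then permute whole samples across the observed factor
combinations. Refitting such datasets probes the null distribution of the
p-values; the test suite runs 20 shuffles x 18 tests and checks the
fraction of `p_z < 0.05` against the exact binomial band around 0.05.

## Problem sizes and numerical choices

The validation suite runs entirely on seeded simulations regenerated at
test time: the coral preset (960 observations, 60 fixed effects,
~650 random effects) fitted with chains of 8000 iterations (M = 1000)
for the recovery/power checks, three replicate datasets per regime; a
6-gene, 192-observation design with 20 null shuffles for calibration;
and assorted smaller fixtures. Fold-change recovery is asserted as a
replicated parameter-recovery design (truth inside the 95% HPD in at
least 2 of 3 replicates, null coverage pooled across replicates) — with
a single simulated dataset the assertion would be a coin-flip on the
~5% of realizations where an interval legitimately misses.

Numerical details that matter: the joint location update uses one
symbolic sparse Cholesky analysis reused with `Matrix::update()`;
Metropolis proposals that overflow `exp()` are rejected naturally via
`-Inf` log-ratios; variance draws are floored at 1e-10; the latent
proxy for initialization is `log(y + 0.5)`; ties in factor levels are
broken lexicographically when choosing reference levels; and the
(sample, gene) block is silently merged into the residual when no
technical replicates exist, since the two are then indistinguishable.

## Limitations

* Point estimates under the count models absorb condition-correlated
  loading (see above); use controls or the classic route when that risk
  is real.
* Interval estimates for variance components are only as good as the
  replication at their level; with 8 grouping levels they are
  order-of-magnitude statements.
* The model assumes the efficiency table is right; it propagates no
  uncertainty in E or Cq1 (mis-set Cq1 mainly perturbs zero-bounded
  genes).
* Bayesian model selection across fixed-effect structures is out of
  scope; the z-test/FDR machinery is an intentionally frequentist-shaped
  summary of posterior evidence.
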