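---
title: "Component groups from IgE sensitization profiles: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Component groups from IgE sensitization profiles: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igegroup)
```

## The scientific problem

Component-resolved diagnostics measure specific IgE to individual allergenic
proteins rather than whole-extract mixtures. On a chip of ~112 components a
child's profile is a long binary (or graded) vector, and the analytical
questions are: do components cluster into groups that children tend to be
jointly sensitized to; how strongly does each child belong to each group;
and do the groups differ in their association with asthma, hay fever,
eczema and lung function? This package implements that analysis as a
reusable, fully tested pipeline, together with a synthetic-cohort generator
that stands in for the non-public cohort data.

## Generative model

For children $i=1..N$, components $j=1..J$, clusters $k=1..K$:

$$\pi \sim \mathrm{Dir}(\alpha), \quad z_j \sim \mathrm{Cat}(\pi), \quad
\theta_k \sim \mathrm{Beta}(a_\theta, b_\theta), \quad
s_{ik} \sim \mathrm{Bern}(\theta_k)$$
$$x_{ij} \mid z_j = k \sim \mathrm{Bern}\!\left(p^{+}_j\ \text{if}\
s_{ik}=1\ \text{else}\ p^{-}_j\right), \quad
p^{+}_j \sim \mathrm{Beta}(a_p, b_p), \quad p^{-}_j \sim \mathrm{Beta}(a_n, b_n).$$

The published analysis describes its model only at the level of intent —
clusters of components to which children respond jointly — so the
parameterization here is this package's own reconstruction: the minimal
structure in which "a child is (or is not) sensitized to a cluster" is an
explicit latent variable, yielding exactly the two posterior summaries the
analysis consumes (component membership probabilities and child
sensitization probabilities). A quaternary emission variant replaces the two
Bernoullis with two 4-category Dirichlet-prior distributions over the ISU
classes, the sensitized one weighted toward higher classes.

Two design choices were genuinely open and were settled by behaviour, not
taste:

* **Per-component emission rates (default) versus shared rates.** With a
  single shared $p^{+}, p^{-}$, a component whose few positives align with
  no cluster still must be placed somewhere, and the least-bad cluster is
  the one with the fewest sensitized children — it gets the component with
  membership near 1 and its sensitization posteriors get dragged down. With
  per-component rates under shared Beta priors, such a component's
  $p^{+}_j$ shrinks toward the background and its likelihood becomes almost
  cluster-agnostic. `emission_scope = "shared"` remains available.
* **A background ("noise") class** alongside the $K$ clusters: a class with
  no sensitized children, so its components are positive only at their
  $p^{-}_j$. Unpatterned components gravitate there and emerge as
  "non-CG" — the behaviour reported for 10 of 71 components in the study
  this emulates. Without it, every component is forced into some cluster no
  matter how poorly it fits. Controlled by `model_config(noise_class = )`.

## Inference

`fit_approximate()` runs coordinate-ascent mean-field variational Bayes
with conjugate updates for all factors; the evidence lower bound is
monotone within a restart (a tested invariant) and the best restart by
final objective is returned. Restarts alternate between a k-means seeding
of the component responsibilities and symmetric Dirichlet noise; the
k-means basins matter because, with a background class present, a purely
random start lets the background absorb small genuine clusters (in
development this happened in every run for the 7-component cluster) while
a k-means start separates them reliably. Convergence: relative objective
change below `tol` (1e-8) or `max_iter` (2000) iterations; non-convergence
is a warning carried in the result, never silent.

Mean-field factors are mode-seeking: where the true posterior is genuinely
ambiguous (membership near 0.5) the variational posterior commits to one
mode. For that reason the package also provides
`fit_approximate(method = "gibbs")` — a collapsed Gibbs sampler (child
sensitizations marginalized analytically, plus a Metropolis
label-permutation move so the chain can cross between permutation basins)
whose Rao-Blackwellized marginals converge to the exact ones. The sampler
is the method held to oracle accuracy against `fit_exact()` (total
variation ≤ 0.05 per latent variable on small identified instances); the
variational fit is held to the cohort-scale standard that matters for the
analysis: exact recovery of the planted hard clustering. When comparing
posteriors across runs, `align_labels()` resolves label switching by exact
search over the $K!$ permutations.

`fit_exact()` enumerates the $K^J$ component assignments and marginalizes
$s$ analytically (so the cost is $K^J$, not $K^J 2^{NK}$), either at fixed
parameters or integrating the conjugate priors; it refuses instances beyond
$J \le 10$, $N \le 10$, $K \le 3$. Note that under exchangeable priors the
exact *marginal* memberships are uniform by label symmetry — oracle
comparisons therefore use asymmetric fixed parameters, and tests of the
integrated mode check closed forms and evidence ordering instead of
memberships.

## Thresholds and reporting conventions

* Component assignment: maximum membership **strictly greater than 0.7**,
  else non-CG.
* Child sensitization call: score **≥ 0.5** (the at-least convention; the
  comparator is an argument, and the difference is measure-zero in
  practice).
* ISU discretization: half-open bins $[0,0.3), [0.3,1), [1,15), [15,\infty)$
  so that "< 0.3 is negative" is exact and the bins are disjoint; 0.3 is
  "low", 1.0 is "medium", 15.0 is "high".
* Canonical cluster labels: clusters sorted by descending number of
  hard-assigned components, ties by smallest component index. Labels are
  arbitrary in a mixture; this just fixes them reproducibly. With the
  default synthetic sizes (27/7/27) the small mite-like cluster is
  therefore printed last (CG3 in fitted output), regardless of the
  generator's own cluster numbering — compare via `align_labels()` or the
  truth sidecar, not by name.
* Stability: subjects resampled **without replacement** (20 subsets of 200
  by default), the ≥ 3-positives component filter re-applied within each
  subset, and pair denominators count only the runs where both components
  survived; two components co-assign only when they carry the same CG
  label (non-CG never co-assigns).
* Dose-response slope: percent FEV1 fall at the last methacholine dose
  divided by cumulative dose in mg — the cohort's exact formula is not
  published, so a standard convention is used and exposed as raw fields
  plus a derived column.

## The synthetic cohort

`generator_config()` encodes the study conditions: 461 children; clusters
of 27, 7 and 27 components (pollen-like, mite-like, diverse); 10 weak
components positive independently at rate 0.025 (enough positives to pass
the prevalence filter, no cluster alignment); 5 rare components at rate
0.0005 (expected positives ≪ 3, exercising the filter); emission rates
$p^{+} = 0.85$, $p^{-} = 0.001$. Sensitization prevalences: the diverse
cluster is fixed at 8.5% (the published prevalence of the
least-sensitized group), the mite-like cluster at 12%, and the pollen-like
cluster is **solved in closed form** so the expected fraction of children
with ≥ 1 positive equals 47.9% exactly (the published any-positive
fraction); the solved value is ≈ 0.112. A per-cell false-positive rate of
0.01 would alone make > 50% of children test positive somewhere on a
76-component chip, so the background rate is 0.001 — the published
any-positive fraction is the binding calibration constraint.

Binary outcomes are drawn from logistic models on the *true* latent
sensitizations with per-CG log odds ratios taken from the published
association table (hay fever 12.79/2.52/1.15 for CG1/CG2/CG3; asthma
1.61/3.60/8.20; wheeze 1.48/4.19/5.44; eczema 1.10/1.62/2.00) and
intercepts solved numerically so each outcome's expected prevalence matches
its target (asthma 12.5% as published; wheeze 20%, hay fever 16%, eczema
21% — plausible values for a population cohort of 11-year-olds, chosen once
since only the asthma prevalence is published). FEV1 % predicted is
normal (mean 98, SD 11) with a −6.8 point shift for the diverse cluster;
exhaled NO is log-normal with positive shifts for every cluster;
methacholine percent-fall is normal with a +9 shift for the mite cluster
(AHR = fall > 20%). Raw questionnaire fields are constructed so that
`derive_outcomes()` reproduces the simulated status exactly — in
particular, the wheeze question is shared between the wheeze outcome and
the asthma 2-of-3 rule, as in the questionnaire definitions.

Pseudo-ISU values are back-mapped from the quaternary categories by
sampling log-uniformly within each ISU bin, so the discretization code is
exercised nontrivially; about half of the true negatives are written as
exactly 0 ISU.

What the generator does **not** emulate: correlation between cluster
sensitizations (children acquire CGs independently here, whereas real
atopic children show strong positive dependence — the published
counts of children sensitized to 1/2/3 groups are not reproducible under
independence); protein-family structure and cross-reactivity mechanisms;
missing data (supported by the pipeline, absent by default); and
measurement drift. Passing recovery tests on these cohorts therefore shows
the pipeline recovers the structure it assumes at realistic size, noise and
effect strength — not that the model is correct for any particular real
cohort.

## Verification protocols and problem sizes

* Oracle equivalence: 25 instances with $N = J = 8$, $K = 2$, identified
  fixed parameters; Gibbs marginals vs exact enumeration, TV ≤ 0.05 per
  latent variable after label alignment.
* Clustering recovery: 20 cohorts at full scale (461 children → ~221 after
  filtering, 71 components); adjusted Rand index vs the planted partition
  ≥ 0.9 (observed: 1.0), weak components all non-CG, rare components all
  filtered, in at least 18 of 20 runs each.
* Odds-ratio recovery: the outcome regressions are fitted to the
  generator's ground-truth sensitization indicators across ≥ 500 cohorts
  and the median estimate compared to the configured odds ratio (within
  10%). This isolates the regression stage — by design the outcomes are
  generated from the true latents, so the regression recovery is
  well-defined independently of posterior estimation, which is validated
  separately by the clustering-recovery protocol.
* Continuous-effect recovery: mean estimated FEV1 difference for the
  shifted cluster over 200 cohorts, within ±0.5 points of −6.8.
* Calibration: any-positive fraction within 3 points of 47.9% and
  smallest-prevalence-cluster sensitization within 2 points of 8.5%,
  averaged over 200 cohorts.
* Deterministic identities: univariate logistic OR equals the 2×2
  cross-product ratio to 1e-6; the discretization boundary table is exact;
  the asthma rule is exact on all 8 input combinations; and the Wald test
  rejects at 5% ± 1% under 10,000 null replicates with uniform scores and a
  30%-prevalence outcome. (With rare binary exposures and ~58 events the
  Wald test is conservative, ~3.5% — a known small-sample property, which
  is why the calibration check uses a well-conditioned design.)

These sizes keep the full suite around two minutes on one CPU while leaving
every statistical check at its stated strength.

## Known limitations

* $K$ is fixed (default 3, as reported by the study this emulates); how the
  original analysis chose it is unstated. `compare_k()` offers a held-out
  predictive-likelihood comparison over candidate $K$, which prefers the
  planted value on test data, but no nonparametric prior is provided.
* The equivalence to the published Expectation-Propagation analysis is at
  the level of the posterior summaries and threshold semantics, not the
  message-passing schedule; the published factor graph details are not
  public.
* Mean-field memberships are overconfident near ambiguity; where calibrated
  uncertainty matters, use the Gibbs option.
* Logistic models use unadjusted CG scores only (the published analysis
  names no covariates); a covariate list can be supplied but defaults to
  none. No multiple-testing correction is applied, matching the source
  analysis.
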