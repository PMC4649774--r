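# igegroup

Latent component groups from component-resolved IgE sensitization profiles.

## What this package does

Multiplex arrays measure serum specific IgE to over a hundred individual
allergen components (proteins) at once, reported in ISAC standardized units
(ISU). Children are rarely sensitized to components independently: IgE
responses come in patterns, and the pattern — not just "atopic yes/no" —
carries the clinical signal. `igegroup` implements a Bayesian latent-variable
analysis that

1. discretizes raw ISU values on the manufacturer's scale
   (no < 0.3, low 0.3–1, medium 1–15, high > 15) and binarizes positivity at
   0.3 ISU;
2. filters to components recognized by ≥ 3 children and children with ≥ 1
   positive result;
3. clusters components into **component groups (CGs)** from the binary
   child × component matrix, scoring simultaneously each child's probability
   of being *sensitized* to each CG;
4. assigns a component to a CG when its posterior membership probability
   exceeds 0.7 (otherwise "non-CG") and calls a child sensitized to a CG
   when the posterior sensitization probability is ≥ 0.5;
5. quantifies robustness by repeating the analysis on random subsets of 200
   children and tabulating pairwise co-assignment;
6. relates CG sensitization to clinical outcomes — asthma, wheeze, hay
   fever, eczema (multivariate logistic regression with the three
   quantitative CG scores entered together), FEV1 % predicted, FEV1/FVC,
   airway hyperreactivity and exhaled NO (linear models on the binary CG
   calls, with estimated marginal means).

Because cohort data of this kind are not public, the package ships a
calibrated synthetic-cohort generator (`generator_config()`,
`generate_cohort()`) that reproduces the statistical structure of such a
study — 461 children, three latent clusters of 27/7/27 components plus weak
and rare components, ~47.9% any-positive prevalence, and outcome effects at
published odds ratios — so that every stage is testable end to end.

## The model

With children i = 1..N, components j = 1..J and clusters k = 1..K:

    pi ~ Dirichlet(alpha),      z_j ~ Categorical(pi)
    theta_k ~ Beta(a_t, b_t),   s_ik ~ Bernoulli(theta_k)
    p+_j ~ Beta(a_p, b_p),      p-_j ~ Beta(a_n, b_n)
    x_ij | z_j = k  ~  Bernoulli( p+_j if s_ik = 1 else p-_j )

`z` assigns each component to one cluster; `s` says which clusters each
child is sensitized to; a sensitized child is positive to a cluster's
components at a high per-component rate `p+_j`, an unsensitized child at a
low rate `p-_j`. A quaternary variant replaces the Bernoulli emissions with
4-category distributions over the ISU classes. Two model features matter in
practice and are on by default:

* **per-component emission rates** (shared Beta priors), so a component
  whose positives do not line up with any cluster's sensitized children can
  shrink toward the background rate rather than distort a cluster; and
* a **background ("noise") class** with no sensitized children, which
  absorbs such unpatterned components so they emerge as "non-CG".

Inference is by mean-field variational Bayes (`fit_approximate()`), with
k-means-seeded and random restarts, returning the J × K membership
posteriors and N × K sensitization posteriors. Two oracles validate it: an
exact enumerator for small instances (`fit_exact()`, which marginalizes `s`
analytically and enumerates the K^J assignments, fixed-parameter or fully
conjugate-integrated) and a collapsed Gibbs sampler with Rao-Blackwellized
marginals (`fit_approximate(method = "gibbs")`) whose marginals converge to
the exact ones.

## Worked example

The numbered scripts under `analysis/` run the whole study on a simulated
cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # cohort: 461 children x 76 components
Rscript analysis/02_prepare.R      # discretize, binarize, filter
Rscript analysis/03_fit_groups.R   # fit, assign CGs, score children
Rscript analysis/04_stability.R    # 20 subsets of 200 children
Rscript analysis/05_associations.R # outcome models
```

`02_prepare.R` reports that 71 of 76 components reach the ≥ 3-positives
filter (the 5 planted rare components are excluded) and 206 of 461 children
have any positive result. `03_fit_groups.R` then prints:

```
components per group: CG1=27, CG2=27, CG3=7, non-CG=10
memberships above 0.9 among assigned components: 61 of 61
children sensitized to 0/1/2/3 CGs: 340/108/12/1
```

i.e. the three planted clusters are recovered exactly, every assigned
component with membership > 0.9, and the 10 weak components end up non-CG.
(CG labels follow a canonical size ordering — largest cluster first — so the
small mite-like cluster is CG3 here.) `04_stability.R` reports mean pairwise
co-assignment of 1.000 within true clusters and 0.000 between them, and
`05_associations.R` prints the association table, e.g.

```
current_asthma    CG2 OR  10.21 ( 4.59- 22.74), p 1.3e-08
current_hayfever  CG1 OR  18.03 ( 8.68- 37.46), p 9e-15
```

and, for lung function, `CG2: -7.3 (-11.0 to -3.7), p 8.9e-05` (FEV1
% predicted, sensitized vs not, adjusted),

reproducing the qualitative pattern the generator encodes: the pollen-like
group drives hay fever, the diverse animal/plant group drives asthma and
lower lung function, and the mite-like group drives airway reactivity.
These single-cohort estimates scatter around the configured effects; the
acceptance script below measures the recovery over hundreds of replicates.

A single call runs everything on arbitrary input files:

```r
library(igegroup)
run_pipeline("isu.tsv", "outcomes.tsv", "catalog.tsv", out_dir = "out",
             seed = 1, stability = TRUE)
```

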