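---
title: "Coordinated gene expression networks: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinated gene expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgenet)
```

## The problem

Regional expression of immediate early genes (IEGs) such as *cfos* and
*arc* indexes recent neuronal activation. When the same panel of brain
regions is quantified in every subject of a treatment group, the
*intersubject correlation* of expression between two regions measures how
tightly their activation covaries across animals — coordinated gene
expression (CGE), an anatomical-resolution analogue of functional
connectivity. `cgenet` turns a subject-level expression table into
per-group correlation networks, finds their modular community structure,
and tests which edges a drug treatment changed relative to baseline.

The packaged default region registry covers 27 forebrain regions in five
anatomical groups (4 prefrontal cortical, 6 sensorimotor cortical, 6
striatal, 6 hippocampal/septal, 5 amygdalar/hypothalamic), each with a
fixed pseudoanatomical layout coordinate for rendering. The layout is an
arbitrary packaged constant — cortex along the top, striatum central,
hippocampus/septum left, amygdala/hypothalamus along the bottom — chosen
for legibility, not for quantitative meaning.

## The model, stage by stage

**Adjacency matrices.** For a group with $n$ subjects, the network is the
$27 \times 27$ matrix of pairwise Pearson correlations $r_{ij}$ of
expression across subjects. With the full factorial design (2 genes
$\times$ 2 ages $\times$ 6 treatments) this yields 24 matrices. Each
$r_{ij}$ carries a two-tailed p-value from the conventional test
$t = r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ degrees of freedom. The test form
is the package's explicit choice (two-tailed by default, one-tailed and
permutation references available): correlation thresholds quoted as
"p < 0.05" in this literature almost universally refer to this t test.
Subjects missing any region are dropped listwise so each network has a
single $n$; pairwise-complete correlation is deliberately not offered
because the downstream Fisher comparison assumes one $n$ per network.

**Thresholding.** Edges with $p \ge \alpha$ (default $\alpha = 0.05$) are
zeroed; survivors keep sign and magnitude. At $n = 7$ this corresponds to
$|r| \gtrsim 0.7545$. No multiplicity correction is applied here — the
threshold is a visualization device for isolating the most robust
relationships, and the family-wise question is deferred to the network
comparison stage.

**Community structure.** Communities are found by modularity maximization
on the thresholded matrix (the object the figures display). For positive
weights the objective is Newman–Girvan weighted modularity with
resolution $\gamma$ (default 1). Thresholded networks can retain negative
edges, and the package's choice for them is the asymmetric signed
composite
$$Q^{*} = Q^{+} - \frac{m^{-}}{m^{+}+m^{-}}\,Q^{-},$$
computed on the positive and negative sub-networks separately. This keeps
positive structure dominant while letting negative edges discourage
co-assignment, which matches the intuition that a significant
anticorrelation is evidence two regions belong to different functional
modules; a `positive_only` mode simply zeroes negative weights. The
optimizer is a seeded multi-restart Louvain-style agglomeration with two
non-standard details dictated by the signed objective: every non-empty
community is a move candidate (with negative weights, a node can profit
from joining a community it has *no* edges to, through the degree
penalty), and a final node-level refinement pass runs on the original
matrix after aggregation. On graphs small enough for exhaustive
set-partition search the optimizer recovers the global optimum in well
over 95% of seeded random instances and never exceeds it; ties are broken
toward fewer communities, then lexicographically, so runs are
reproducible bit for bit.

**Network comparison.** Drug and baseline networks are compared edge by
edge on the *unthresholded* correlations: all r-values enter the
comparison, because discarding sub-threshold baseline edges would bias
gain/loss calls. With $z = \operatorname{atanh}(r)$,
$$Z_{ij} = \frac{z^{(a)}_{ij} - z^{(b)}_{ij}}
  {\sqrt{1/(n_a-3) + 1/(n_b-3)}},$$
two-tailed normal p-values are corrected by Benjamini–Hochberg across the
351 unique edges of one comparison (Benjamini–Yekutieli by option), at a
deliberately liberal FDR level $q = 0.35$ that prioritizes avoiding
Type II errors in low signal-to-noise networks. Each contrast is
corrected as its own family; contrasts are always within gene and age.
Correlations at $|r| \ge 1 - 10^{-7}$ are clamped before the transform
and flagged.

**Classification of changes.** Significant edges are labeled by the
transition of their thresholded state from baseline to drug: null→pos =
gain of positive CGE, pos→null = loss of positive, null→neg = gain of
negative, neg→null = loss of negative, pos↔neg = sign reversal. The
mapping through thresholded states is an explicit reconstruction chosen
so difference maps stay consistent with the rendered networks; a
significant edge whose thresholded state did not change (a pos→pos or
neg→neg strength change) receives no gain/loss class and is instead
flagged in a supplementary `strength_change` column.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | edge-significance threshold (unitless p) |
| `q_level` | 0.35 | FDR level for edge-wise comparison |
| `gamma` | 1 | modularity resolution |
| `restarts` | 20 | Louvain restarts (deterministic given seed) |
| `n_subjects` | 7 | simulated subjects per group |
| PSD `tol` | 0.05 | max movement of a planted correlation during repair |

## The synthetic generator

Real subject-level autoradiography data are rarely shareable, so every
stage is validated against a generator with known ground truth.
`covariance_spec()` plants block structure — regions within a block
correlate at `within_r`, across blocks at `between_r`, individual edges
overridable — through a one-factor-per-block latent Gaussian model
(loadings $\sqrt{\text{within}_r}$, cross-block factor correlation
$\text{between}_r/\text{within}_r$), which realizes the targets exactly
and is positive semi-definite by construction. Overrides are applied
afterwards and the matrix is projected to the nearest PSD matrix by
eigenvalue clipping; if the projection moves any target by more than
`tol` (default 0.05) the spec is rejected as infeasible rather than
silently distorted. Subjects are multivariate-normal draws with
per-region mean 100 and SD 15 in arbitrary optical-density units
(plausible film-densitometry magnitudes; the analysis is scale-free, so
these only need to keep values positive).

`paper_like()` is the packaged end-to-end fixture: the full 24-group
factorial at $n = 7$, baseline blocks = the five anatomical area groups
with `within_r` 0.6 / `between_r` 0.2, and drug groups planting
strengthened couplings between the bed nucleus of the stria terminalis
(BNST) and prefrontal/accumbens nodes (r = 0.55 vs the 0.2 background;
combination treatments perturb four edges). The perturbation strengths
were fixed at design time at the largest values that remain comfortably
PSD-feasible against this background. These magnitudes emulate the
qualitative phenomenon of drug recruitment of stress nuclei into
forebrain networks; at $n = 7$ such differences are rarely individually
significant, which is faithful to how underpowered edge-wise comparison
is at this sample size.

What the generator does **not** emulate: autoradiography noise physics,
spatial autocorrelation between anatomically adjacent regions,
subject-level covariates, or non-Gaussian marginals (values are Gaussian,
clamped at zero in the vanishingly rare negative tail). Passing tests
therefore certify the statistical machinery, not robustness to every
artifact of real film data.

## Numerical choices and degenerate inputs

- Diagonals are fixed (r = 0, p = 1) and never counted as edges.
- Zero-variance regions yield r = 0, p = 1 on all their edges, with a
  warning, rather than NaNs.
- Groups with fewer than 4 complete subjects are refused: the Fisher
  standard error $1/\sqrt{n-3}$ is undefined at $n \le 3$.
- An empty thresholded network has $Q = 0$ and the all-singleton
  partition; isolated nodes always end as singletons.
- Exports print doubles with `%.17g`, so write→read round-trips are exact
  and repeated writes are byte-identical; SVG output is generated as
  deterministic text.
- The pipeline manifest records parameters and per-file MD5 checksums and
  contains no timestamps, so reruns under the same config and seed are
  byte-identical.

## Known limitations

- **Small-sample tail calibration.** The normal approximation for the
  Fisher z difference is accurate near the center but anti-conservative
  in the far tail at $n = 7$: the test-suite null simulation measures
  roughly 1.8× the nominal probability at the $10^{-3}$ level. At the
  liberal $q = 0.35$ with 351 edges this inflates the chance of at least
  one false discovery in a fully null comparison above $q$ (the
  calibration test in the suite computes this directly, alongside the raw
  0.05 rejection rate, which is accurate). The per-edge raw test and all
  comparisons at moderate-to-large $n$ are well calibrated; conclusions
  from $n = 7$ difference maps should be treated as hypothesis-generating,
  which is also why the liberal $q$ is paired with a stringent
  visualization threshold.
- The t-based edge p-value is an approximation to the exact permutation
  distribution; at $n = 7$ individual fixtures can disagree with the
  exact permutation p by a few hundredths in the mid-p range (mean
  disagreement is ~0.01).
- Modularity maximization is NP-hard; optimality is certified only on
  small graphs via the exhaustive oracle. For 27-node networks the
  seeded multi-restart optimum is reproducible but not provably global.
- No partial correlations, shrinkage, covariate adjustment, or omnibus
  whole-network tests: the method is intentionally plain intersubject
  Pearson correlation with edge-wise comparison.

## Problem sizes used in validation

The suite validates calibration with 500 replicate null comparisons (27
regions, $n = 7$), 200-replicate retention-rate checks, 1000-replicate
Fisher-z coverage, 100 random small graphs against the exhaustive
partition oracle, and planted-structure recovery at $n = 200$ subjects;
generator convergence is checked at $n = 10{,}000$. These sizes were
chosen so Monte-Carlo error is small relative to each tolerance while the
whole suite runs in well under a minute on one core.
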