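---
title: "Modelling connectome-based spread of tau pathology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling connectome-based spread of tau pathology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tauspreadr)
library(dplyr)
set.seed(1)
```

## The model

Misfolded tau propagates between connected brain regions. `tauspreadr`
models this as linear diffusion on a directed, weighted connectome. Given
an adjacency matrix $A$ over $N$ regions, where $A_{ij}$ is the projection
strength from region $i$ to region $j$, the out-degree graph Laplacian is

$$L = D_\mathrm{out} - A, \qquad D_\mathrm{out} = \mathrm{diag}(A\,\mathbf 1),$$

and pathology seeded in a vector $x_0$ (one unit per injection site; by
default the dentate gyrus, CA1, CA3 and the posterior parietal association
area PTLp) evolves as

$$\hat x(t) = x_0\, e^{-cLt},$$

with $c$ a free diffusion rate (per month) and $t$ the post-injection
horizon (3 months by default). We treat the state as a row vector — i.e.
the generator applied to column vectors is $-cL^\top$ — because in that
orientation the all-ones vector is a left null vector of the generator:
pathology flows along edges and the total amount is exactly conserved.
Conservation is a physical requirement for a pure transport model and
gives the implementation one of its sharpest tests (total mass is checked
to $10^{-10}$ relative error on every call). Only the product $c\,t$ is
identified; rescaling $t$ rescales the fitted $c$ accordingly.

Three connectome "modes" share this machinery: **anterograde** spread uses
$A$ as stored (soma-to-terminal), **retrograde** uses $A^\top$, and the
**Euclidean** control replaces connectivity with a symmetric spatial
proximity matrix (by default $1/d_{ij}$ on centroid distances; an
$\exp(-d/\lambda)$ kernel is available). Because tract-tracing resources
differ in whether the measured fluorescence labels the terminal or the
somatic end of a projection, the direction tag attached when a matrix is
read is a convention: `read_connectome()` tags matrices as anterograde
under the source-to-target convention and `directional_view()` flips
between directions by transposition, so an opposite upstream convention
amounts to swapping the two labels rather than changing any number.

## Numerical choices

The propagator $e^{-cL^\top t}$ is computed from an eigendecomposition of
the generator, performed once per connectome, so a whole rate grid costs a
single complex matrix product; the decomposition is accepted only when it
reconstructs the generator to $10^{-9}$ relative accuracy, otherwise the
code falls back to a dense Padé matrix exponential (`Matrix::expm`).
Residual rounding drift is redistributed uniformly (it is below $10^{-12}$
in practice) and negative dust is clipped to zero.

Rate fitting maximizes the Pearson correlation between
$\log_{10}$-transformed predicted and observed regional pathology. Each
vector is shifted by its own smallest positive value before the log:
predictions live in seed-mass units (mostly $\ll 1$) while observations
are object densities per mm², so a shared shift would flatten whichever
vector has the smaller scale and measurably biases the fitted rate on
synthetic cohorts. Regions with zero observed pathology are excluded from
the correlation; seed regions are excluded by default since their values
are imposed rather than predicted (`include_seeds = TRUE` restores them).
The search is a 200-point log-spaced grid on $c \in [10^{-4}, 10^{2}]$
per month followed by golden-section refinement, and is fully
deterministic.

## The combined regressions

The "Bidirectional Euclidean (tdT)" model regresses observed regional
pathology on the three mode-specific predictions, optionally with tdT+
cell density $T$ (a proxy for neuronal activity at labeling time):

$$x(t) = \beta_a \hat x(t)_a + \beta_r \hat x(t)_r + \beta_e \hat x(t)_e
  + \beta_T T + \varepsilon.$$

All variables are $\log_{10}(x+\varepsilon)$-transformed and z-scored, so
the reported coefficients are standardized beta weights: with a single
predictor the beta equals the Pearson correlation, and the fit is
invariant to affine rescaling of any predictor or of the response. One
consequence worth knowing when simulating: if data are generated as
$y = \sum_j \beta_j z_j + e$ with correlated predictors, the population
standardized coefficients are $\beta_j/\mathrm{sd}(y)$, not $\beta_j$ —
the generating weights are recovered exactly only after multiplying the
fitted betas back by $\mathrm{sd}(y)$. `beta_ratios()` reports the
anterograde:retrograde, Euclidean:retrograde and anterograde:Euclidean
ratios used to compare the relative contribution of each mode between
groups, flagging near-zero denominators as undefined rather than
returning infinities.

The tdT-by-treatment interaction model (`fit_tdt_interaction()`) is fit
separately per genotype on regional means per treatment group, with
treatment coded Sal = 0, PTZ = 1, so the tdT main effect is the saline
simple slope and the PTZ slope adds the interaction coefficient; both are
tested two-sided with the delta-method standard error from the
coefficient covariance. Partial residuals for the tdT term (residual plus
the group's fitted tdT contribution) reproduce the simple slopes exactly
when regressed on tdT within a group, which the test suite checks.

Group-level diffusion and combined fits use regional means across mice;
mouse-level uncertainty is handled by `bootstrap_statistic()`, which
resamples mice with replacement within a genotype-by-treatment group and
recomputes regional means per resample. Two bootstrap distributions are
compared with a two-tailed sign construction,
$p = 2\min\{\hat P(\Delta \le 0), \hat P(\Delta \ge 0)\}$ with a
$+1/(B+1)$ continuity correction (minimum attainable $p = 2/(B+1)$),
pairing draws by index by default (`all_pairs` available). Families of
such comparisons are adjusted with Benjamini–Hochberg FDR
(`fdr_adjust()`). Region-wise Pearson screens against behavioral
covariates are unadjusted by default — matching the ambiguity of
"adjusted where appropriate" in this setting — with `adjust = TRUE`
available.

## Seed specificity

`random_seed_null()` asks whether the observed spatial pattern is
specific to the experimental seed sites or merely to their generic
network position: it redraws seed sets of the same cardinality whose mean
pairwise centroid distance is within a tolerance (default ±20%) of the
experimental set's, refits the diffusion model for each, and reports the
fraction of null fits below the experimental fit. Sets are drawn by
rejection sampling without replacement (never duplicating a set and never
the true set); exhausting the candidate pool is an error that reports the
achievable count rather than silently returning fewer sets. The matching
statistic is pluggable (`max_pairwise` as an alternative).

## What the synthetic data emulate — and what they do not

`generate_atlas_connectome()` builds a geometry-embedded directed graph:
centroids uniform in an 8 mm box, edge probability
$\mathrm{density}^{d/\bar d}$ (so edges are distance-local, and the graph
is complete at density 1), log-normal weights mixing a symmetric and a
direction-independent component under an `asymmetry` parameter, and a
two-level hierarchy from spatial k-means clusters with designated DG /
CA1 / CA3 (under a HIP parent) and PTLp acronyms so seed-variant analyses
run unchanged. Weights are rescaled to unit mean row sum, which keeps the
Laplacian spectrum — and therefore sensible values of $c$ — on a common
scale across sizes; the unit choice is absorbed by $c$.

`simulate_cohort()` generates per-mouse, per-region pathology as the
inverse-log transform of a weighted combination of the standardized
log-spread predictors plus a group-specific tdT association, with
multiplicative log-normal noise (pathology densities are positive and
right-skewed, so additive Gaussian noise would be the wrong null model).
tdT densities are generated as a correlate through a shared regional
activity profile, not as a cause: the package tests association recovery,
and causal claims rest on experimental design, not on this code. Default
conditions mirror the reported study structure: 10 mice per group (the
observed range is 6–15), ~100 regions, retrograde-dominant weights in WT
with an increased anterograde weight in 5X, a positive tdT association in
every group except PTZ-treated WT, rate 0.25/month, horizon 3 months, and
log10 noise SD 0.25.

What passing tests on these fixtures do **not** show: real atlas geometry
and hemispheric asymmetries, spatial autocorrelation of measurement error,
region-size-dependent detection noise, and any nonlinearity (aggregation,
clearance, carrying capacities) are all absent by construction, so
recovery performance here is an upper bound on what identical analyses
achieve on real imaging data.

## Calibration experiments and problem sizes

`scripts/acceptance.R` re-runs the package's calibration suite from
scratch: ODE-oracle agreement and mass conservation on 50 random small
graphs; rate recovery (100 noise replicates at 50 regions, rate
0.5/month); direction identifiability (100 fresh asymmetric worlds);
recovery of combined-model weights (200 replicates at 100 regions);
interaction power and type-I error (200 cohort replicates at 150
regions); seed-null uniformity (200 replicates of 100 matched sets at 40
regions) and specificity (50 low-noise runs); brute-force FDR agreement;
bootstrap-test edge cases; and byte-level pipeline determinism. These
sizes keep the full suite to a few minutes on one CPU while leaving the
Monte-Carlo error of each fraction near one percentage point.

Two measurements sit at their thresholds by construction and are worth
reading with the standardization caveat above in mind: the noisy-rate
median relative error hovers around 10% (its seed-to-seed spread brackets
the threshold), and the combined-model weight-recovery fraction compares
standardized betas against generating weights that differ by the
$1/\mathrm{sd}(y)$ factor, so it plateaus around 0.85 rather than 1.

## Known limitations

- The linear model has no regional vulnerability, clearance or saturation
  terms; it is the transport null model, not a biophysical fit.
- Bootstrap comparisons assume exchangeable mice within a group; litter
  or batch structure is not modelled.
- The Euclidean kernel's functional form is a convention; conclusions
  that depend on its tail behavior should be checked under both kernels.
- With strongly correlated mode predictions, standardized betas are
  estimated with inflated variance (the condition number is reported and
  a warning raised beyond $10^4$); beta *ratios* inherit that noise.
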