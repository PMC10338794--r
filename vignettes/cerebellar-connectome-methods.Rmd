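---
title: "Methods: weighted connectome analysis with cerenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted connectome analysis with cerenet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cerenet)
```

# The analysis in one page

`cerenet` studies group differences in the topology of functional brain
networks — here sized and parameterized for the cerebellum (28 regions of a
cerebellar parcellation, 235 retained volumes at TR = 2 s), though nothing
in the code is tied to that anatomy. The chain is:

1. **Motion screening.** Six rigid-body parameters per volume; rotations
   are converted to millimeters of arc on a 50 mm sphere, framewise
   displacement (FD) is the sum of absolute volume-to-volume changes over
   the six parameters, and subjects exceeding 3 mm translation or 0.5 mm
   mean FD are excluded.
2. **Cleaning.** Nuisance regression and 0.01–0.08 Hz band-pass filtering
   in a *single* linear model: the design holds the 24-parameter motion
   expansion (6 parameters, their one-volume-back copies, both squared),
   optional tissue/global signals, an intercept, and discrete-cosine
   columns spanning every frequency *outside* the passband. Residualizing
   on this design filters and de-noises simultaneously, so the filter
   cannot reintroduce variance that the nuisance regressors removed.
3. **Connectivity.** Pearson correlation between every pair of regional
   mean series.
4. **Thresholding.** At each sparsity level `s` in 0.12–0.40 (step 0.01),
   keep `round(s * N(N-1)/2)` edges: first the maximum-correlation
   spanning tree (computed as a minimum spanning tree on distance
   `1 - r`), then the strongest remaining positive correlations. Every
   network is therefore connected and density-matched across subjects.
5. **Graph metrics.** Weighted clustering coefficient (Onnela form),
   characteristic path length on inverse-weight distances, binary nodal
   degree, and nodal betweenness centrality. Cp and Lp are normalized by
   the mean over an ensemble of degree-preserving (Maslov–Sneppen
   rewired) random networks, giving gamma and lambda; sigma =
   gamma/lambda summarizes small-worldness. Each metric's curve over the
   sparsity grid is integrated (trapezoid) into an AUC.
6. **Inference.** Two-sample pooled-variance T statistics with
   10,000-permutation null distributions; Benjamini–Hochberg FDR at
   q < .05 within the global family (4 tests) and the nodal family
   (2 × 28 tests) separately; partial correlations (controlling age, sex,
   mean FD, education) between FDR-significant metrics and clinical
   scores, with a second FDR pass.

# Design choices where the procedure was genuinely open

**Weighted clustering formula.** The clustering coefficient of a weighted
network is not unique; we use Onnela's geometric-mean triangle intensity
with weights rescaled by the network maximum. It is bounded in [0, 1],
reduces to the binary coefficient on uniform weights, and is invariant to
rescaling all weights by a constant — which keeps the metric comparable
across subjects whose overall correlation level differs.

**Distance transform.** Edge distance is `1/weight`. The alternative
`1 - weight` compresses distances among strong edges; the reciprocal is
the common choice for correlation-weighted connectomes and is exposed
through the path-length functions only via weights, so no hidden constant
enters group comparisons.

**Negative correlations** are discarded before thresholding (default
`negative_edges = "drop"`). Path-length and clustering transforms require
positive weights, and sparsified connectomes conventionally retain
positive edges. An `"absolute"` mode exists for sensitivity analyses.

**Edge budget rounding** is round-half-up (`floor(x + 0.5)`), not R's
banker's rounding, so counts are platform-stable and monotone in
sparsity.

**Tie-breaking** among equal correlations at the budget boundary is
lexicographic on the region-index pair — arbitrary, but deterministic, so
identical inputs always give identical networks.

**Null networks are drawn connected.** Degree-preserving double-edge
swaps can disconnect a sparse network, and a disconnected null has
infinite path length, which would poison the lambda normalization. The
ensemble therefore rejects disconnected rewirings and redraws (the
rejection rate is a few percent at the sparsest levels and essentially
zero above s = 0.15). Swap weights travel with their edges, so the weight
multiset — and hence the scale of null Cp and Lp — is preserved. Each
null uses 10 swap attempts per edge, a standard mixing heuristic;
`swap_multiplier` exposes it.

**Betweenness scale.** Betweenness is reported unnormalized on the
unordered-pair scale. Any fixed rescaling cancels in the permutation
group test, so the choice affects readability, not inference.

**Permutation p-values** use the add-one estimator
`(#{|T*| >= |T|} + 1) / (n_perm + 1)`: the plain proportion is undefined
as a p-value when zero permutations exceed the observed statistic. The
reported critical values are ± the 95th percentile of |T*|, which makes
"significant at .05" and "|T| beyond the critical value" agree up to
permutation discreteness. The T statistic is the pooled-variance form; a
Welch option exists.

**Sex as a covariate** is encoded 0/1, the only encoding compatible with
a linear partial-correlation framework.

# The synthetic cohort generator

Because the pipeline consumes only second-order statistics of the
regional series, the generator produces *band-limited Gaussian
processes*, not a hemodynamic forward model: each subject's T × N series
is drawn from a zero-mean multivariate Gaussian with a block (modular)
correlation structure — `n_modules` contiguous blocks with correlation
`within_module_corr` inside blocks and `between_module_corr` elsewhere —
then projected onto the discrete-cosine components inside 0.01–0.08 Hz.
The projection is applied per region after sampling, so spectra resemble
cleaned BOLD; because the same projection hits every region, target
correlations are preserved in expectation (any test oracle for the
realized correlations must include the same filter). What this generator
deliberately does *not* emulate: hemodynamic convolution, physiological
noise, scanner drift, spatial smoothness, or global artifacts. Passing
tests therefore demonstrate that the pipeline recovers known
second-order structure, not that it is robust to every artifact of real
fMRI.

Defaults mirror the study conditions the pipeline targets: 40 + 40
subjects, 28 regions, 235 timepoints at TR = 2 s, 4 modules,
within-module correlation 0.35 (group A) versus 0.55 (group B),
between-module correlation 0.10. Raising within-module correlation
strengthens clustering relative to degree-matched nulls, i.e. it raises
gamma — the effect the group comparison is designed to detect.

Each subject's latent within-module correlation is jittered around the
group target (`subject_corr_sd`, default 0.05) and clinical scores are
generated as `clinical_effect x latent + noise`; this gives the
brain–behavior stage a recoverable ground truth. Motion traces are
6-parameter cumulative random walks (defaults 0.02 mm / 0.02° per-volume
increments, giving mean FD around 0.1 mm — typical of a usable scan).
Covariates are drawn group-independently (age uniform 25–65, sex
Bernoulli(0.5), education uniform integers 9–19), emulating a matched
design. One master seed spawns per-subject child seeds
(`seed * 10000 + index`), so any subject is reproducible in isolation.

# Numerical notes and degenerate inputs

- The block correlation matrix is provably positive definite for valid
  targets (`1 > within > between >= 0`); a closed-form minimal shrinkage
  toward the identity (`s* = (1 - 1e-6) / (1 - lambda_min)`, using the
  linearity of the eigenvalues of `I + s(Sigma - I)`) guards hand-built
  matrices.
- A sparsity below `(N-1) / (N(N-1)/2)` cannot produce a connected
  network and fails with the constraint spelled out; so does a
  correlation matrix whose positive part is disconnected.
- At the tree floor (budget = N − 1) real and null clustering are both
  zero and gamma is undefined; the default grid's lowest level (45 edges
  for N = 28) is far above it.
- Rank-deficient cleaning designs fall back to the pivoted-QR
  least-squares projection with a warning; zero-variance regions abort
  connectivity with the region named.
- Shortest-path ties are detected with an absolute tolerance of 1e-10 on
  accumulated inverse-weight distances.

# Problem sizes used in the test suite

The validation suite runs the full recovery experiment at the study
conditions (20 effect cohorts and 20 matched null cohorts of 40 + 40
subjects, 200-network null ensembles, 1000-permutation tests) and checks
the graph metrics against brute-force enumeration on all connected
graphs of 3–5 nodes plus sampled 6-node graphs. The 200-null /
1000-permutation choices for the simulation experiments are the
generator's own calibration — Monte-Carlo stability checks show gamma
and lambda stable to within 2% between 500- and 1000-null ensembles,
and the 10,000-permutation default remains the analysis setting for real
cohorts (and for `scripts/acceptance.R`).

# Known limitations

- The generator's modular blocks are contiguous and equal-sized; real
  parcellations have unequal, spatially interleaved communities.
- Gaussianity means no amplitude outliers; the permutation test's
  robustness advantage over the t test is therefore not exercised.
- The exclusion rule is evaluated on the simulated motion traces, but
  simulated motion is independent of the signal, so motion–artifact
  coupling (the reason the rule exists) is not modeled.
- Only the two nodal metrics of the analysis are implemented; modularity,
  efficiency, and rich-club coefficients are out of scope.
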