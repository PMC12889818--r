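---
title: "From multiplexed lung images to dormant-lesion immune niches"
author: "tumorNiche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From multiplexed lung images to dormant-lesion immune niches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorNiche)
```

## The problem

Disseminated breast-cancer cells that reach the lung can either grow into
proliferative metastatic lesions or persist as dormant lesions of a
handful of cells. Whether a lesion stays dormant appears to depend on the
immune cells in its immediate neighborhood. tumorNiche implements the
analysis that makes this question quantitative for multiplexed
immunofluorescence images of mouse lung: segment and phenotype every
cell, group tumor cells into spatially defined lesions, call each lesion
dormant (1–8 tumor cells) or proliferative (more than 8), describe each
lesion's immune composition compositionally, and compare genotypes with
mixed-effects models that respect the per-mouse sampling structure.

Throughout, the two genotypes are a control and a myeloid-specific
TGF-β-receptor-II knockout, in which dormancy is strongly enriched.

## Pipeline stages and their models

### Image normalization

Raw channels are saturated at the brightest 0.01% of pixels and rescaled
to 8 bits (`saturateQuantize`). Rounding is half-to-even so results are
platform-reproducible; a constant channel maps to all zeros, since a
featureless channel carries no signal. Residual autofluorescence and
spillover are handled by explicit pairwise channel arithmetic
(`spilloverSubtract`, clipped at zero); which channel pairs and factors
to use is inherently a judgement about a particular staining run, so the
package applies none by default and exposes the triples in the pipeline
configuration.

Membrane stains form rings that barely overlap the nuclear mask, so
membrane channels are smoothed with a Gaussian filter before per-cell
averaging. The protocol names a "four-pixel radius"; we read that as
sigma = 4 px (the simplest faithful interpretation, overridable via
`smooth_radius_px`). The kernel is normalized and boundaries are handled
by symmetric reflection, so total intensity is conserved to well within
0.1%.

### Segmentation

Nuclei are segmented from the Hoechst channel: Otsu binarization (the
protocol says only "binarized"; Otsu is standard and parameter-free, and
a manual threshold can be supplied), a watershed on the Euclidean
distance transform to split touching nuclei (locality `ext = 5` px), and
a minimum object size of 20 px (~1.6 µm² at the 0.284 µm pixel size) as
a debris filter. Per nucleus we record the area, the centroid in
micrometres (0-based pixel centers, x along rows, y down columns), and
the mean fluorescence intensity of every marker — from the smoothed
channel for membrane markers, from the raw channel for nuclear markers
(GFP-class and Ki67).

### Phenotyping

Cell typing is a two-stage rule. First, each marker gets a threshold at
the elbow of its expression distribution: values are sorted, plotted on
a log1p scale against rank with both axes normalized to [0, 1], and the
knee is the point of maximum perpendicular distance from the endpoint
chord (the kneedle construction). Because the distance profile is often
nearly flat across the upper shoulder of the negative population, we take
the *last* index within 1% of the maximum and draw the threshold midway
(on the log1p scale) between that value and the next sorted value — when
a clear positive/negative gap exists, the threshold lands inside the gap.
Cells whose ±-profile satisfies exactly one template's expected signs are
matched; "any" markers (Ki67) never participate. Ambiguous profiles are
deliberately not split by heuristics: they flow to the second stage.

The matched cells define each type's representative quantitative profile
(per-marker mean MFI, minimum 20 matched cells). Every unmatched cell is
then regressed, across markers, on all representative profiles plus an
intercept (ordinary least squares — the cell as a mixture of known
types). Among coefficients that are positive and significant at
two-sided alpha = 0.05, the largest wins; positivity is required because
a negative "contribution" has no mixture interpretation, and the
intercept absorbs per-cell background. Cells with no qualifying
coefficient are uncategorized; they can be inspected by seeded k-means
(k = 5 by default) — in practice such clusters tend to be
single-marker image noise — and are excluded from analysis, as are any types
listed in the panel's exclusion list (e.g. a γδ T-cell channel
compromised by spillover).

### Lesions and dormancy

Tumor cells are nodes of a per-sample proximity graph with an edge
whenever two centroids are at most 200 µm apart (inclusive); connected
components are lesions, including singletons. Every non-tumor cell
joins each lesion that has a tumor cell within 200 µm of it — zero, one,
or several; a de-duplication toggle (nearest lesion only) is provided
for sensitivity analysis but is off by default, following the
multi-membership definition. A lesion with 1–8 tumor cells is dormant,
more than 8 proliferative; the cutoff is configurable
(`dormancy_cutoff`) because it originated in surface imaging of
whole-lung lesions and its reuse for section-based lesions is a
judgement call.

### Compositional niche analysis

Per-lesion immune-type counts are compositional: attachment radii fix a
neighborhood, not a sampling fraction. Counts are therefore re-expressed
as centered log-ratios, clr_i = ln(c_i + 0.5) − mean_k ln(c_k + 0.5);
the 0.5 pseudocount handles empty categories (the multiplicative-
replacement default, configurable). Each type's CLR is then z-scored
across lesions so abundant types do not dominate. Pairwise Pearson
correlations across types, clustered by average linkage on 1 − r and cut
at two modules, define the co-occurrence niches; module 1 is anchored by
a configurable tumor-proximal reference type (CD8 T cells by default).
PCA on the standardized CLRs (already centered) gives each lesion a PC1
score; loading signs are pinned by making the largest-magnitude loading
of each component positive. Linkage, distance and the module count are
explicit choices where heatmap software usually decides implicitly,
and all are exposed.

### Mixed models

Three random-intercept models quantify the genotype contrasts, each with
the mouse (sample) as the grouping factor:

* **binomial**: each cell's tumor/non-tumor status on genotype (logit
  link) — is the tumor-cell burden different?
* **zero-truncated negative binomial**: each lesion's size on genotype
  (log link), θ estimated jointly — a lesion has at least one cell, so
  the NB is conditioned on positivity;
* **Gaussian**: each lesion's PC1 on size, genotype and their
  interaction — does the niche composition track size and genotype?

The fitters are implemented in the package: the marginal likelihood
integrates the random intercept by adaptive Gauss–Hermite quadrature (15
nodes by default; one node is the Laplace approximation), with per-group
posterior modes found by a vectorized, safeguarded Newton iteration.
Optimization is multi-start BFGS with a Nelder–Mead polish; inference is
Wald z from the observed information (a likelihood-ratio helper,
`lrTest`, is provided). Genotype is coded 0/1 with the alphabetically
first level as reference — stable under row permutation — and the coding
is recorded in the fit's notes. The Gaussian model has a closed-form
marginal likelihood (compound-symmetric per-group covariance via
Woodbury) profiled over GLS fixed effects; ML is the default so
log-likelihoods are comparable across fixed-effect specifications, REML
is available. Lesion size enters untransformed by default with a
log-size option. Non-convergence is flagged, never silently accepted;
variance parameters collapsing to a boundary (σᵤ → 0, θ very large) are
noted on the fit.

## The synthetic-data generator

Every stage above is validated against `generateCellTable` /
`renderMultiplexImage`, which simulate the study design with full ground
truth. The defaults *are* the emulated study conditions and are not
tuned per test:

* two genotypes × 4 mice, 15 lesions per mouse, in a 3 × 3 mm field;
* lesion sizes zero-truncated NB with means 16.8 (control) and 3.8
  (knockout) — average lesion sizes typical of a strong dormancy
  phenotype — and dispersion θ = 2, a realistic mid-range
  overdispersion;
* per-mouse random intercepts with SD 0.5 on the log scale, the
  heterogeneity used throughout the calibration simulations;
* lesion centers at least 450 µm apart, so that planted lesions and
  recovered 200 µm components correspond 1:1 and recovery checks are
  unambiguous; tumor cells scatter isotropically (SD 30 µm);
* Poisson(40) immune cells per lesion, placed within 150 µm of a random
  tumor cell of their lesion (guaranteeing attachment), with types drawn
  from one of two niche profiles; by default niches are size-linked
  (≤ 8 cells → the NK/monocyte/neutrophil/CD103⁺-DC profile, > 8 → the
  T-cell/macrophage/DC profile), with an independent-assignment switch
  for null simulations;
* 50 background immune cells per mm², uniform, placed at least one
  nuclear diameter apart and inset from the field edge so rendered
  nuclei are wholly imaged;
* type-conditional log-normal MFIs with 8-fold positive/negative
  separation (sdlog 0.45) over a 20-marker, 12-type panel chosen so
  every pair of types differs in expected signs and markers outnumber
  types + 1 (the regression stage's identifiability condition);
* optional rendering: Gaussian nuclear blobs (σ = 2.5 px), membrane
  annuli (radius 4 px), Poisson shot noise and a linear spillover matrix.

What the generator does *not* emulate: staining-cycle misalignment,
bleaching kinetics, autofluorescence structure, cell-shape variation,
3-D sectioning effects, or spatial correlation of marker noise. Passing
tests therefore demonstrate the pipeline's correctness on its own model
of the data, not robustness to every artifact of real imaging.

## Numerical and testing choices

Seeds fan out from one global seed by fixed offsets, so stages are
reproducible in isolation and two runs of the same configuration are
byte-identical. Distances are Euclidean in micrometres; the spatial
index (grid binning at the neighbor radius) is contractually identical
to brute-force all-pairs union-find, and the test suite verifies exact
partition equality on random point sets up to 2,000 points. The ZTNB
log-pmf is computed in log space with `log1p`/`log1mexp` guards and
matches the zero-truncated Poisson at θ = 10⁶ to 10⁻⁴. Simulation-based
checks in the test suite use 500 null replicates for Wald-test
calibration (20 samples) and 50 replicates for effect recovery
(6 samples per genotype, 30 lesions per sample); the default end-to-end
pipeline run (about 10,000 cells, 120 lesions) completes in well under a
minute on one CPU.

## Known limitations

* Phenotyping assumes the panel's sign templates are correct and
  complete; genuinely novel cell types end up uncategorized.
* The elbow rule presumes a unimodal-plus-shoulder or bimodal marker
  distribution; a marker with three populations gets a single gate.
* Lesion definition is 2-D; serial-section or volumetric lesion fusion
  is out of scope.
* The Wald tests are asymptotic in the number of mice and are
  anticonservative when mice are few: maximum likelihood underestimates
  the random-intercept variance, and the observed-information standard
  error conditions on it (the calibration simulations in the test suite
  quantify this at 20 samples, where reference fitters such as glmmTMB
  and lme4 behave identically). With few samples the likelihood-ratio
  option is preferable.
* Spillover correction is user-specified, not estimated.

## A minimal run

```{r example, eval = FALSE}
cfg <- readPipelineConfig(overrides = list(seed = 7))
res <- runPipeline(cfg, "run7")
res$fits$ztnb           # genotype effect on lesion size
head(lesionTable(res$lesionSet))
res$niche$modules       # the two immune-niche modules
```
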