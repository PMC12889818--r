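# tumorNiche

Spatial immune-niche analysis of multiplexed immunofluorescence images of
metastatic lung tissue, for labs studying tumor dormancy: from raw
multi-channel images (or per-cell measurement tables) to phenotyped
cells, distance-defined tumor lesions, dormant/proliferative calls,
compositional immune-niche modules, and mixed-effects genotype
comparisons. A seeded synthetic-data generator with full ground truth
makes every stage testable without any external download.

## The analysis

Cells are segmented from the nuclear channel (Otsu binarization +
distance-transform watershed) after percentile saturation (brightest
0.01% of pixels), 8-bit conversion, pairwise spillover arithmetic, and
Gaussian smoothing (σ = 4 px) of membrane channels. Cell types are
assigned in two stages: per-marker elbow (kneedle) thresholds gate each
cell ±, cells matching exactly one expected sign profile are typed, and
the rest are modeled by OLS as mixtures of the matched types'
representative profiles — among positive, significant (two-sided t,
α = 0.05) contributions the largest wins; leftovers are excluded.

Tumor lesions are the connected components of the per-sample proximity
graph with an edge whenever two tumor-cell centroids are ≤ 200 µm apart;
every non-tumor cell joins each lesion with a tumor cell within 200 µm
(zero, one, or several). A lesion of 1–8 tumor cells is *dormant*, > 8
*proliferative*. Per-lesion immune counts c are re-expressed as centered
log-ratios,

    clr_i = ln(c_i + 0.5) − (1/K) Σ_k ln(c_k + 0.5),

z-scored per type, then summarized by pairwise correlations (average-
linkage modules, cut at 2 — the two immune niches) and by PCA (PC1 is
the niche axis). Genotype effects are tested with three random-intercept
models fitted by adaptive Gauss–Hermite quadrature (15 nodes),
implemented in the package:

* cell tumor status ~ genotype + (1 | sample), binomial;
* lesion size ~ genotype + (1 | sample), zero-truncated negative
  binomial, log link, with NB(y; μ, θ) conditioned on y ≥ 1;
* lesion PC1 ~ size × genotype + (1 | sample), Gaussian (closed-form
  marginal likelihood).

## Worked example

```r
library(tumorNiche)
cfg <- readPipelineConfig(overrides = list(seed = 7))
res <- runPipeline(cfg, "run7")   # simulate -> phenotype -> lesions ->
                                  # niches -> models, ~30 s
res$fits$ztnb
```

```
Zero-truncated negative binomial (log link) mixed model with per-sample random intercept
  n = 120 observations, 8 groups; logLik = -390.896
            Estimate Std.Error      z        p
(Intercept)   2.7570    0.2349 11.739 8.03e-32
genotype     -0.9093    0.3361 -2.706 6.81e-03
  random-intercept SD: 0.4345
  dispersion theta: 2.4776
  notes: genotype coding: control = 0 (reference), knockout = 1
```

The genotype coefficient is the log ratio of expected lesion size in the
knockout relative to control — negative, i.e. knockout lesions are
smaller (more dormant), with the per-mouse random intercept absorbing
between-animal variability. `res$niche$modules` labels each immune type
with its co-occurrence module (module 1 anchored at CD8 T cells — the
proliferative-lesion niche; module 2 the NK/monocyte/neutrophil/CD103⁺
DC niche around dormant lesions), and
`lesionTable(res$lesionSet)` holds one row per lesion with its size,
dormancy state and sample.

A thin CLI wrapper is included at `inst/scripts/tumorniche.R`
(`run`, `simulate`, `validate` subcommands over a YAML config).

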