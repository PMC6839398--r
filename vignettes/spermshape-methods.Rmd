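---
title: "Shape analysis of sperm nuclei and sex-ratio drive statistics: models and choices"
author: "spermshape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape analysis of sperm nuclei and sex-ratio drive statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spermshape)
```

This vignette is the package's own account of its methods: the models
behind each stage, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices a maintainer would want to know about. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The angle profile

The primary shape descriptor is the sliding-window interior-angle profile.
An outline is a simple, closed, counterclockwise polygon in micrometres.
At each of `n_index` (default 100) positions equally spaced along the
perimeter, the interior angle is measured between the two points lying
half a window before and after the position, where the window
(`window_fraction`, default 0.05) is a fraction of the total perimeter.
Convex regions give angles below 180°, concave (reflex) regions above;
interior-versus-reflex disambiguation uses the sign of the cross product
of the traversal vectors, which is valid because orientation is
canonicalized to counterclockwise on construction.

Two properties make this descriptor convenient. It is invariant to
rotation, translation and uniform scaling, so no size normalization is
needed before clustering. And on a circle it has the closed form
$180° - 180°\,f$ for window fraction $f$ (the inscribed-angle theorem),
which the test suite uses as an analytic oracle at several window widths.

The window default of 0.05 is a configuration choice: wide enough that a
one-pixel zigzag cannot dominate the angle, narrow enough that the hook
apex of a mouse sperm head still stands out sharply. Because the choice is
a convention rather than a derived quantity, the circle oracle in the
tests is parameterized in $f$, so any other default remains verifiable.

Profiles are anchored at the **hook apex**, the global minimum of the
profile — the sharpest convex point of the falciform head. Ties break to
the earliest traversal position. A profile whose range is below 5° (a
circle, a blob) carries no landmark, and anchoring raises an error rather
than silently picking noise.

## Morphometric parameters

`morph_stats()` reports area (shoelace formula), perimeter, length
(maximum caliper diameter over the convex hull), width (extent
perpendicular to the length axis), circularity $4\pi A/P^2$, regularity
$A/(\pi L W/4)$ — the ratio of the area to that of the ellipse spanning
the same axes — and the profile minimum angle. Circularity and regularity
are size-independent; both equal 1 for the ideal shape (circle, ellipse).
The regularity formula is this package's documented stand-in for the
bounding-ellipse deviation measure used in nuclear-morphology tools; it is
size-free, equals 1 for any ellipse, and penalizes both angular and
crescent-shaped departures.

## The synthetic-data generator

There is no public per-cell generative model for mouse sperm head shape,
so the generator is a parametric stand-in designed to give independent,
interpretable knobs for the four effects reported for Yq-deficient sperm:
acrosomal curvature, hook length, cross-sectional area, and base width.

A head is a star-shaped radial function around an elliptical body
(`body_length` × `body_width`, defaults 8 × 4.2 µm, typical of the mouse
sperm nucleus):

* an **apical hook**: a sharp radial spike at angle 0 whose width scales
  with its length (a self-similar tip). This keeps the apex angle roughly
  constant as hook length varies, so hook-length variation changes the
  hook's extent rather than making some cells needle-sharp and others
  blunt — without this, hook noise dominates the profile variance through
  the steep apex walls;
* a **dorsal acrosomal concavity**: a broad Gaussian dip (s.d. 0.8 rad) in
  the radius between hook and mid-body, with depth proportional to the
  dimensionless `acrosome_curvature`. The dip is deliberately broad: a
  narrow notch of the same area is dominated by angle-measurement noise,
  whereas the biological effect is a smooth change of edge curvature. A
  softplus floor makes extreme curvature saturate smoothly instead of
  clipping, so no discrete shape regime appears in the far tail;
* a **caudal base-width** modulation and a global `area_scale`;
* a small seeded low-order Fourier perturbation of the radius (default
  amplitude 0.4% of the half-width) for cell-to-cell texture. Because the
  radius stays positive, every generated polygon is simple by
  construction.

Populations draw per-cell parameters as independent Gaussians. All cells
of a genotype receive `genotype_effect`; Y-bearing cells additionally
receive `sex_effect`; wild type ignores `sex_effect`, making X and Y cells
exchangeable there (a property the null-calibration tests rely on).
Latent sex labels are Bernoulli(0.5), reflecting the equal production of
X- and Y-bearing sperm by meiosis.

**Calibration.** The default effect sizes are a tuning target, not
measured biology: they were set, once, so that clustering a mixed
wild-type + Yq-deletion cohort and reading off the X percentage of mutant
cells in the predominantly-wild-type ("normal") clusters lands near the
high-50s percent range reported for real data, while wild-type cohorts
stay at 50%. Within-population noise SDs (e.g. 0.35 for curvature, 4–5%
CVs for the linear dimensions) make acrosomal curvature the dominant
variance axis, which matches the described phenotype: a continuous
spectrum of abnormality severity rather than discrete morphs. The
`acceptance.R` script recomputes these compositions from scratch on every
run.

**What the generator does not emulate:** flagella, acrosome biochemistry,
3D structure, staining heterogeneity, imaging aberrations beyond Gaussian
blur plus additive Gaussian noise (shot noise is immaterial at the
contrast used), within-male correlation of cell shapes, and any
correlation structure between shape parameters. Passing tests therefore
demonstrate that the pipeline recovers planted effects of realistic size
under idealized independence — not that real micrographs would segment or
cluster equally cleanly.

## Images: rasterization and segmentation

Rasterization fills the polygon on a pixel grid (centres at
$(i-\tfrac12)\,\mathrm{px}$, y upward), applies Gaussian blur, then
additive Gaussian noise, and clamps to [0, 1]; 16-bit TIFF is the on-disk
format. Segmentation thresholds with Otsu's method by default —
parameter-free and adequate for high-contrast DAPI-like material; a fixed
threshold is available for tests — labels connected components, fills
holes, applies physical area bounds, and discards components touching the
border.

Outline extraction traces the border-pixel chain, pushes each vertex half
a pixel along the outward normal (outer pixel-boundary convention), and
smooths with a circular moving average before resampling. The smoothing
window adapts to the pixel size (about three pixels of arc, capped at 2%
of the perimeter): pixel zigzag otherwise inflates perimeter estimates by
roughly 5%, while a window fixed at 2% of the perimeter would blunt the
hook tip at fine pixel sizes. With this choice a rasterized disc's
perimeter and area are recovered to well under 1%, and the planted hook
apex survives the raster round trip to within ±1 profile index.

## Consensus shapes

Outlines resampled to a common vertex count are aligned by landmark
(apex to vertex 1, fixing index correspondence with a biologically
meaningful point), centred, optionally unit-scaled, and rotated to the
running mean by a rotation-only Kabsch fit iterated to a hard tolerance
(mean movement below $10^{-6}$ of the mean radius). Reflections are never
applied — a mirrored cell is biological information, not an alignment
nuisance. The consensus is the vertexwise mean with a per-vertex radial
interquartile envelope. Landmark-then-Procrustes was chosen over full
generalized Procrustes because the apex fixes correspondence cheaply and
interpretably; the vertexwise mean after alignment is this package's
documented averaging scheme.

## Embedding and clustering

`embed_profiles()` is an exact-gradient t-SNE (Student-t kernel,
perplexity calibration by bisection, early exaggeration, momentum and
adaptive gains), deterministic for a fixed seed, with defaults matching
the published analysis settings (perplexity 100, 1000 iterations). At the
dataset sizes used for angle profiles the exact $O(n^2)$ gradient is
ample.

Clustering is agglomerative Ward (on Euclidean distances, `ward.D2`) cut
at `k`. Two feature spaces are supported and recorded in the result: the
t-SNE embedding (the visual-clustering route) and the raw 100-vector
profiles (seed-free, the default for reproducible composition
statistics). When `k` is not given, it maximizes the mean silhouette over
2–8 — an explicit rule replacing by-eye dendrogram cutting.

Per-cluster sex composition reports $\hat p = n_X/(n_X+n_Y)$ with the
standard error of proportion $\sqrt{\hat p(1-\hat p)/n}$ and a one-sample
Z-test against 0.5, Holm-corrected across clusters; unlabelled cells are
excluded and counted separately, and the cluster proportions aggregate
exactly to the population proportion.

For grading mutant cohorts, `rank_clusters_by_reference()` orders clusters
by the mean squared vertex distance between each cluster's consensus and a
wild-type reference consensus (unit-scaled alignment). With the default
planted effects, a `k = 3` grading (normal / intermediate / severe) makes
the extremes statistically stable; the per-cluster X proportions sit only
two to three standard errors from one half, so the directionality of the
gradient — normal-most cluster X-enriched, most deviant cluster
Y-enriched — is recovered in about 90% of seeds at 1000 cells, and the
test suite estimates that rate on a 60-seed panel.

## Capture/recapture matching

Candidate pre/post pairs are all cross-phase pairs within a stage-radius
(coordinates are only comparable within one slide; mixing slides is an
error). Scoring is Gaussian-window SSIM (11 × 11, σ = 1.5, stability
constants $C_1 = (0.01L)^2$, $C_2 = (0.03L)^2$) averaged over dyadic
scales. Because the FISH chromatin-swelling step dilates nuclei by roughly
10% and SSIM is sensitive to that misregistration, the scorer searches a
small set of shrink factors (0.85–1.0) applied to the post image and keeps
the best score — register-then-compare. Without the scale search,
true-pair scores fall below wrong-neighbour scores for a nontrivial
fraction of cells; with it, re-identification on the synthetic slide
battery is essentially perfect. Assignment is greedy one-to-one in order
of descending similarity, ties broken by lowest id, with a configurable
acceptance threshold (default 0.5; the threshold used in the original
study is not published, so this is a plain configuration value).

## Swim-up statistics

Counts are modelled as X ~ Binomial(cells, p) with logit(p) linear in the
fraction index and slope 0 for freeze/thaw-killed sperm (the negative
control). The analysis model is beta regression with a logit link and a
common precision $\varphi$: $y_i \sim \mathrm{Beta}(\mu_i\varphi,
(1-\mu_i)\varphi)$, $\mathrm{logit}(\mu_i) = x_i^\top\beta$, fitted by
BFGS on $(\beta, \log\varphi)$ with analytic gradients and least-squares
starting values on the logit scale. The binomial generator makes this a
quasi-true model — the mean structure matches exactly, the dispersion
approximately — which is what the CI-coverage acceptance check exploits.
Choices worth noting:

* boundary proportions (0 or 1) are shrunk by $(y(n-1)+\tfrac12)/n$
  before fitting, since the beta likelihood is undefined at the boundary;
* the fraction index enters as a numeric trend by default (the published
  fraction profiles are monotone and the scientific question is the
  slope's sign and genotype dependence); a categorical mode is available;
* rank-deficient designs error naming the aliased columns;
  non-convergence errors carrying the optimizer's last state.

Likelihood-ratio tests use $\chi^2 = 2(\ell_{\text{full}} -
\ell_{\text{red}})$ with the parameter-count difference as degrees of
freedom; a reduced model beating the full model beyond tolerance is
reported as an optimization failure, not silently clamped.

The two-proportions Z-test uses the pooled variance with Yates continuity
correction on by default: the published two-decimal p-values for the
embryo-resorption counts are consistent with the continuity-corrected
pooled test (and with R's `prop.test`) and not with the uncorrected test.
Both modes are exposed. The exact binomial test uses the
minimum-likelihood two-tailed definition (summing all outcomes no more
likely than the observed one), with doubled-one-tail as an option; the
rank-sum test is exact for combined samples up to 20 without ties and a
tie-corrected normal approximation otherwise.

## Seeds and reproducibility

Every stochastic function takes a seed and runs on a private RNG stream,
restoring the caller's `.Random.seed` afterwards. `run_pipeline()` derives
per-stage seeds deterministically from one pipeline seed and logs them in
the manifest, together with package version, configuration and MD5
digests of every output file; identical configurations produce identical
digests. Intermediates are plain files (CSV, SVG, TIFF) by design —
inspectable and diffable.

## Problem sizes

The test suite and acceptance script run simulations at the scale the
scientific claims refer to: 10 males × 6 fractions × 400 cells for the
swim-up recovery (200 replicates), 400–500 replicate null fits for the
calibration checks, 500–2000 cells for clustering and composition, 50
nuclei for capture/recapture, and a 60-seed panel for the directionality
rate. These sizes were chosen so each rate estimate's Monte-Carlo error is
small relative to the tolerance being checked.

## Known limitations

* The generator's independence assumptions (between parameters, between
  cells) are idealizations; real morphometry data have correlated
  parameters and per-male structure (no mixed-effects layer is provided,
  matching the pooled-count analysis it emulates).
* The regularity formula is a documented stand-in; published values
  computed with a different bounding-shape definition are not directly
  comparable.
* SSIM here is plain multi-scale SSIM; the starred MS-SSIM variant used in
  the original imaging workflow has modifications that are not restated in
  the source describing it, and the matching task only needs a ranking
  score.
* Beta-regression inference uses asymptotic (Hessian-based) standard
  errors; no small-sample correction is applied.
* t-SNE is exact, not Barnes-Hut: quadratic memory limits it to a few
  thousand profiles, which covers the intended use.
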