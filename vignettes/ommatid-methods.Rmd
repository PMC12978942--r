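---
title: "Quantifying ommatidial mosaics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ommatidial mosaics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ommatid)
```

## The generative model

The package treats a butterfly retina as a hexagonal lattice of ommatidia.
Each ommatidium belongs to one of three classes set by the opsins of its
R1/R2 photoreceptors — UV-UV, B-B or UV-B — and class membership is drawn
independently per lattice site from class proportions interpolated linearly
along the dorsoventral (dv) axis between a dorsal and a ventral triple.
Conditional on class, every blue (B) photoreceptor independently
co-expresses the long-wavelength (LW) opsin with probability `p`
(also dv-interpolated). The screening pigment is **red** exactly when at
least one R1/R2 cell is LW-positive, and red pigment is what turns the
eyeshine of an ommatidium from yellow to red. This "at least one" rule is
the unique pigment rule consistent with the quadratic structure of the
yellow-eyeshine equation,

$$\mathrm{Yellow} = UVUV + (1-p)^2\,BB + (1-p)\,UVB,$$

since $(1-p)^2$ is the probability that neither B cell of a B-B ommatidium
co-expresses and $(1-p)$ that the single B cell of a UV-B ommatidium does
not. UV-UV ommatidia carry no B cell and are always yellow — the model
cannot produce red UV-UV ommatidia, and the generator never does.

`fit_coexpression()` inverts this equation by least squares. Substituting
$q = 1-p$ gives $BB\,q^2 + UVB\,q + (UVUV - Y) = 0$. Because the prediction
is strictly increasing in $q$ whenever $BB + UVB > 0$, at most one root lies
in $[0,1]$ and the closed form is exact; the discriminant simplifies
algebraically to $(UVB + 2\,BB\,q)^2$, so the square root is
well-conditioned and the round-trip
`fit(predict(p))` reproduces `p` to better than $10^{-9}$ across the
parameter space (verified against a $10^{-6}$-step grid-search minimizer in
the test suite).

Three edge regimes are handled explicitly rather than silently:

* **Infeasible observations.** The attainable range of the model is
  $[UVUV, 1]$. An observed yellow fraction below the $UVUV$ floor returns
  the boundary estimate `p_hat = 1` with `feasible = FALSE` and a positive
  squared residual.
* **Unidentifiable retinas.** With $BB = UVB = 0$ the prediction is
  constant; `p_hat` is `NA`, `identifiable = FALSE`, and the fit is
  feasible only when the observation equals $UVUV$. Returning an arbitrary
  `p` here would be meaningless.
* **Ambiguous roots.** Two admissible roots require a degenerate
  configuration that cannot arise from valid proportions; defensively, the
  root nearer 0.5 is taken and the fit is flagged `ambiguous`.

The fit is intended for **group means** (`fit_group_p()`), since eyeshine
and staining usually come from different individuals. `bootstrap_group_p()`
adds a nonparametric bootstrap over individuals as a clearly separated
extension for uncertainty reporting; the group-mean point estimate itself
involves no resampling.

## What the synthetic generator emulates — and what it does not

`generate_mosaic()` plus the three renderers give every pipeline stage an
input with exact ground truth:

* **IHC sections** (`render_ihc_section()`): a 3-channel (UV1, UV2, B)
  8-bit raster. Each ommatidium contributes two cell disks of radius
  `0.55 r` offset `±0.45 r` from the ommatidium centre (`r =
  omm_radius_px`, default 8 px). The stained area of a cell is
  `fill_fraction` × its full footprint, realized by keeping exactly the
  `k` pixels closest to the cell centre, so measured fill fractions are
  correct to one pixel. Fill fractions are drawn
  N(`fill_fraction_mean` = 0.85, `fill_fraction_sd` = 0.03) and truncated
  to `fill_fraction_range` = [0.7, 1]; below ≈ 0.67 the two cell disks
  separate and one ommatidium would segment as two components, so the
  truncation encodes the near-complete tiling seen in real stains.
* **Eyeshine photographs** (`render_eyeshine()`): the dv axis is tiled into
  non-overlapping bands; each ommatidium is one disk colored from a red
  (220, 45, 25) or yellow (235, 195, 45) palette, chosen so the red
  chromaticity R/(R+G) separates the classes with a wide margin around the
  0.60 default threshold. A `resolution_gradient` of `g` allocates `g`
  times more lattice rows to the most ventral image than the most dorsal,
  emulating the higher ommatidial counts of ventral photographs.
* **Reflectance stacks** (`render_reflectance_stack()`): per-ommatidium
  spectra on the 500–800 nm grid are a logistic rising edge (half-maximum
  560 nm dorsally, width 12 nm) times a logistic tapetal cutoff (700 nm,
  width 7.5 nm), scaled to a 0.85 plateau, which leaves reflectance nearly
  absent above 730 nm. Red ommatidia are attenuated by 50% inside the
  550–660 nm pigment band (8 nm soft edges) — this both depresses the band
  and lowers the red peak relative to yellow. The rising edge red-shifts by
  `dv_redshift_per_unit` (default 15 nm) per unit dv position, emulating
  the longer optical path of ventral ommatidia.

Gaussian read noise (`noise_sd`, 8-bit units) is added to every pixel and
values are clipped to [0, 255] — saturation behaves like a real 8-bit
camera. The generator does **not** model autofluorescence, antibody
cross-reactivity, uneven illumination, optical blur between neighbouring
ommatidia, pupil-response pigment migration, or eye curvature. Passing
tests on synthetic data therefore validate the *computational* pipeline —
segmentation, counting rules, QC rules, the estimator — not the
immunostaining or optics themselves; on real images the binarization step
is the component most exposed to un-modelled structure, which is why a
fixed-threshold override and a manual-count import path exist.

## Segmentation and classification choices

The merged mask is the pixelwise OR of the three channel masks (whether
the original analysis thresholded a composite image instead is unknowable
from the text; OR is the conservative union semantics and is asserted as an
invariant). Components are 8-connected, matching the MATLAB default the
original `bwareafilt` step implies, and are labelled in raster-scan order
of their first pixel so output is deterministic. The area filter defaults
to `[0.3, 3]` × the median component area, computed in a first pass — a
scale-free default robust to magnification. Binarization defaults to Otsu
per channel on the 8-bit histogram (lowest-threshold tie-break); a channel
whose foreground/background mean contrast is below `min_contrast` (30) is
declared blank, because Otsu applied to pure noise would split it in half
and flood the merged mask — this matters whenever an antibody channel is
genuinely empty, e.g. UV2 in a UV1-only retina.

Positivity uses the inclusive rule: a component is positive in a channel
when ≥ 4% of its pixels are foreground there ("at least 4%"), and
UV-positive means positive in UV1 *or* UV2 (double-positive UV cells count
once as UV). Calls: UV only → UV-UV, B only → B-B, both → UV-B, neither →
unclassified. Unclassified components are counted and reported but excluded
from proportions; their count doubles as a tiling-quality metric.

The cross-section rule works on the *cell-level* blue-photoreceptor
proportion, $(2\,n_{BB} + n_{UVB}) / (2\,n_{total})$, because "proportion
of blue photoreceptors" is a statement about cells, not ommatidia. The
exclusion is strict ("more than 5%"): a difference of exactly 5 percentage
points is kept. A $10^{-12}$ guard keeps hand-computable exact-boundary
cases (0.50 vs 0.55) from being excluded through floating-point
representation.

## Eyeshine and reflectance choices

"Ventral half" is read as the last $\lceil n/2 \rceil$ images of the
ordered series, by image count — the images tile the axis without overlap
and no anatomical landmark is available in a count table. Spot detection is
provided for synthetic renders and convenience (threshold on mean-channel
luminance, connected components, per-spot mean RGB); it does not split
touching spots by local maxima because rendered spots never overlap, and
real analyses are expected to use the manual-count CSV import. The red call
is `R/(R+G) >= 0.60`, scale-invariant by construction; `R+G = 0` is
reported as unclassifiable rather than guessed.

Reflectance is kept in raw 8-bit intensity units: the constant-photon-flux
calibration (`shutter_time = target / flux_rate`, target $10^{15}$ photons)
makes planes comparable across wavelengths, so no white-standard
normalization is applied by default. Spectra whose maximum falls below 50%
or above 95% of the dynamic range are flagged `excluded_low` /
`excluded_saturated` — exactly one status per spectrum. Group comparisons
use Welch t-tests by default (a robust default where the original wording
says only "t-test"; pooled variance is available via `var_equal = TRUE`)
or a per-wavelength one-way ANOVA for the three eye regions, with
Holm–Bonferroni over the 31 wavelengths. Holm is delegated to
`stats::p.adjust` and cross-checked in the tests against a literal
sequential-rejection enumeration. The yellow-vs-red peak excess is reported
as $(\text{yellow} - \text{red})/\text{red}$ — the denominator choice is a
package convention, documented here because the ratio is otherwise
ambiguous.

## Cohort statistics choices

Clustering of class-proportion triples is UPGMA on Euclidean distances via
`stats::hclust`, validated exactly against an $O(n^3)$ re-averaging oracle
for $n \le 12$. The compact letter display assigns one letter per maximal
clique of the non-significance graph (via `igraph::max_cliques`), which
guarantees the defining property — two groups share a letter iff their
Holm-adjusted pairwise test is non-significant — with deterministic letter
order. The two-way species × sex ANOVA uses Type-II sums of squares
(`car::Anova`) because the real design is unbalanced and no decomposition
was stated; on balanced designs Type II coincides with the textbook
decomposition, which the tests assert. When the residual sum of squares is
numerically zero, Type-II sums of squares are computed by explicit model
comparison and affected F statistics are reported as `Inf` with a
`perfect_fit` flag instead of erroring or capping silently.

qPCR triplicates are discarded when the sample standard deviation
($n-1$ denominator) strictly exceeds 1. Relative expression assumes 100%
efficiency, `UV2:UV1 = 2^(meanCt_UV1 - meanCt_UV2)`, reported with its
log2; LW and EF1a serve only as presence/quality controls, since the
UV1:UV2 ratio is internally normalized by construction. A gene with no
record yields a "not detected" result; a gene whose replicates were all
discarded flags the sample for re-testing rather than producing a value.

## Problem sizes and reproducibility

The test suite and the acceptance script size their simulations to run in a
few minutes on one CPU while keeping estimates statistically meaningful:
100 replicate eyes of 3,700 ommatidia (50 × 74) per co-expression
condition; a 101 × 20 (p, proportions) grid for the round-trip identity;
500 random masks up to 64 × 64 for the segmentation oracle; sections of
180–324 ommatidia for end-to-end recovery; 2,000 simulated null datasets
(24 spectra each) for the familywise-error estimate; 100 simulations of two
planted 10-point clusters; and a 5 × 5 (proportions, p) grid at 10,000
ommatidia for generative consistency. Every random draw is seeded —
`mosaic_spec(seed =)`, the `seed` arguments of the renderers, and the
`--seed` flag of `scripts/acceptance.R` — and identical seeds give
bit-identical mosaics and renders.

## Known limitations

* The generator's lattice is geometrically idealized (no curvature, no
  missing ommatidia, constant footprint size); real sections show oblique
  cuts and partial ommatidia that the area filter must absorb.
* Binarization quality on real micrographs is unvalidated here; the 4% rule
  interacts with threshold choice, and the fixed-threshold override should
  be preferred when staining intensity varies systematically.
* The co-expression estimate assumes one `p` shared by all B cells of a
  region ("equal probability" assumption) and exact class proportions; a
  per-cell heterogeneous model is out of scope.
* Dorsal red pigment may follow a different mechanism than the ventral
  Bernoulli(p) process; the generator exposes `p_coexpress_dorsal`
  separately but the package takes no position on its interpretation.
* No LW antibody channel exists anywhere in the pipeline; `p` is inferred,
  never directly observed.
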