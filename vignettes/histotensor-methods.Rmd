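---
title: "Quantitative histology and DTI-histology statistics with histotensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative histology and DTI-histology statistics with histotensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histotensor)
```

histotensor implements a quantitative-histology pipeline for stained brain
sections and its statistical link to diffusion-tensor MRI: structure-tensor
anisotropy of myelin-stained photomicrographs, automated cell counting on
Nissl-stained sections, DTI scalar metrics, and the ROI-level statistics
relating the two modalities. Because the package is developed and validated
without access to animal data, every stage comes with a synthetic-data
generator that plants known ground truth; this vignette explains the models,
the parameters that matter, the numerical choices, and what the synthetic
validation does and does not establish.

## Structure-tensor anisotropy of stained sections

Local texture orientation in a grayscale section image $I$ is summarized by
the windowed structure tensor

$$
J \;=\; \sum_{w} \begin{pmatrix} I_x^2 & I_x I_y \\ I_x I_y & I_y^2 \end{pmatrix},
$$

where $I_x, I_y$ are directional-derivative images obtained by convolving
$I$ with the $x$- and $y$-derivatives of a 2D Gaussian (kernel size 11 px,
$\sigma = 3$ px by default) and the sum runs over a $128 \times 128$-pixel
window. With eigenvalues $\lambda_1 \ge \lambda_2 \ge 0$, the anisotropy
index is

$$
\mathrm{AI} \;=\; \frac{\lambda_1 - \lambda_2}{\lambda_1 + \lambda_2} \in [0, 1],
$$

the standard two-dimensional coherence measure of structure-tensor analysis:
0 for isotropic texture, 1 for perfectly aligned fibers. This is the 2D
analogue of FA in DTI. The reported orientation is the fiber direction (the
eigenvector of $\lambda_2$, i.e. the direction of least intensity change),
in radians in $[0, \pi)$ from the image x axis.

Numerical choices:

* **Gradient calibration.** An 11-pixel kernel truncates a $\sigma = 3$
  Gaussian at $1.67\sigma$, which would shrink the response to a unit-slope
  ramp to about 0.71. The kernels are rescaled by their first moment so that
  a unit ramp yields exactly 1; AI, a ratio, is unaffected, but derivative
  fields become directly interpretable.
* **Boundary handling** is mirror reflection for every convolution in the
  package.
* **Aggregation.** The default is non-overlapping tiling (one tensor per
  $128\times128$ tile, border remainders dropped), because the downstream
  use is ROI summaries; a per-pixel sliding box sum is available via
  `st_config(aggregation = "sliding")`. Both were implemented because the
  phrase "summed within a window" is genuinely ambiguous between the two.
* **Zero-gradient windows** have $\lambda_1 + \lambda_2 = 0$; AI is defined
  as 0 there.
* **ROI summaries** report both the AI of the mask-summed tensor and the
  mean of per-tile AI values. These differ when a region mixes orientations
  — two orthogonal coherent tiles cancel in the tensor sum (AI 0) while the
  mean of their AIs is 1 — so `roi_ai()` returns both.
* **RGB input** is converted by luminance (0.2125 R + 0.7154 G + 0.0721 B);
  stain polarity is irrelevant to a derivative-based method, so no
  inversion is performed.

```{r st-demo}
fib <- gen_fiber_image(fiber_image_spec(coherence = 1, seed = 1))
round(median(st_analyze(fib$image)$tiles$ai), 3)
```

## Automated cell counting

Counting on Nissl-stained RGB photomicrographs proceeds in four stages.

1. **Preliminary segmentation.** The *speed image* is the Sobel gradient
   magnitude of the green channel (cell outlines are sharpest in green),
   rescaled to $[0,1]$. A two-phase piecewise-constant (Chan–Vese) active
   contour is evolved on this field from a seeded random binary mask with
   smoothing weight 0.2 and at most 300 iterations. The high-gradient phase
   traces cell outlines; speckles under 100 px are removed, a 5-px
   morphological closing seals the pixel-scale raggedness of the contour,
   holes are filled (outlines enclose flat cell interiors), and components
   are labelled with 8-connectivity.
2. **Ellipse triage.** Every component gets an equivalent ellipse from its
   second-order central moments. Major axis $< S = 30$ px: noise, discarded.
   Major axis $> B = 140$ px: under-segmented (probably fused cells). In
   $[S, B]$: accepted as one cell.
3. **Marker extraction** for under-segmented components. The intensity image
   is the HSV value channel, Gaussian-filtered ($\sigma = 3$ px) and
   inverted so somata are maxima. Markers are the regional maxima of its
   H-maxima transform (depth $h = 0.1$), restricted to the component, then
   filtered by three rules: intensity $> I = 0.5$; pairwise distance
   $> D_s = 70$ px; pairwise intensity difference $> D_i$ (1 unit on the
   8-bit scale, i.e. $1/255$). Pairs violating a rule keep the brighter
   marker, processed in deterministic order (descending intensity, then row,
   then column).
4. **Watershed correction.** Each under-segmented component is split by
   marker-based region growing on the intensity landscape, one region per
   marker; a component with fewer than two surviving markers is kept as a
   single cell. Cell density is $\rho = N/A$ with $A$ the ROI area in
   $\mu m^2$ (pixel count $\times$ pixel area, default
   $0.013\,\mu m^2$/px), reported on the $\times 10^{-2}$ cells/$\mu m^2$
   scale.

**Why threshold dynamics for Chan–Vese.** The package minimizes the
two-phase piecewise-constant Mumford–Shah energy with a threshold-dynamics
(MBO-style) scheme: each sweep recomputes the two region means, diffuses the
region indicator with a small Gaussian ($\sigma = 2$ px) and rethresholds it
against the data term, with the smoothing weight scaling the
diffusion-threshold regularizer. We chose this minimizer over the classical
semi-implicit level-set discretization after observing that the latter,
started from an iid random binary mask, spends most of a 300-iteration
budget breaking the symmetry of the initialization (both region means start
equal) and clearing large flat regions, where its curvature coefficients
degenerate into plain neighbor averaging. The threshold-dynamics sweep
breaks the symmetry in its first iteration (which applies the pure data
threshold, since a regularizer has nothing meaningful to say before phases
exist) and reaches a fixed point in a few dozen sweeps; on our synthetic
sections the converged mask is identical across initialization seeds, which
is exactly the reproducibility one wants from a counting pipeline. The
energy being minimized, the random-mask initialization, the smoothing
weight, and the iteration cap are unchanged.

Further numerical conventions: `D_i` is dimensionless on an 8-bit-equivalent
scale because a threshold of 1 on $[0,1]$ intensities would suppress every
marker pair; the `d_i_scale` config entry (default $1/255$) makes the
interpretation explicit. Components touching the image border are triaged
normally; ROI membership of a cell is decided by centroid inclusion.
H-maxima depth and the marker pre-filter $\sigma$ are free parameters of the
method (defaults 0.1 and 3 px) exposed in `cell_count_config()`.

```{r count-demo}
g <- gen_nissl_image(nissl_image_spec(seed = 1))
d <- count_and_density(g$image)
c(planted = g$count, counted = d$N, density_x1e2 = round(d$rho_x1e2, 3))
```

## DTI scalar metrics and the tensor fit

From sorted diffusion-tensor eigenvalues
$\lambda_1 \ge \lambda_2 \ge \lambda_3$ (mm$^2$/s):

* $\mathrm{MD} = (\lambda_1+\lambda_2+\lambda_3)/3$,
  $\mathrm{AD} = \lambda_1$, $\mathrm{RD} = (\lambda_2+\lambda_3)/2$;
* $\mathrm{FA} = \sqrt{3/2}\,\lVert\lambda - \mathrm{MD}\rVert / \lVert\lambda\rVert$;
* Westin shape indices in the $\lambda_1$-normalized convention,
  $CL = (\lambda_1-\lambda_2)/\lambda_1$,
  $CP = (\lambda_2-\lambda_3)/\lambda_1$, $CS = \lambda_3/\lambda_1$, which
  sum to 1 identically. The sum-normalized variant is available via
  `westin = "sum"`; the $\lambda_1$ form is the default because the cited
  index family is usually stated that way and the partition-of-unity
  property makes ROI comparisons interpretable.

`fit_tensor()` is an ordinary least-squares fit of log-signal against the
six unique tensor elements plus $\log S_0$ — exact on noiseless log-linear
data, which the tests exploit: simulate with `gen_dwi()` under the default
acquisition geometry (4 b0 + 60 quasi-uniform directions at
$b = 2000$ s/mm$^2$) and the fit must return the generating eigenvalues to
$10^{-9}$. Non-positive signals are excluded with a warning; negative fitted
eigenvalues are kept and flagged rather than clamped, matching common
practice so that downstream scalars reflect the raw fit.

## The statistics layer

The ROI table holds one record per (animal, hemisphere, bregma level,
region) with AI, CD (on the $\times 10^{-2}$ cells/$\mu m^2$ scale), FA and
AD. The scheme has cc, ec and S1 at +1.08 and −1.60 mm from bregma, plus ic
and VPL at −3.60 mm.

* **Group contrasts**: pooled-variance Student's t per
  (level, region, hemisphere, measure), Welch behind a flag. Pooled is the
  default because the source analyses used a conventional unpaired t test
  whose printed statistics cannot adjudicate the variant; the choice is
  documented, not asserted.
* **FDR**: Benjamini–Hochberg q values via the step-up rule. The default
  family is one family per measure across all levels, regions and
  hemispheres (44 tests split into two families of 22); a single pooled
  family is available. Family composition is a genuine unknown of the
  original analysis — the printed significance thresholds do not uniquely
  determine it — so it is configurable and recorded in the output.
* **Regressions**: OLS of FA or AD on AI and CD with intercept, fitted per
  region family (each single region, cc+ec at every level, cc+ec+ic and
  S1+VPL at −3.60 mm), pooling both groups and both hemispheres. One BH
  family covers all regression p values. The scatter projection is
  $\chi = \beta_{AI}\,\mathrm{AI} + \beta_{CD}\,\mathrm{CD}$ — deliberately
  without the intercept, matching its published definition; the correlation
  of the response with $\chi$ equals the multiple correlation $\sqrt{R^2}$,
  which the tests verify numerically.

## What the synthetic generators emulate

* `gen_fiber_image()` mixes an aligned texture (a smooth 1D profile constant
  along the fiber axis, so its gradient energy is entirely across-fiber)
  with isotropic smoothed noise; the `coherence` weight in $[0,1]$ moves the
  texture continuously from isotropic to perfectly aligned, and tile-median
  AI is monotone in it.
* `gen_nissl_image()` plants dark elliptical somata (major axis 85–110 px ≈
  10–12.5 $\mu m$ at the default pixel size, safely inside the $[S, B]$
  triage regime) with smooth super-Gaussian profiles and a blue-violet
  Nissl-like palette on a light background, at about
  $0.3 \times 10^{-2}$ cells/$\mu m^2$. A `fraction_touching` share of cells
  is planted as overlapping pairs offset along their common major axis by
  $0.95\times$ the mean major axis: the fused component's moment ellipse
  then exceeds $B$ while the two intensity peaks stay farther apart than
  $D_s$. Cells are placed on a jittered grid (pairs on a checkerboard of
  interior sites so two pairs never merge); paired cells receive distinct
  staining depths, emulating natural staining variability and keeping their
  markers separable under the $D_i$ rule. Ground truth (centroids, axes,
  depths, pair ids) is returned with the image.
* `gen_dwi()` is the noiseless mono-exponential forward model
  $S = S_0 e^{-b\,g^\top D g}$ plus optional Gaussian noise at a given SNR
  (Rician behind a flag). Gaussian is the default because the generator's
  job is to validate fitting algebra, not scanner physics.
* `gen_cohort()` draws independent Gaussians per record from region-wise
  group means and SDs; the default parameterization transcribes the
  published region-wise AI and CD summary statistics for sham (n = 6) and
  mTBI (n = 8) groups in both hemispheres. ROI-level FA/AD summary
  statistics are not published, so their defaults are synthetic: FA mean
  $= 0.8 \times$ AI mean (SD 0.06) and AD mean
  $= (0.8 + 0.6\,\mathrm{AI}) \times 10^{-3}$ mm$^2$/s (SD
  $0.08 \times 10^{-3}$), chosen to give white/gray-matter values in the
  physiological range.

What passing tests show — and what they do not. The generators produce
clean, well-separated, consistently stained objects; real sections have
stain gradients, debris, anisotropic illumination, out-of-focus blur and
within-animal correlation across regions, none of which are modelled (cohort
draws are independent across regions, a documented simplification). Exact
count recovery on synthetic images therefore validates the algorithm's
logic — triage thresholds, marker rules, watershed correction — not its
accuracy on real tissue, which in the original workflow was established by
comparison with expert manual counts.

## Validation problem sizes

The shipped test-suite and acceptance-script sizes are: structure-tensor
oracles on $512\times512$ images; count recovery on ten
$768\times768$ images of 24 cells each (10% planted as touching pairs), with
the pair-heavy regime exercised at `fraction_touching = 0.5`; tensor fits at
the full 64-volume acquisition geometry; BH against exhaustive enumeration
for all family sizes up to 8; a 1000-permutation null for the regression F;
and 500 simulated cohorts for the group-contrast power pattern (the
ipsilateral −3.60 mm external-capsule AI and CD contrasts flag in well over
80% of cohorts while every rostral +1.08 mm contrast stays unflagged in
over 90%). These sizes were chosen so the whole validation runs comfortably
on a laptop-class single core.

## Known limitations

* 2D only: sections are analyzed as planes; no 3D structure tensors and no
  stereological correction for 30 $\mu m$ section thickness.
* No stain normalization or color deconvolution; channel conventions (green
  for edges, value channel for markers) assume Nissl-like staining.
* The counting thresholds $(S, B, I, D_s, D_i, h)$ are calibrated for the
  default 0.013 $\mu m^2$/px acquisition scale and must be rescaled for
  other magnifications.
* Voxel-wise group statistics (permutation testing, cluster enhancement)
  and image registration are outside the package's scope; the statistics
  layer starts from ROI tables.
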