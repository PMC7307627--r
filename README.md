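# histotensor

Quantitative histology of stained brain sections and its statistical link
to diffusion-tensor MRI, for neuroimaging and neuropathology researchers
who want an auditable, fully scriptable version of a microscopy–MRI
correlation workflow.

The package implements four connected stages:

1. **Structure-tensor (ST) anisotropy** of myelin-stained photomicrographs.
   Gaussian-derivative images (11-px kernel, σ = 3 px) form the pixelwise
   tensor `[Ix², IxIy; IxIy, Iy²]`, summed over 128 × 128-pixel windows and
   eigen-decomposed; the anisotropy index is
   `AI = (λ₁ − λ₂)/(λ₁ + λ₂) ∈ [0, 1]`, the 2D texture analogue of FA.
2. **Automated cell counting** on Nissl-stained RGB sections: Chan–Vese
   active contours on the green-channel gradient (smooth factor 0.2,
   ≤ 300 iterations), equivalent-ellipse triage of components (major axis
   < S = 30 px → noise, > B = 140 px → under-segmented), markers from the
   H-maxima transform of the filtered HSV value image under three rules
   (intensity > I = 0.5, spacing > D\_s = 70 px, intensity gap > D\_i = 1
   8-bit unit), and marker-based watershed splitting. Cell density is
   ρ = N/A in cells/μm².
3. **DTI scalar metrics** from sorted tensor eigenvalues — FA, MD, AD, RD
   and the Westin CL/CP/CS shape indices (CL + CP + CS = 1) — with an
   ordinary least-squares log-linear tensor fit for simulated
   diffusion-weighted signals (4 b0 + 60 directions, b = 2000 s/mm²).
4. **ROI statistics**: pooled-variance unpaired t tests per region with
   Benjamini–Hochberg q values, multiple regression `FA|AD ~ AI + CD` over
   region families, and the scatter projection
   `χ = β_AI·AI + β_CD·CD`.

Every stage has a synthetic generator with machine-readable ground truth
(oriented fiber textures, Nissl-like cell images with planted counts,
noiseless/noisy DWI signals, sham/mTBI cohorts with region-wise means and
SDs), so the whole pipeline is testable without animal data.

## Worked example

```r
library(histotensor)

# --- ST anisotropy of a coherent fiber texture ---------------------------
fib <- gen_fiber_image(fiber_image_spec(coherence = 1, seed = 1))
st  <- st_analyze(fib$image)
median(st$tiles$ai)
#> [1] 0.9943246

# --- cell counting with planted ground truth -----------------------------
g <- gen_nissl_image(nissl_image_spec(seed = 1))   # 24 cells, 1 touching pair
d <- count_and_density(g$image)
d
#> <cell_density> N = 24 cells, A = 7667.7 um^2, rho = 0.313 x 1e-2 cells/um^2

# --- DTI scalars and a round-trip tensor fit -----------------------------
scalars_from_eigenvalues(c(1.7, 0.3, 0.3) * 1e-3)[, 1:7]
#> # A tibble: 1 x 7
#>      FA       MD     AD     RD    CL    CP    CS
#>   <dbl>    <dbl>  <dbl>  <dbl> <dbl> <dbl> <dbl>
#> 1 0.799 0.000767 0.0017 0.0003 0.824     0 0.176

prot <- dwi_protocol()                       # 4 b0 + 60 dirs, b = 2000
fit  <- fit_tensor(gen_dwi(c(1.7, 0.3, 0.3) * 1e-3, protocol = prot), prot)
max(abs(fit$evals - c(1.7, 0.3, 0.3) * 1e-3))
#> [1] 3.252607e-19

# --- cohort statistics ---------------------------------------------------
coh <- gen_cohort(cohort_spec(seed = 5))     # sham n = 6, mTBI n = 8
out <- analyze_cohort(coh)
subset(as.data.frame(out$t_table), significant,
       select = c(level, region, hemisphere, measure, t, q))
#>   level region    hemisphere measure          t            q
#> 1  -1.6     cc   ipsilateral      CD  -3.624218 1.918118e-02
#> 3  -3.6     ec   ipsilateral      AI   4.766713 1.009443e-02
#> 4  -3.6     ec   ipsilateral      CD -12.869875 4.859989e-07
#> ...
```

The first median says the coherent texture is read as almost perfectly
anisotropic; the counting example recovers exactly the 24 planted cells and
a density of 0.31 × 10⁻² cells/μm²; the tensor fit inverts the noiseless
forward model to machine precision; and the simulated cohort flags the
ipsilateral external-capsule AI decrease and CD increase at the −3.60 mm
level — the epicenter pattern the generator's default parameterization
encodes.

A command-line wrapper over the same functions ships in
`inst/cli/histotensor.R`:

```sh
Rscript inst/cli/histotensor.R simulate nissl --seed 7 --out out/
Rscript inst/cli/histotensor.R cell-count out/nissl.tif --out out/
Rscript inst/cli/histotensor.R run --seed 1 --out out/full
```

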