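# gatefilter

Edge-preserving denoising for respiratory-gated PET: a case-optimized
anisotropic 3D bilateral filter, an automated ROI-driven parameter
search, and a residual 3D U-Net that learns to reproduce the optimized
filter — plus the SUV quantification metrics and a synthetic gated-PET
phantom generator that make every stage testable without patient data.

## Who this is for

Respiratory gating removes motion blur from PET but splits the counts
over (typically) 8 phase gates, so each gate image is noisier than the
ungated image by about `sqrt(8)`. Plain Gaussian smoothing restores the
noise level but erodes lesion SUVmax through the partial volume effect —
unacceptable when SUVmax drives clinical reads. This package is for
image-analysis researchers and physicists who want a reproducible,
scriptable implementation of the alternative: smooth the homogeneous
tissue, keep the edges.

## The method

The bilateral kernel is the product of a spatial and an intensity
Gaussian,

    W(m,n) = exp(-|Pm - Pn|^2 / (2 sigma_S^2)) * exp(-(Im - In)^2 / (2 sigma_I^2)),

with an anisotropic spatial term (`sigma_z = 0.76 sigma_xy`;
`sigma_S = (2 sigma_xy + sigma_z)/3` is the quoted mean). The two free
parameters are selected per gated study by brute force over an 11 x 15
grid (`sigma_S` in [3.1, 5.9] mm, `sigma_I` in [0.1, 10] SUV),
minimizing, jointly over all gates `i` and lesion ROIs `j`,

    S(sigma_S, sigma_I) = sum_ij dSUVmax[i,j]^2 + sum_i dNoise[i]^2,

where both deltas are symmetric fractional differences in percent:
`dSUVmax` of the filtered vs unfiltered gate (signal preservation) and
`dNoise` of the filtered gate's liver coefficient of variation vs the
ungated image (noise matching). A compact residual 3D U-Net with a
logit/sigmoid bypass — `output = sigmoid(logit(clamp(x)) + body(x))`, so
zero body output means identity — is then trained on 32-cube patch pairs
(MAE loss) to reproduce the optimized filter in a single pass.

See the methods vignette (`vignettes/gated-pet-denoising.Rmd`) for the
model details, parameter defaults and design rationale.

## Worked example

Generate a synthetic gated study, pick filter parameters automatically,
and quantify the effect on a gate:

```r
library(gatefilter)

ph <- generate_phantom(phantom_config(seed = 1))
ph
#> <phantom_study> 8 gates, 44 x 44 x 36 voxels, 3 lesions, noise CV 15%, seed 1

sr <- bf_grid_search(ph$study, ph$rois, build_grid(n_s = 5, n_i = 7))
sr
#> <bf_search> best sigma_s = 5.2 mm, sigma_i = 1 SUV (S = 6247.2)

gate <- ph$study$gates[[1]]
bf   <- bilateral_filter(gate, sr$best)
noise_level(gate, ph$rois$liver)   # unfiltered single-gate liver noise
#> [1] 15
noise_level(bf, ph$rois$liver)     # after case-optimized filtering
#> [1] 6.246111
noise_level(ph$study$ungated, ph$rois$liver)  # the target noise level
#> [1] 5.558528

les <- ph$rois$lesions[[3]]        # hottest lesion, FLR ~ 16
delta_frac(suv_max(bf, les), suv_max(gate, les))
#> [1] -2.243354
```

The filtered gate's liver noise (6.2%) moves close to the ungated
reference (5.6%) from the single-gate 15%, while the hot lesion's SUVmax
changes by only about -2% — uniform smoothing that strong would cost far
more. `metrics_report()` assembles the same numbers (SUVmax, noise,
absolute and percent differences, FLR) for all ROIs and image-type pairs
as a data frame.

A command-line interface wraps the same functions for shell pipelines
(`gatefilter phantom | filter | optimize | train | denoise | evaluate`);
see `exec/gatefilter --help`.

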