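# mwiphase

Quantitative two-band interference phase imaging for pixelwise tumor
delineation in hyperspectral diffuse-reflectance cubes.

## The problem and the method

Intraoperative margin assessment in breast-conserving surgery needs a
fast, stain-free way to tell malignant from normal tissue. Malignant
tissue has a higher effective refractive index, so light reflected from
it accumulates a different optical path than light from the surrounding
tissue. Imaged against a flat white-paper reference, that optical-path
difference appears as a wrapped phase offset on each spectral band of a
hyperspectral cube, and the offset depends on wavelength:

- median refractive index of a scattering medium:
  `n_m = c_sc * n_sc + (1 - c_sc) * n_g`
- scattering coefficient (mono-disperse dielectric spheres):
  `mu_sc = 3.28 * pi * r^2 * V_S * (2*pi*r/lambda)^0.37 * (n_sc/n_g - 1)^2.09`
- round-trip phase offset of a tumor at depth `d`:
  `phi(lambda) = wrap(2*pi * 2*dn*d / lambda)`, `dn = n_m(tumor) - n_m(normal)`

The classification feature is the **absolute inter-wavelength phase
shift** between a blue (446.6 nm) and a red (632 nm) band,
`dphi = |wrap(phi_blue - phi_red)|` in `[0, pi]`: zero where the optical
path matches the surroundings, nonzero over tumor. Because red light
penetrates deeper than blue, a deep tumor shows up only in the red band —
stacking per-band phase maps by wavelength (`phase_stack()`) gives a
depth-resolved 3-D phase view. A threshold classifier trained on labeled
shift maps (maximizing Youden's J) labels tumor pixel by pixel, scored by
sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and accuracy.

The package implements the whole chain — ENVI-dialect cube I/O,
white-reference preprocessing (histogram equalization, 256-level
normalization, moving-average filtering), carrier-fringe phase
demodulation (synchronous, analytic-signal, and 2-D Fourier modes),
shift mapping, classification and scoring — plus a physics-based phantom
generator so everything is testable without external data. See the
methods vignette (`vignettes/mwi-phase-imaging.Rmd`) for the model and
design choices.

## Worked example

```r
library(mwiphase)

scene   <- phantom_scene(seed = 42)      # 128-band synthetic specimen
phantom <- render_phantom(scene)
phantom
#> <phantom_output> cube 128 x 160 x 128, 1942 tumor px (9.5% of frame)

cfg <- pipeline_config(output_dir = file.path(tempdir(), "demo"))
res <- pipeline_run(phantom$cube, reference_rows = 1:16, config = cfg,
                    mask = phantom$truth, sample_id = "phantom-42")
res$model
#> <threshold_model> dphi > 0.6059 rad (J = 0.972), pair 445.0 / 630.0 nm
res$metrics
#>    sample_id sen_pct spec_pct fn_ratio_pct fp_ratio_pct accuracy_pct
#> 1 phantom-42   98.97    98.28         1.03        1.725        98.35
```

The run trains a phase-shift threshold on the cube's own truth mask
(pixels with `dphi > 0.61` rad are called tumor), then scores it: 99.0%
of tumor pixels are found with 1.7% false positives among normal tissue.
Phase maps, the shift map, the predicted mask and a provenance manifest
land in `output_dir`.

The bundled ten-specimen benchmark table aggregates with a mean row:

```r
metrics_table(stained_specimen_ratios())
#>    sample_id sen_pct spec_pct fn_ratio_pct fp_ratio_pct
#> ...
#> 11      Mean  90.903    94.01        9.097         5.99
```

A thin command-line front end with `simulate` / `run` / `report`
subcommands is at `inst/cli/mwi.R`.

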