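# fibriquant

Quantitative morphometry of fibrillin microfibrils and aortic tissue
sections, for vascular extracellular-matrix researchers working with AFM
height images, histology/zymography sections and scanning acoustic
microscopy maps.

Fibrillin microfibrils are beads-on-a-string ECM polymers with a
characteristic bead-to-bead repeat (periodicity) of ≈56 nm. Diseases such
as diabetes alter both the repeat distribution and the chain length, and
at tissue scale they remodel the layered aortic media. fibriquant
implements the full measurement chain:

* **AFM morphometry** — scanline flattening, artifact masking, bead
  detection with sub-pixel centroids, greedy chain linking, and
  periodicity/length measurement (`afm_pipeline()`).
* **Distribution statistics** — Lorentzian peak fits of periodicity
  histograms, $A\gamma^2/((x-x_0)^2+\gamma^2)$, with a
  unimodal-vs-bimodal model selection rule, extended-fraction estimates
  with Wilson intervals, and the standard nonparametric group tests
  (`fit_lorentzian()`, `select_modality()`, `fraction_above()`,
  `compare_samples()`).
* **Tissue quantification** — stain area fractions, cubic-spline wall
  straightening, medial thickness, regional gelatinase intensity, and
  per-region acoustic wave-speed statistics with the isotropic conversion
  $v_L = \sqrt{C_{11}/\rho}$, $C_{11} = E(1-\nu)/((1+\nu)(1-2\nu))$
  (`area_fraction()`, `straighten_wall()`, `medial_thickness()`,
  `regional_gelatinase()`, `wave_speed_from_modulus()`).
* **Synthetic data with ground truth** — truncated-Lorentzian periodicity
  presets (control: 56 nm; diabetic: 51/73 nm mixture), log-normal chain
  lengths, rendered AFM chain images and layered tissue sections, so every
  stage is testable without raw study images (`sample_periodicities()`,
  `render_chain_image()`, `render_tissue_section()`).

## Worked example

```r
library(fibriquant)

# render five control-preset microfibrils and measure them back
cfg <- chain_render_config(pixel_scale = 4, image_size = 512,
                           noise_sd = 1, rng_seed = 11)
r   <- render_chain_image(control_preset(), c(10, 15, 8), cfg)
res <- afm_pipeline(r$image)
res
#> morphometry_result: 3 chains, 30 pooled periodicities
#>   mean length 11.0 beads; mean periodicity 57.4 nm
mean(r$periodicities)       # ground truth for the same image
#> [1] 57.43493

# fit the periodicity distribution of a synthetic diabetic group
x <- sample_periodicities(diabetic_preset(), 500, seed = 2)
fit_lorentzian(x, k = 2, bin_width = 2)
#> Lorentzian fit, k = 2, bin width 2 nm, R^2 = 0.983
#>   peak 1: centre 51.08 nm, HWHM 2.71 nm, amplitude 83.8
#>   peak 2: centre 73.31 nm, HWHM 2.32 nm, amplitude 39.4
```

The measured mean periodicity (57.4 nm) matches the generator's truth for
that image to 0.01 nm, and the two fitted centres recover the diabetic
preset's 51/73 nm components; `select_modality(x)` returns 2 for this
sample and 1 for a control sample.

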