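---
title: "Methods: microfibril morphometry and tissue quantification with fibriquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microfibril morphometry and tissue quantification with fibriquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibriquant)
```

## Scope and model

fibriquant quantifies structural remodelling of the vascular extracellular
matrix at two scales. At the nanoscale it measures fibrillin microfibrils in
AFM height images: these polymers appear as beads-on-a-string chains with a
characteristic bead-to-bead repeat (periodicity) near 56 nm, and both the
repeat distribution and the chain length (beads per microfibril) change in
disease. At the tissue scale it quantifies stained aortic cryosections:
collagen/elastin area fractions, medial thickness measured perpendicular to
the intima after spline straightening, regional gelatinase activity from in
situ zymography, and per-region acoustic wave-speed statistics, where the
longitudinal wave speed relates to Young's modulus by
$v_L = \sqrt{C_{11}/\rho}$ with
$C_{11} = E\,(1-\nu)/\bigl((1+\nu)(1-2\nu)\bigr)$.

Because raw images from such studies are rarely deposited, the package ships
a synthetic-data generator that renders beaded-chain height images and
layered tissue sections with complete ground truth. Every analysis stage is
validated by parameter recovery against that truth.

## Periodicity model

Periodicity histograms are modelled as sums of Lorentzian (Cauchy) peaks
$A\,\gamma^2/((x-x_0)^2+\gamma^2)$. The generator presets are:

* **control**: one component centred at 56 nm;
* **diabetic**: two components at 51 and 73 nm with weights 0.7/0.3;
* **combed** (tensioned): single broad peak at 58 nm (control) or a
  55/66 nm mixture (diabetic), shifting mass above 60 nm.

Three generator parameters are modelling choices rather than published
values, fixed once and exposed as arguments:

* **Mixture weights 0.7/0.3** for the diabetic preset. The weights were
  calibrated so that roughly 27% of repeats fall above 65 nm, the reported
  size of the extended sub-population; with truncation the realized
  fraction is ≈0.31.
* **Half-widths of 3 nm** (HWHM). Narrow enough that the 51/73 nm peaks
  are visually distinct and the 56 nm control peak is clean, while the
  Cauchy tails still produce realistic histogram shoulders.
* **Truncation to [30, 120] nm.** Repeats outside this range are
  biologically implausible (below one bead diameter, or beyond maximal
  molecular extension), and published periodicity histograms span roughly
  this range. Sampling is by per-component rejection, so the component
  identity of every draw is retained as ground truth.

Chain lengths (beads per chain) are drawn from a log-normal distribution
moment-matched to the group mean and SD (control 21 ± SD 13; diabetic
18 ± SD 19), rounded and rejection-truncated at ≥ 2 beads. A log-normal is
the natural choice: bead counts are positive, and an SD exceeding the mean
forces strong positive skew that no symmetric distribution can provide.
Truncation and rounding shift the realized mean by ≲ 0.3 beads, well inside
the sampling error at n = 100.

## Synthetic AFM images

Chains are laid along low-curvature random walks: each next bead is placed
at the sampled spacing from the previous one, with a heading change of
SD 12° capped at 25° per step, steered back toward the field centre near
the margins. Because beads are placed directly at the sampled Euclidean
spacing, arc-length and straight-line spacing agree exactly — stronger than
the ≤ 1% agreement a spline-path renderer would give. Placement enforces a
140 nm clearance between chains and 100 nm between non-neighbouring beads
of one chain, so the true chain partition is geometrically unambiguous;
bounded retries produce an informative error when a chain cannot fit.

Beads are radially symmetric Gaussian bumps (σ = bead_radius/2, default
radius 12 nm, amplitude 10 height units) on a field of 4 nm/px. Imaging
nuisances are added in the order scanline offsets (per-row constants,
SD 0.5), white pixel noise (SD 1, i.e. 10% of bead amplitude), and
optionally large bright blob artifacts (radius 30–60 nm, 2.5–4× bead
amplitude) emulating surface impurities; artifacts are kept off the chains
themselves, as impurities sit on the background mica, not on adsorbed
fibrils. What the generator does **not** emulate: AFM tip convolution,
height quantization, drift shear, or touching/overlapping fibril bundles.
Passing recovery tests therefore show the analysis is correct for
well-separated fibrils under additive noise, not that it untangles
overlapping bundles.

## AFM analysis pipeline

1. **Scanline flattening** subtracts a per-row robust baseline (order 0:
   median; order 1: Huber M-estimated tilt, then median re-centring).
2. **Artifact masking** flags connected components brighter than
   median + 5 robust σ (MAD) with area > 150 px — far larger than a bead's
   footprint. Flattening is then applied again with flagged pixels excluded
   from the baseline estimate, mirroring the two-pass compensation of
   semi-automated AFM routines. A fully uniform (saturated) frame is
   masked entirely.
3. **Contrast inversion** (display convention) reflects heights about the
   median; detection itself operates on a polarity flag, and inverting
   twice is an exact identity.
4. **Bead detection** finds 8-neighbourhood local maxima of the smoothed
   image (Gaussian σ = 6 nm ≈ half the bead radius, clamped to ≥ 1 px)
   that stand ≥ 3 height units above the smoothed-image median, accepts
   them greedily by height under a 30 nm minimum separation (below the
   smallest plausible repeat), and refines each to a sub-pixel centroid by
   centre of mass over a 5×5 window. On ≤ 64×64 images the detector is
   tested for exact agreement with a brute-force exhaustive scan.
5. **Chain linking** joins beads greedily, shortest admissible link first,
   with degree ≤ 2, no cycles, turn angle ≤ 60°, and ties broken by bead
   index. The default maximum link length is **125 nm**: the spacing
   distribution extends to its 120 nm truncation bound, so the link radius
   must exceed that bound — a tighter radius (e.g. 90 nm) splits chains at
   heavy-tail repeats and at any single missed bead, biasing chain counts
   up and mean lengths down. The renderer's 140 nm inter-chain clearance
   keeps cross-chain links impossible at this radius. A missed mid-chain
   bead is bridged as one long repeat rather than splitting the chain.
6. **Measurement** reports periodicity as consecutive-centroid distance
   and length as beads per chain; repeats per chain (= beads − 1) are
   stored alongside, since both conventions appear in the literature.

## Histogram fitting and modality

Lorentzian parameters are estimated by least squares on the binned counts
(bin width 2 nm by default; fits are verified stable for 1–5 nm bins), not
by maximum likelihood on raw values — matching how periodicity histograms
are fitted in practice. `nls.lm` runs from five jittered starts seeded by
the most separated smoothed-histogram modes, with box constraints keeping
amplitudes and widths positive; R² is computed over bins, and centres are
reported in ascending order.

The unimodal-vs-bimodal call fits k = 1 and k = 2 and returns 2 only if
(i) k = 2 lowers the AIC and (ii) the fitted centres are more than
3 bin widths apart. The AIC is computed from the **Poisson likelihood** of
the bin counts at the fitted curve. The Gaussian-residual form was
rejected during design: bin counts are Poisson, and under the Gaussian
form a broad second component that absorbs the heavy Cauchy shoulders of
a genuinely unimodal sample "wins" the comparison in roughly 15% of
simulated control samples, while the Poisson form keeps that error at
~5% without affecting sensitivity on bimodal samples (100% over 40
simulations). The centre-separation guard prevents peak-splitting wins.

Group comparisons use the standard two-sided nonparametric tests
(Mann–Whitney U, two-sample KS, Kruskal–Wallis) through their base-R
implementations; no multiple-testing correction is applied. The extended
fraction (values strictly above a threshold) carries a Wilson 95% interval.
R² values are treated as dimensionless throughout. Since it is often
unclear whether per-animal samples were pooled before group comparison,
`summarize_samples()` emits both per-animal and pooled rows.

## Tissue quantification

The synthetic section renders 7 lamellae of 3.1 μm separated by 11.5 μm
bands (total 90.7 μm), straight or annular, at 1 μm/px. The stain channel
covers an exact pixel count (clumped by thresholding a smoothed noise
field) so area-fraction truth is known to rounding; an error is raised if
the requested fraction is unreachable at the raster resolution. Pixel
membership is decided by the pixel centre.

* **Area fractions** threshold the tissue channel (excluding voids) and
  the signal channel — Otsu by default, or `"fixed:t"` for
  reproducibility. Otsu assumes a bimodal channel histogram; for a
  signal-free channel a fixed calibrated threshold must be used.
* **Wall straightening** fits a cubic spline through centerline control
  points (periodic continuation for closed contours), reparameterizes by
  arc length, and resamples channels bilinearly along normals at one
  pixel per step. Normal self-intersection (curvature radius smaller than
  the band half-width) is a hard error reporting the arc position. A full
  circle unrolls to its circumference within 0.01%, and annular walls
  straighten to their true thickness within 1 μm.
* **Medial thickness** counts tissue pixels per straightened column
  (i.e. perpendicular to the intima), excluding voids; columns without
  tissue are dropped with a message.
* **Regional gelatinase** subtracts a background estimated as the median
  of a user-designated off-tissue area (clipping negatives to zero) and
  reports mean intensity per μm²; strip regions of configurable width
  (default 100 px) spanning the wall are provided by `region_strips()`.
* **Wave-speed statistics** summarize per-region samples (mean, SD, SEM)
  and call each region's modality with the same Lorentzian machinery on
  10 m/s bins; zero-variance regions are reported unimodal by
  convention.

## Problem sizes and numerical choices

Recovery simulations use the study's own sample sizes: 500 periodicity
values per group and 100 chain lengths per group, rendered at 1024 px
(4 nm/px) with up to four chains per image. Convergence tolerance for the
least-squares fits is 1e-8 on the residual norm; bead sub-pixel refinement
is accurate to ~0.2 px at 10% noise; TIFF height maps are stored 16-bit
with an affine transform in a JSON sidecar, so round-trip error is one
quantization step. All stochastic steps accept a seed and restore the
caller's RNG state, giving bit-identical outputs for a fixed seed.

## Known limitations

* Chain linking is tuned for the clearances the generator guarantees;
  real images with crossing fibrils would need the (out of scope)
  manual-editing step of semi-automated routines.
* The modality rule is a model-selection heuristic; it asserts nothing
  about biological sub-populations beyond histogram shape.
* The tissue generator uses ideal straight/annular lamellae; it does not
  emulate wavy lamellae, staining gradients, or section folds, so tissue
  recoveries validate the measurement geometry, not stain chemistry.
* Acoustic maps are ingested as ready-made wave-speed rasters;
  reconstruction from raw acoustic signals is out of scope.
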