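---
title: "bonesr: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bonesr: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Clinical cone-beam CT (CBCT) resolves features of roughly half a millimetre:
at 100–200 µm voxels the perceived spatial resolution is at least twice
coarser than the grid, which is not enough to see trabecular bone
microstructure. Laboratory micro-CT resolves that microstructure (3–30 µm
voxels) but cannot image patients. `bonesr` implements a super-resolution
(SR) route between the two: high-resolution laboratory-style volumes are
synthetically degraded to clinical resolution, a convolutional network is
trained on the resulting pairs, and the trained network restores clinical
volumes by a factor of four. Because an upscaling network can hallucinate,
the package carries its own validation stack: 3D trabecular morphometry,
line-pair MTF analysis of a QA phantom, and agreement statistics, all
runnable on synthetic data with known ground truth.

## Degradation model

Training pairs are built in two stages from a high-resolution scan:

1. **Target stage.** The scan is resampled per axis to the target voxel size
   (linear, anti-aliased with a Gaussian pre-blur of sd `(f − 1)/2` for a
   downscale factor `f`), then smoothed with a Gaussian of kernel size 7 and
   sd 0.5 voxels to suppress residual aliasing. Supported cascades fix
   input = 4 × target: 200→50, 400→100 and 488→122 µm.
2. **Input stage.** The target volume is downscaled by exactly four
   (block averaging), blurred with a Gaussian of sd 1.0 voxels, and median
   filtered (size 3), emulating the poorer clinical image chain. In 2D mode
   this acts in-plane per axial slice; in 3D mode on all axes.

Two published kernel sizes are grid-ambiguous for centred filtering: the
"size 4" Gaussian (an even kernel has no centre) is realized as the nearest
odd size 5 at the stated sd 1.0, preserving the sd without a half-pixel
shift, and the downscale operator (no interpolator is named by convention)
is block averaging — deterministic and alias-suppressing. Both choices are
exposed in code rather than buried.

Patches of 32³ (3D) or 32² per slice (2D) against 128³/128² targets are
tiled non-overlapping by default ("divided" implies a partition); training
crops them further to the 16 → 64 network size with co-located random
origins (target origin = 4 × input origin). When a 2D pair set is tiled
from a 3D-degraded volume, input slice *s* pairs with target slice
`4(s−1)+2`, the centre of its averaging window.

## Network and losses

The architecture follows the residual image-transformation design: a 9×9
head convolution into `base_channels` features, four residual blocks (two
3×3 convolutions with instance normalization and ReLU, additive skip), two
×2 upsampling stages, and a linear 9×9 tail, with reflect padding
throughout. Upsampling is *resize convolution* — nearest-neighbour resize
followed by a 3×3 convolution — rather than transposed convolution, so a
constant input produces a spatially constant output at initialization (no
checkerboard; tested to 1e−5). Channel width, normalization type and
padding are not fixed by the published description; the defaults here
(64 channels, instance norm, reflect padding) are package decisions.

One addition is a parameter-free *global residual skip*, on by default
(`global_skip`): the network's output is its residual prediction plus a
linear ×4 upsampling of the input, and the tail convolution is damped at
initialization so the untrained network starts at interpolation quality.
Learning a complete image from scratch needs training budgets in the
thousands of steps; learning the residual detail on top of interpolation
converges orders of magnitude faster, which is what makes the package's
short CPU schedules meaningful. Setting `global_skip = FALSE` restores the
plain feed-forward design.

Three loss recipes are first-class, with the published weights:

* **baseline** — 0.8·MSE + 0.2·TV,
* **structure** — 1 − SSIM (Gaussian window 11, sd 1.5, K₁ = 0.01,
  K₂ = 0.03, dynamic range 1),
* **visual** — 0.1·MAE + 1.0·TV + 1.0·perceptual loss.

TV is the anisotropic mean absolute forward difference per axis, summed
over axes; this normalization is pinned by the 1×4 ramp `0,1,2,3` scoring
exactly 1, which keeps loss weights scale-free across patch sizes. The
perceptual loss compares feature maps of a *frozen* convolutional stack at
two tap points (after the second and fourth stages). A pretrained VGG16
backend is the fidelity option when weights are available locally; the
default `seeded_random_conv` backend is a fixed He-initialized 3×3 stack,
so the build never downloads anything and stays deterministic. Random
frozen features are a weaker perceptual metric than pretrained ones; the
recipe structure is identical under either backend.

The published optimizer setting "Adam (α = 0.0001, β = 0.0001)" is not a
valid Adam parameterization: α is unambiguously the learning rate (1e−4,
the default here), and the decay pair uses the standard (0.9, 0.999) with
optional decoupled weight decay. All gradients — through convolutions,
instance norm, upsampling, SSIM, TV and the perceptual stack — are written
by hand and verified against finite differences in the test suite.

Training uses patient-grouped k-fold cross-validation (k = 4): every
patient's patches fall in exactly one fold, asserted on every run. Reported
summaries are mean ± SEM (sd/√n) over folds and seeds.

## Inference

Whole volumes are restored with a sliding window (16-pixel window, 8-pixel
step on the input grid). Each ×4 tile prediction is blended with a
separable Gaussian weight map (sd = one quarter of the output window = 16
output pixels — the published account names the kernel but not its width)
floored at 1e−4, and every output voxel is Σ(w·pred)/Σ(w): per-voxel
normalization is the only choice that makes constants exact, and a
perfect-oracle stub reconstructs the true volume to 1e−6. Borders are
reflection-padded so the window grid covers the volume, and the padding is
cropped from the output. For 2D models, predictions from the three
orthogonal planes can be averaged: each plane's stack is restored in-plane,
its slice axis is cubically resampled ×4 onto the common grid (some
resampling is unavoidable; cubic keeps ramps exact), and the three volumes
are averaged.

Two non-learned benchmarks are provided: tricubic (Catmull-Rom)
interpolation to the ×4 grid, and a conventional enhancement chain of
Perona–Malik anisotropic diffusion (10 iterations, conductance 30/255,
time step 0.1 — the filters are named in the source description without
parameters; these are conventional values, all exposed), percentile
contrast stretching (2–98) and a size-3 median filter.

## Morphometry

Volumes are binarized with Otsu's threshold on a 256-bin histogram after
float01 scaling (matching 8-bit clinical processing), per volume. BV/TV is
the exact foreground fraction. Tb.Th and Tb.Sp are mean local thickness of
the bone and marrow phases under the model-independent inscribed-sphere
definition, computed as an exact Euclidean distance transform followed by
sphere painting and validated against an exhaustive inscribed-sphere search
on small masks. Spheres are clipped at volume faces and border-touching
voxels are included — excluding them would bias small test volumes. Tb.N
uses the plate-free `BV/TV / Tb.Th` (per mm) by default, since the original
analysis script's definition is not recoverable; the alternative
`1/(Tb.Th + Tb.Sp)` is selectable.

## MTF from line pairs

Spatial resolution is quantified from six bar-pattern groups. Per slice and
group, modulation is the noise-corrected ROI standard deviation
`sqrt(max(sd(ROI)² − sd(noise ROI)², 0))`. Converting square-wave
modulation to sine-wave MTF requires a normalization constant, and the
classical single constant π√2/4 over-reads an unblurred pattern (~1.11 at
low frequency, where harmonics pass). The default `"calibrated"` conversion
therefore divides each group's modulation by the analytic sd of an ideal
pixel-area-integrated square wave at that group's frequency and the
material contrast (odd-harmonic series with sinc aperture attenuation,
summed without a Nyquist cutoff because aliased power still contributes to
a standard deviation). A blur-free phantom then reads exactly 1 at every
frequency, and a Gaussian-blurred phantom tracks `exp(−2π²σ²f²)` to within
a few percent; the residual deviation is the sd-method's intrinsic harmonic
mismatch, which grows with blur and is why tests use σ ≤ 1 pixel — the sd
the degradation cascade itself applies. The classical `"droege"` constant
is retained as an option.

Both published normalizations are first-class: `material_pair` scales by
half the mean difference of two uniform material ROIs; `max_intensity`
rescales the curve to peak 1, the fallback when a method distorts the
grayscale calibration (as SR does). MTF50/MTF10 are read off by linear
interpolation of the first crossing by default, or from a third-order
polynomial trendline. Confidence half-widths across slices use t-quantiles
(slice counts are small).

Agreement statistics follow the standard definitions: Pearson r with a
Fisher-z 95 % interval, Bland–Altman bias ± 1.96 sd, linearly weighted
Cohen's κ with the Fleiss–Cohen–Everitt asymptotic variance, and the
Wilcoxon signed-rank test (zero differences dropped; exact null for n ≤ 25
without ties, tie-corrected normal approximation otherwise) with Bonferroni
correction `min(1, m·p)`.

## Synthetic data: what it emulates, and what it does not

The trabecular generator thresholds a smoothed Gaussian random field: white
noise blurred with sd `feature_scale_um / voxel_size_um / 2`, cut at the
`1 − BV/TV` quantile. This gives a connected, plate-and-rod-like
microstructure with *exactly* controllable volume fraction (the quantile
forces it) and a tunable strut scale (doubling `feature_scale_um` roughly
doubles measured Tb.Th), embedded in soft-tissue background with Gaussian
noise and blur. Defaults — 150 µm struts at 50 µm voxels, bone/background
levels 0.8/0.2, noise sd 0.05, blur 0.5 voxels — put the microstructure
well below the 200 µm clinical grid, which is the regime the method
addresses. Ground-truth Tb.Th/Tb.Sp for random fields have no closed form,
so the reference values are the morphometry module's own measurements on
the clean mask; BV/TV is exact by construction. The parallel-plate phantom
(shifted half a gap so no plate touches a volume face) provides fully
analytic references instead.

What the generator does **not** emulate: CT physics (beam hardening, ring
and metal artifacts, cone-beam geometry), anisotropic real trabecular
architecture, marrow inhomogeneity, or scanner-specific noise spectra.
Passing tests therefore demonstrate that the pipeline is internally
correct and that SR beats interpolation *under the stated degradation
model* — not that any particular clinical scanner will see the same
margins.

The QA phantom renders six bar groups (defaults geometrically spaced
2–10 lp/cm, bracketing the 3.5–8.3 lp/cm range where clinical CBCT
readouts live; the physical phantom's full frequency list is not public,
so these are package defaults, not copies) with exact pixel-area
integration, plus uniform material inserts and a noise region, with an
auto-generated ROI layout covering whole bar periods.

## The end-to-end demo and its scale

`demo_end_to_end()` runs the whole loop on one CPU: 8 synthetic training
patients and 20 held-out volumes of 48×96×96 voxels at 50 µm, generated
directly on the target grid (the target-resample stage is the identity
there and is exercised separately by unit tests), degraded 3D to 200 µm;
a 2D structure-recipe network of 12 channels trained 6 epochs at
learning rate 1e−3 on 16→64 crops (a narrow, shorter-schedule variant of
the full 64-channel/50-epoch/1e−4 configuration, chosen as the desk-scale
condition); restoration by three-plane averaging; morphometry
of SR vs tricubic vs conventional enhancement against ground truth; and a
line-pair MTF comparison at 50 µm pixels. The headline check is ordinal:
the Pearson correlation between SR-derived and true BV/TV must exceed that
of tricubic interpolation of the degraded input, and SR's MTF50 must sit
at a higher frequency than interpolation's. Every stage draws from a
hierarchically derived seed, so a seed reproduces the full report
bit-for-bit.

## Numerical conventions

* Axis order is (slice, row, column), axial = axis 1, fixed package-wide.
* Rounding is half-to-even everywhere (base R `round`).
* Min–max normalization of a constant volume maps to zeros, never NaN.
* Reflect (symmetric) borders for all separable filters and convolutions;
  replicate borders for the median filter; zero padding only in explicit
  crop-pad of patches.
* PSNR of identical images is encoded as the documented 120 dB cap.
* All randomness flows through explicit seeds; generators restore the
  caller's RNG state.

## Known limitations

* The perceptual backend bundled offline is a seeded random stack, not a
  pretrained VGG16; visual-recipe results are structurally faithful but not
  comparable to pretrained-feature training.
* 2D single-plane restoration leaves the slice axis at input resolution
  (anisotropic voxels); volumetric morphometry should use the three-plane
  average or a 3D model.
* The sd-based MTF method carries an intrinsic harmonic-content bias under
  strong blur (documented above).
* Grayscale is not calibrated: like any patch-normalized SR, restored
  intensities do not preserve quantitative CT numbers, which is why the
  max-intensity MTF normalization exists.
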