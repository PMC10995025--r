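# bonesr

Super-resolution for clinical cone-beam CT of trabecular bone, with the
validation stack needed to trust it.

Clinical CBCT images bone at 100–200 µm voxels — too coarse to quantify the
trabecular microstructure that laboratory micro-CT resolves. `bonesr`
implements the degradation-based route around that limit: high-resolution
volumes are degraded to clinical resolution with a fixed two-stage cascade
(resample to the target grid + Gaussian k = 7, σ = 0.5; then ×4 block
downscale + Gaussian σ = 1 + median 3), a residual convolutional network
with a ×4 resize-convolution upscaler is trained on the resulting pairs
under one of three composite losses

* baseline  = 0.8·MSE + 0.2·TV
* structure = 1 − SSIM
* visual    = 0.1·MAE + 1.0·TV + 1.0·perceptual

with patient-grouped 4-fold cross-validation, and whole volumes are restored
by Gaussian-blended sliding windows (16-px window, 8-px step), optionally
averaging the three orthogonal planes. The network, backpropagation and Adam
are implemented in the package itself (no deep-learning framework is
required); every gradient is verified against finite differences in the test
suite.

Because super-resolution can hallucinate, the package ships its own
validation instruments:

* **Morphometry** — Otsu binarization and BV/TV, Tb.Th, Tb.Sp (exact
  Euclidean distance transform + inscribed-sphere local thickness,
  oracle-checked), Tb.N.
* **MTF** — spatial resolution from six-group line-pair phantoms by the
  noise-corrected ROI standard-deviation method, with MTF50 %/MTF10 %
  readouts and both material-pair and max-intensity normalizations.
* **Agreement statistics** — Pearson r with Fisher-z intervals,
  Bland–Altman limits of agreement, linearly weighted Cohen's κ, Wilcoxon
  signed-rank with Bonferroni correction.
* **Synthetic phantoms** — trabecular volumes from thresholded Gaussian
  random fields with exactly known BV/TV, analytic parallel-plate phantoms,
  line-pair and slanted-edge QA phantoms; no scanner data needed anywhere.

## Worked example

The end-to-end experiment generates eight synthetic training subjects and
twenty held-out test volumes (48×96×96 at 50 µm, ~150 µm struts), degrades
them to 200 µm, trains a small 2D structure-recipe model, restores the test
volumes by three-plane sliding-window averaging, and compares SR against
tricubic interpolation and a conventional enhancement pipeline
(anisotropic diffusion + contrast stretch + median):

```r
library(bonesr)
report <- demo_end_to_end(demo_config(seed = 1))
print(report)
```

```
== correlations with ground truth (Pearson r) ==
       method      param         r        ci_lo     ci_hi
           sr       bvtv 0.8785952  0.713464357 0.9512675
           sr    tbth_um 0.7938672  0.541612327 0.9149615
           sr    tbsp_um 0.6783546  0.336987284 0.8620907
           sr tbn_per_mm 0.7359476  0.435132651 0.8889610
     tricubic       bvtv 0.5677218  0.167200101 0.8074035
     tricubic    tbth_um 0.4551530  0.015809563 0.7471845
     tricubic    tbsp_um 0.3680471 -0.088971622 0.6970462
     tricubic tbn_per_mm 0.4454110  0.003590972 0.7417373
 conventional       bvtv 0.5427218  0.131863564 0.7944475
 conventional    tbth_um 0.4477158  0.006469826 0.7430296
 conventional    tbsp_um 0.2790215 -0.186539183 0.6422479
 conventional tbn_per_mm 0.3295907 -0.132222146 0.6738373

== MTF readouts (lp/cm) ==
    method mtf50_lp_cm mtf10_lp_cm
 reference          NA          NA
        sr   16.202299          NA
  tricubic    8.206335    15.40117

Bland-Altman BV/TV (SR - truth): bias 0.0688, LoA [-0.0738, 0.2114]
Out-of-fold: MSE 0.0820 | PSNR 10.86 dB | SSIM 0.137 (734 s total)
```

Read: the learned restoration tracks the true bone volume fraction across
the held-out volumes better than interpolating the degraded input
(`r = 0.88` vs `0.57`), with the conventional filtering pipeline behind
both, and it holds 50 % modulation out to roughly twice the frequency of
interpolation (16.2 vs 8.2 lp/cm; the noise-free reference never falls to
0.5 inside the sampled band, hence "NA"). The ordering, not the absolute
values, is the robust finding at this synthetic desk scale: the ~150 µm
struts sit below the 200 µm input grid, so even the restored volumes carry
a positive BV/TV bias (Bland–Altman bias 0.069) and the pixel-wise
out-of-fold SSIM stays low — structure below the input Nyquist is
genuinely gone, and what the network recovers is the statistically likely
microstructure, which is exactly why the morphometric validation layer
exists.

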