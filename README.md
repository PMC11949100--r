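# pterygrade

Automated severity assessment of **pterygium** — the wing-shaped
conjunctival overgrowth that invades the cornea — from 3-class
anterior-segment segmentation masks (pterygium / pupil / cornea).

Segmenting a slit-lamp photograph is not yet a diagnosis: the lesion
occludes part of the corneal outline, so the cornea class has an
*incomplete contour*, and clinical grading needs measurements against
the **restored** corneal circle. `pterygrade` provides that
post-processing chain, for ophthalmic-imaging researchers and for
anyone who needs a quantitative, reproducible pterygium grade from a
label mask:

* **Robust circle restoration.** The visible corneal (or pupillary)
  contour is fitted by iteratively reweighted least squares: each
  iteration solves the weighted algebraic (Kåsa) circle system under a
  diagonal weight matrix `W = diag(w₁ … w_m)`, then re-weights the
  signed residuals `δᵢ = ‖pᵢ − c‖ − r` with the Huber weights
  `w(δ) = 1` for `|δ| ≤ γ`, `γ/|δ|` beyond, or the Tukey biweight
  `w(δ) = (1 − (|δ|/γ)²)²` for `|δ| ≤ γ`, 0 beyond — so leading-edge
  points are progressively rejected as outliers (10 iterations by
  default, scale-adaptive `γ`).
* **Invasion metrics.** Area ratio `α = A_p / A_c` by per-pixel
  counting against the restored disc; depth ratio
  `β = (L/2 − d_min)/L` with `d_min` the minimum distance from the
  fitted center to the visible contour and `L` the fitted diameter;
  physical depth `β · L_ref` for a reference adult corneal diameter
  `L_ref ∈ [11.5, 12.5]` mm (default 11.5 mm).
* **Clinical grade.** Grade 1: invasion ≤ 3 mm. Grade 2: > 3 mm, pupil
  spared. Grade 3: pupil covered (decided by pixel counting inside the
  fitted pupil disc, with a 0.5% noise-tolerance epsilon).
* **Evaluation.** Per-class IoU / Dice / precision / recall, and
  grading agreement (accuracy, prevalence-weighted F1, Cohen's κ) with
  a reference-diameter sweep.
* **Phantom generator.** Synthetic anterior-segment masks whose
  invasion geometry is known in closed form (circular-cap lesion
  model), with seeded segmentation-noise perturbations — every stage of
  the pipeline is testable without clinical data.
* **Segmentation network.** A compact hybrid CNN–transformer
  encoder–decoder with a channel-and-shape attention module (CSAM) on
  each skip connection (channel gating via 1D convolution over pooled
  channel descriptors; shape gating via (optionally deformable)
  depthwise + dilated-depthwise + 1×1 convolutions), trained with the
  equal-weight cross-entropy + soft-Dice loss. Implemented natively in
  R with hand-derived backward passes; trainable at smoke scale on
  rendered phantoms.

## Worked example

```r
library(pterygrade)

# a 512x512 phantom: cornea radius 200 px, leading edge 150 px from the
# corneal center (d/R = 0.75), exact geometry
ph <- generate_phantom(phantom_spec(512, 512, cornea_radius_px = 200,
                                    invasion_distance_px = 150,
                                    boundary_jitter_sd_px = 0))
res <- assess_image(ph$mask)
res
#> <grade_result> grade 1  (invasion depth 1.442 mm <= 3 mm)
#>   alpha_cornea=0.0714  beta=0.1254  depth=1.442 mm  pupil spared

ph$truth$alpha_cornea_analytic   # closed-form cap fraction
#> [1] 0.07214681
ph$truth$beta_true               # (R - d) / (2R)
#> [1] 0.125
res$metrics$cornea_fit
#> <circle_fit> center=(255.508, 255.500) radius=199.554  tukey weights, 10 iter
```

The measured `α` (0.0714) and `β` (0.1254) track the closed forms
(0.0721 and 0.125) to a few thousandths; the Tukey-IRLS fit restores the
corneal circle to about half a pixel even though the lesion has erased a
quarter of the limbal arc. Grading uses the 11.5 mm default reference
diameter, so `β = 0.1254` means a 1.44 mm invasion: grade 1.

Command-line use (the same functions behind a thin launcher):

```sh
inst/cli/pterygium-tool phantom --n 10 --size 512 --seed 1 --out phantoms/
inst/cli/pterygium-tool assess --mask phantoms/phantom_001.png --out report.json
inst/cli/pterygium-tool sweep --mask-dir phantoms/ --expert-grades grades.csv \
    --sweep 11.5:12.5:0.1 --out sweep.csv
```

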