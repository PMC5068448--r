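---
title: "Quantifying genomic DNA quality from agarose gels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying genomic DNA quality from agarose gels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelquant)
```

## The measurement

A classic agarose gel separates DNA fragments by size: small fragments
migrate far from the well, large fragments stay near it, and migration
distance is, to first order, linear in the logarithm of fragment length.
For genome sequencing one wants *genome-quality* DNA — predominantly
high-molecular-weight fragments — and the standard visual check is to run
an extraction next to a high-range ladder such as the lambda/HindIII
digest and look for a tight band above the large marker bands rather than
a smear.

`gelquant` turns that visual check into a number. A threshold band of the
ladder is chosen as the *DNA threshold* (the HindIII 9,416 bp band by
convention; any catalogued band works). Each lane's 1-D intensity profile
is split at the threshold into the signal migrating less far (fragments at
or above the threshold size) and further (below it), and the *percent
above threshold* is

$$
\mathrm{percentAboveThreshold}
  = 100 \cdot \frac{A_{\ge X}}{A_{\ge X} + A_{<X}},
$$

the ratio of integrated profile areas. Both quantities are the two GGBN
Gel Image Vocabulary terms (`DNAThreshold`, `percentAboveThreshold`), so
records can be published alongside biorepository samples. A lane with at
least 50% of its signal above the 9,416 bp threshold is annotated (never
filtered) as candidate "genomic quality".

## Pipeline and assumptions

Scoring follows the manual densitometry workflow step by step:

1. **Inversion** — photographs have dark DNA on a light background; the
   analysis wants bright bands and positive density curves, so intensity
   is mapped to `1 - intensity`. Inversion is explicit, never guessed; a
   heuristic warning fires when an image already looks dark-background.
2. **Leveling** — the image is rotated about its centre so the top ladder
   band (largest fragment) sits on one row in both flanking ladder lanes.
   Pure rotation only; shear is not modelled here because the per-lane
   threshold interpolation (step 5) absorbs residual linear tilt.
3. **Background subtraction** — the smooth continuous background is
   estimated by greyscale morphological opening with a flat disc
   (default radius 50 px, which must exceed the largest band half-width)
   and subtracted, clamping the raster at zero.
4. **Lane profiles** — all lanes share one vertical box extent, starting
   below the wells and above the largest ladder band, reaching past the
   smallest fragments. The profile is the *mean* across the box width per
   row. Summing (as interactive tools do) differs only by the constant
   width factor and leaves every area ratio unchanged; the mean has the
   advantage that a box slightly wider than a laterally uniform lane does
   not change the score.
5. **Threshold line** — band apexes are detected in the two bracketing
   ladder lanes and a straight line is drawn from the threshold band's
   apex on the left to its apex on the right; each sample lane's
   threshold row is that line evaluated at the lane centre. This is
   deliberately *not* a per-lane re-detection: the line is how the manual
   method compensates smooth lateral distortion.
6. **Closing, masking, integration** — profiles are closed (a vertical
   drop at the last row, which adds no area), user-specified artifact
   chords replace gel-flaw peaks, and the two regions are integrated by
   the trapezoid rule, the trapezoid at the threshold row being split at
   the (generally fractional) interpolated position.

Assumptions worth stating: wells at the top of the image; staining signal
proportional to DNA mass (intercalating dyes bind per base pair);
lanes vertical after leveling; background smooth on scales larger than
the structuring disc.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `band_size` | 9416 | bp | the DNA threshold ("X" in greater-than-X-kb) |
| `background_radius` | 50 | px | disc radius of the opening; must exceed band half-width |
| `min_prominence_frac` | 0.05 | — | peak prominence floor, fraction of profile max |
| `window_frac` | 0.05 | — | expected-position window for band assignment (with a calibration model) |
| `closure_tol` | 0.01 | — | terminal value above this fraction of max records a closure |
| box width | layout | px | free; the paper's protocol leaves it to the operator |

Band assignment maximises total assigned peak height over
order-preserving assignments (larger fragments at smaller rows), so extra
peaks (specks) or missing faint bands (over-diluted ladders, where the
~2 kb pair routinely disappears) degrade gracefully; only two assigned
bands are required for calibration, and the bands used are reported. Ties
between equal-height candidates go to the peak nearer the
migration-model prediction.

## Numerical choices

* **Indexing** is R-native 1-based `(row, col)`, row 1 at the wells,
  migration distance increasing downward.
* **Resampling** for rotation is bilinear, which preserves integrated
  intensity to first order.
* **Background estimation details.** The opening is computed on a
  denoised copy (3 px median filter, then Gaussian sigma 6): the minimum
  of thousands of noisy pixels is biased low by several noise SDs, and
  that bias would otherwise reappear as a spurious pedestal under every
  lane — a pedestal of only 0.001 intensity units shifts a bright lane's
  percentage by about two points. The estimate is then smoothed at two
  scales, $G_{60}(b) + G_{75}(b - G_{60}(b))$: the first stage suppresses
  the narrow slope-coupled bumps the disc leaves under lanes (where the
  background is never directly observed), and the second restores the
  large-scale field so genuine vignettes are not flattened. Repeated
  subtraction is then a near-no-op (pixels move by less than $10^{-3}$).
* **Noise rectification.** The raster is clamped to `[0, 1]` after
  subtraction, but profile extraction averages the *signed* residual
  across the box width before clamping at zero; clamping per pixel first
  would rectify zero-mean noise into phantom positive area in empty
  profile stretches.
* **Threshold split.** The profile value at the threshold row is shared
  between regions via the split trapezoid. Whether an interactive
  wand-selected region includes the boundary column on both sides is not
  decidable from the manual protocol; this rule is declared, not
  inferred.
* **Degenerate inputs.** Empty lanes (total area under
  $10^{-6}$ per profile row) yield `NA` with an `empty-lane` warning
  rather than 0; saturated sources (over 1% of pixels at the bit-depth
  maximum) tag every downstream record with a `saturation` warning;
  negative variance components in the Gage R&R are truncated to zero and
  flagged.
* **Ladder choice with dilution series.** When several ladder lanes flank
  one side, the lane with the most assigned bands wins; ties go to the
  brightest (least diluted) lane.

## The synthetic gel simulator

Real gel images with known truth do not exist, so the package ships a
forward simulator (`synthetic_gel_spec()`, `render_gel()`) used by every
recovery test. A sample lane's fragment-mass distribution is a
two-component lognormal mixture: a tight intact component (meanlog
$\log 4\times10^4$, sdlog 0.1 — high-MW DNA running near limiting
mobility) and a broad degraded smear (meanlog $\log 3000$, sdlog 0.8 by
default). The mixture weight `w_intact` is the quality dial; the default
four-lane gel uses weights 0.9, 0.5, 0.2, 0 to span the range. Mass maps
through the log-linear migration law (a = 1247.8, b = −250 on a 600 × 480
px image, placing 23,130 bp at row ~157 and 564 bp at row 560), is
convolved with a 3 px Gaussian band spread, and off-scale mass
accumulates at limiting-mobility/gel-front rows so that total lane mass
is conserved. Ladder lanes render discrete bands with mass-proportional
amplitudes floored at 15% relative brightness so the 564 bp band stays
visible. On top come a constant-plus-vignette background (0.08 + 0.06),
optional rigid rotation (`skew_deg`) and pure vertical shear
(`shear_px` — the distortion the threshold interpolation is meant to
absorb), Gaussian sensor noise (sigma 0.01), dark Gaussian specks
emulating gel flaws, and 16-bit quantisation. A seed fully determines the
image.

The closed-form mixture tail (`true_percent_above()`) is the ground
truth; a `degrade()` helper scales `w_intact` by $e^{-0.15\,h}$ and
shifts the smear downward by 0.03 log-units per hour to emulate
postmortem time series. The decay constants are synthetic: no
quantitative rate is recoverable from published tables without the
original images.

What the simulator does **not** emulate: curved ("smiling") lanes,
per-lane vertical warping, well-retention or comet artifacts,
stain-specific spectral effects, and camera flat-field structure beyond a
radial vignette. Passing recovery tests therefore demonstrates the
pipeline's correctness under smooth distortions and realistic noise, not
robustness to every real-world gel pathology — which is precisely why
scoring retains per-lane warnings and manual mask control.

Problem sizes used by the test-suite and the acceptance script — 50
random gels for recovery, 100 lanes for the integration oracle, 200
simulated studies for the Gage R&R recovery — were chosen so the whole
validation runs in a couple of minutes on a single core while keeping
Monte-Carlo noise well inside the tolerances checked.

## Scoring-consistency analysis

`gage_rr()` implements the crossed two-factor ANOVA with interaction used
in measurement-system analysis: parts (lanes) × operators (scorers) with
replicates. Variance components come from the expected-mean-squares
solution; the interaction is pooled into repeatability when its F-test
p-value exceeds 0.25 (standard MSA practice; the pooling threshold is a
parameter). Reported percentages are percent of total *study variation*
on the SD scale — the convention under which the published
worked examples are internally consistent, since the total obeys
$\sqrt{\text{repeatability}^2 + \text{reproducibility}^2}$ — with the
conventional acceptability bands: total GRR under 10% acceptable, under
30% conditionally acceptable, 30% or more unacceptable. Whether a
5.15-sigma or 6-sigma study-variation multiplier is used is irrelevant to
these ratios.

With only two operators the operator mean square has a single degree of
freedom, so when the true operator effect is near zero the truncated
estimate is exactly zero in about two-thirds of studies and noisy
otherwise; the tests assert that correctly derived distribution rather
than a tighter bound the design cannot deliver.

## Known limitations

* The migration model is first-order (linear in $\log_{10}$ size);
  residuals are exposed so curvature can be detected, but no spline
  alternative is provided.
* Background accuracy under a lane is fundamentally interpolation from
  the neighbouring gaps; layouts whose lanes touch leave the estimator
  little to work with.
* Auto-detected lanes are a convenience; quantitative work should use an
  explicit lane layout.
* Masking is manual by design — the original protocol treats artifact
  removal as an operator judgment, and an automatic detector would hide
  that judgment from the audit trail.
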