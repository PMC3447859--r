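---
title: "Methods: stained-area quantification and assay statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stained-area quantification and assay statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcquant)
```

# The problem

Brightfield immunohistochemistry scores an antigen by the area of brown DAB
precipitate over a blue hematoxylin nuclear counterstain. Manual thresholding
is irreproducible: illumination is uneven across the optical path, slide
background and debris carry color, and the brown/blue separation depends on
stain intensity. `ihcquant` implements a deterministic per-field pipeline
that addresses each of these, plus the arithmetic used to report the
surrounding cell-based assays (dose–response GI50, LDH cytotoxicity, caliper
tumor volumes, percent inhibition, t-tests). Because studies of this kind
rarely deposit raw images, validation rests on a first-class synthetic-data
module with exact ground truth.

# The segmentation pipeline

`segment_field()` composes seven steps; every intermediate parameter is kept
in the result object.

1. **Flat-field correction.** Each channel is divided by the light-field
   image (an acquisition of the empty optical path), floored at
   $\varepsilon = 10^{-3}$ to avoid division blow-ups, and rescaled by the
   flat-field channel mean so the scene's per-channel spatial mean is
   preserved when nothing clips. Segmenting a shaded scene with its
   flat-field supplied reproduces the unshaded segmentation (tested to
   within 2% of pixels).
2. **Non-specific color suppression.** The image is taken to
   hue/saturation/brightness; pixels whose hue lies outside both stain
   sectors — DAB 10–50°, hematoxylin 200–260° by default — have their
   saturation multiplied by `offsector_saturation_scale` (default 0, i.e.
   full desaturation). Achromatic pixels are fixed points, so the operation
   is idempotent at scale 0. The sector defaults bracket the rendered hues
   of the two stains; they are configurable because acquisition color
   balance varies between microscopes and cameras.
3. **Adaptive stain contrast.** The pipeline scores the weighted channel
   difference $C = \alpha R - (1-\alpha) B$ on the grid
   $\alpha \in \{0, 0.05, \dots, 1\}$. For each $\alpha$, $C$ is min–max
   rescaled to 8-bit, auto-thresholded (step 5), and scored by the
   between-class variance at that threshold normalized by the total variance
   — a measure of how bimodally the contrast separates the image. A grid
   point is *admissible* only if its above-threshold class passes the same
   red/blue color test the artifact filter applies (mean red over mean blue
   at least $\tau$): without this constraint the best split on many fields is
   tissue-versus-background with the bright background as the positive class,
   which is maximally separable but scores the wrong stain. A
   four-parameter logistic is then fitted to metric versus $\alpha$ and
   $\alpha^\*$ is the grid argmax of the fitted curve. The fitted sigmoid is
   by construction monotone, so its high side is a near-exact plateau; ties
   on that plateau are resolved by the raw metric, and any remaining ties
   toward larger $\alpha$ (favoring the red/DAB axis). If the logistic fit
   fails the raw grid argmax is used and a warning is logged.
   On the default synthetic stains this lands at $\alpha^\* \approx 0.3$,
   the weight at which background and counterstain project to the same
   contrast level and DAB stands alone above threshold.
4. **Band-pass background removal.** Difference of two Gaussian blurs with
   $\sigma = \text{size}/2$ for the small (2 px) and large (80 px) structure
   sizes, then mean-centering, so smooth shading and the DC level vanish
   while stain-scale structure passes. The implementation is checked against
   the analytic Gaussian transfer $e^{-2\pi^2\sigma^2 f^2}$: a sinusoid of
   period 32 px retains ≈98% of its amplitude, one of period four times the
   large size ≈27%.
5. **Isodata (intermeans) threshold.** On the 8-bit histogram, starting from
   the truncated overall mean, $T \leftarrow \lfloor (\mu_{\le T} +
   \mu_{>T})/2 \rfloor$ until fixed. Truncation (integer part) rather than
   round-half-up is deliberate: it matches integer-arithmetic
   implementations of the classic algorithm and the worked values this
   package pins in its tests (equal-mass spikes at 0/255 give $T = 127$).
   Integer input already on the 0–255 scale is used as-is; float input is
   min–max rescaled first. Pixels strictly above $T$ are positive. The
   iterative fixed point is tested against an exhaustive search over all 256
   candidate thresholds on random histograms.
6. **Connected components.** 8-connectivity; boundary objects are kept (no
   edge exclusion). Labeling is EBImage's 4-connected labeling plus a
   diagonal union-find merge.
7. **Artifact rejection.** Per object, the mean red and mean blue of the
   flat-field-corrected image; an object is kept iff
   $\bar R / (\bar B + 10^{-6}) \ge \tau$ (boundary inclusive, default
   $\tau = 1.15$) and its area is at least `min_object_area` (20 px).
   This removes hematoxylin nuclei and gray debris that survive
   thresholding. Raising $\tau$ can only shrink the kept set (tested).

Degenerate fields — blank, constant, or without red/blue contrast — raise a
typed condition and are excluded from group summaries with a logged reason,
never imputed.

## Tunables

| parameter | default | unit | rationale |
|---|---|---|---|
| `alpha_grid_step` | 0.05 | – | 21 candidate weights; finer grids did not change $\alpha^\*$ on synthetic fields |
| `bandpass_small` / `bandpass_large` | 2 / 80 | px | bracket stain-scale structure; $\sigma = \text{size}/2$ |
| hue sectors | 10–50° / 200–260° | deg | rendered DAB / hematoxylin hues |
| `offsector_saturation_scale` | 0 | – | full suppression of non-specific color |
| `artifact_ratio_cutoff` $\tau$ | 1.15 | – | separates DAB (ratio ≈ 3 at the default stain colors) from counterstain (≈ 0.54) and gray (≈ 1.0); justified purely by synthetic-data performance |
| `min_object_area` | 20 | px | speckle floor at ~0.5 µm/px |

Note the large band-pass scale implies a minimum field size of about 250 px;
the shipped configurations use 256–512 px fields.

# Dose–response model and GI50

The 4PL is parameterized
$$y(x) = \text{bottom} + \frac{\text{top} - \text{bottom}}{1 + (x/\text{ec50})^{-\text{hill}}}$$
with the dose–response sign convention: negative Hill slope means a
descending (inhibition) curve, and then $y(0) = \text{top}$ exactly, so the
untreated control anchors the top asymptote without any special casing.
Parameters are canonicalized to `top >= bottom` (the swap negates `hill` and
leaves the curve unchanged). Fitting is Levenberg–Marquardt least squares
(`minpack.lm`) on (`bottom`, `top`, `log ec50`, `hill`) with initialization
top = mean control response, bottom = mean response at the largest dose,
ec50 = geometric mid-dose, hill = −1; convergence at relative SSE change
$< 10^{-10}$ or 500 iterations. Step-like data drive `|hill|` to the
boundary; fits with $|hill| \ge 50$ are flagged non-converged with a warning
rather than silently reported. GI50 inverts the fitted curve at half the
untreated-control mean in closed form; a curve that never crosses that level,
or crosses only beyond ten times the observed dose range, errors with "GI50
not reached" — mirroring assay reports where the maximal tested
concentration shows no effect. A forward–inverse round trip reproduces half
the control to $10^{-9}$ relative (tested).

Remaining assay arithmetic is deliberately plain: percent cytotoxicity
$100\,r/t$, tumor volume $\tfrac43\pi R_1^2 R_2$ with radii sorted so the
smaller is squared (a warning, not an error — calipers do not guarantee axis
order), percent inhibition $100(1 - \bar x_T/\bar x_C)$ (negative values =
stimulation), and Student's pooled-variance unpaired two-tailed t-test
("unpaired two-tailed t-test" without qualification is read as the pooled
variant; Welch is available behind `welch = TRUE`). Zero pooled variance with
equal means returns $t = 0, p = 1$. Both SD and SEM are always computed;
report layers choose per figure convention.

# What the synthetic data emulates — and what it does not

`generate_ihc_field()` composes a bright background, circular hematoxylin
nuclei, and elliptical DAB blobs painted last (so the ground-truth mask is
exactly the visible DAB area and nuclei are never positive), multiplied by a
smooth linear illumination ramp with an exact peak-to-trough ratio, plus
zero-mean Gaussian intensity noise clipped to $[0,1]$. Blobs are placed one
at a time — the closing blob shrunk to fit — until the realized positive
fraction is within 10% relative of the target; unreachable targets fail
naming the violated constraint. Defaults: 0.5 µm/px, blob semi-axes
$\mathcal N(12, 3^2)$ px, nucleus radius 5 px, nucleus density
0.0023 px⁻², illumination ratio 1.3, noise SD 0.02 (Gaussian rather than
Poisson shot noise, for simplicity). Stain colors default to typical
rendered hues — DAB (0.42, 0.28, 0.14), hematoxylin (0.35, 0.35, 0.65),
background (0.92, 0.90, 0.90) — and are configurable since acquisition color
balance is instrument-specific.

The shipped presets encode effect sizes as ground truth: stained-area
fractions 0.25 → 0.16 (proliferation marker, a 36% decrease) and
0.10 → 0.076 (vessel marker, 24%); an LDH release profile of 2% (control),
15% (1 µM) and 80% (7.5 µM) of total LDH from 3 h onward (pre-3 h levels —
7% and 40% — are design values consistent with an early, rapid release);
colony means of 30/well untreated, 0.25× control at 0.1 µM and 0 at ≥2.5 µM;
and a xenograft preset with treated/control endpoint volume ratio 0.45,
per-mouse lognormal dispersion (CV 0.6), 25 mm³ enrollment volume and a
47-day course measured at up to 14 timepoints, converted to caliper radii at
a fixed 1.3 axis aspect ratio. Only these ratios and percentages are
anchored to reported biology; every absolute level (colors, colony means,
LDH totals, growth rates) is an invented, documented design value.

Passing on this synthetic data therefore shows that the pipeline recovers
*known stained-area fractions and effect ratios under uneven illumination,
counterstain confusion and moderate noise* — it does not certify performance
on real tissue, which adds texture within stains, stain colocalization,
necrotic regions, section folds and chromatic camera effects that the
generator deliberately omits (no texture synthesis, no tissue architecture).

# Numerical choices and degenerate inputs

* Isodata rounding is truncation; ties at the threshold go to the negative
  class (positive is strictly above $T$).
* $\alpha$ ties: fitted-plateau ties → raw metric → larger $\alpha$.
* The artifact cutoff is boundary inclusive ($\ge \tau$).
* Flat metric curves (range $< 10^{-6}$), single-level histograms and
  identical red/blue channels are degenerate-field failures, not zeros.
* Per-field seeds in a study and per-stage seeds in the pipeline are derived
  deterministically from the master seed, so identical configurations give
  byte-identical outputs and stages can be rerun independently.

# Problem sizes used in validation

The test suite exercises segmentation at 256×256 px (where a field takes
well under a second), ten-seed recovery sweeps over target fractions
0.05–0.4, a 100-histogram threshold oracle, 100 noise-free and 50 noisy 4PL
recovery draws, and exact 252-split permutation oracles for the t-test. The
end-to-end effect-size checks use the study conditions themselves: six
512×512 fields per group. The acceptance script re-runs those plus 1000-well
colony and 200-mouse growth simulations; everything completes in about a
minute on one CPU.

# Known limitations

* The adaptive-contrast admissibility constraint ties the optimizer to the
  artifact filter's $\tau$; a field whose true positive stain is *not*
  red-dominant would need re-configured sectors and cutoff.
* The hue-sector suppression is a simple saturation gate, not a measured
  stain-vector unmixing; heavily colocalized stains will blur the red/blue
  sort (stain-vector estimation is out of scope).
* Area, not cell counts: the pipeline quantifies stained area and object
  counts of connected regions; it does not segment individual nuclei or
  score per-cell positivity.
* The t-test layer applies no multiple-testing correction, matching the
  reporting conventions it mirrors; users comparing many measures should
  correct downstream.
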