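---
title: "Methods: Fourier retinotopy, field-sign segmentation, and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Fourier retinotopy, field-sign segmentation, and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement and its model

Intrinsic signal optical imaging (ISOI) records small (order 0.1–1%)
reflectance changes of cortex under red light; neural activation produces a
reflectance *decrease* through its hemodynamic correlates. When a visual
stimulus repeats periodically with period $P$ (here $P = 8$ s, 1 cycle /
8 s), the evoked reflectance modulation of every cortical pixel is periodic
with the same period, and the pixel's response is summarized by the complex
coefficient of its time course at the stimulus frequency $f = 1/P$:

$$c_p = \frac{2}{T}\sum_{k=0}^{T-1} (x_p[k] - \bar x_p)\,
        e^{+i 2\pi f t_k}.$$

`retinomapper` uses the $e^{+i2\pi f t}$ kernel so that **phase increases
with time-of-response within the cycle**: a pixel whose response peaks at
cycle time $t_0$ has phase $2\pi f t_0$. The inverse map
(`phase_to_stimulus_time()`) is then literally
$t = (\phi/2\pi)\,P - \text{delay} \pmod P$. Because the intrinsic signal
is a dip, analysis of real movies passes `invert = TRUE`
(work on $\bar x - x$), which removes the $\pi$ offset the dip would
otherwise add. This one sign convention is used everywhere in the package.

The magnitude $|c_p|$ is reported in fractional units, $|c_p|/\bar x_p$
(a $\Delta R/R$-like quantity), so that simulated ground-truth amplitudes
are directly recoverable and so that amplitudes are comparable across
animals before the final V1 normalization. Raw-counts magnitude is also
available (`response_magnitude(map, fractional = FALSE)`).

A drifting bar sweeping the screen once per cycle phase-encodes retinotopy:
the time the bar crosses a pixel's receptive field sets that pixel's
response phase, so azimuth (horizontal bar sweep) and elevation (vertical
sweep) maps follow from the two phase maps. Screen geometry uses the
arctangent flat-monitor correction; the monitor tilt is modeled as a
rotation of the elevation axis only (a single tilt angle is all the
protocol specifies).

### Timing details

* The stimulus frequency sits exactly on a DFT bin when the movie covers an
  integer number of cycles; harmonics of the (non-sinusoidal) response
  waveform are then orthogonal to the fundamental, and the phase estimate
  is exact in the noise-free limit.
* 4$\times$ temporal binning shifts the effective sample time of each
  binned frame to the centroid of its four parents,
  $(t_{\mathrm{bin}}-1)/(2 f_s) = 0.05$ s at 30 fps. The pipeline passes
  this as `t0_offset_s` to `extract_response()`; ignoring it would bias
  azimuth by $\sim$0.7° — well inside the recovery tolerance, but there is
  no reason to keep the bias.
* The hemodynamic delay appears as a constant phase offset. The protocol
  this package models does not include bidirectional-sweep delay
  cancellation, so the delay is a configuration scalar (`delay_s`,
  default 0 for real data, where it is unknown; simulations pass their
  true value). This is a documented limitation for real recordings.

## Binning

The camera delivers 12-bit values at 30 fps. Binning **sums** 4 consecutive
frames and 2$\times$2 pixel blocks: 16 samples of at most 4095 give at most
65520, which is exactly why 12-bit input yields 16-bit output. Summation
(not averaging) is therefore the contract; total intensity is conserved,
and overflow is impossible for valid input (asserted, never clipped). Odd
spatial dimensions are rejected; a trailing temporal remainder is dropped
with a warning.

## Field-sign segmentation

Borders between visual areas are reversals in the progression of
retinotopy. The computational form of a reversal is a sign change of the
Jacobian of the cortical map $(x,y) \mapsto (\text{azi}, \text{ele})$ —
the *visual field sign*,
$\mathrm{sign}\!\left(\partial_x a\,\partial_y e -
\partial_y a\,\partial_x e\right)$. The package automates what was
historically drawn by hand from the phase maps; manually drawn label
images can still be imported (`import_labels()`), including separate AM
and PM labels that are merged into one AM/PM region, whose mutual border
is not reliably resolved in this preparation.

Numerical choices that matter:

* **Circular treatment of phase-derived maps.** Degrees at the two ends of
  a sweep are circularly adjacent (they derive from a periodic phase).
  Each retinotopy map is lifted to the unit circle,
  $z = e^{i\theta}$, smoothed as a complex field (Gaussian,
  `smooth_sigma_px = 2` by default), and differentiated circularly
  ($\Delta\theta = \arg z_1 \bar z_2$). Linear smoothing of degree maps
  would create spurious sign flips wherever the sweep extremes abut, which
  is exactly what happens at area borders.
* **Masked smoothing.** Phase outside responsive cortex is noise. The
  field sign is computed with NA-aware normalized convolution restricted
  to the responsive mask, so background phase cannot pollute in-mask
  gradients.
* **Opening and regrowth.** Each sign class is morphologically opened
  (1 px) before connected-component labeling, cutting thin same-sign
  bridges that the blurred magnitude halo can create between areas;
  after naming, components regrow within the mask by `open_px + 2` px
  (multi-source dilation, fronts stop where they meet), recovering the
  border band the opening and the sign-transition zone consumed.
* **Component naming.** The largest component is V1. Other components are
  named by their centroid offset from V1, normalized by $\sqrt{|V1|}$
  (scale-free), greedily matched (largest first) to a template of
  expected HVA positions: LM lateral-posterior, LI further lateral, AL
  anterolateral, RL anterior, AM/PM anteromedial. Unassignable components
  go to background with a warning.
* The minimum component size is 100 binned px²; the Jacobian noise floor
  defaults to numerical zero (an all-constant map gives an all-zero
  sign).

## Responsive mask and quantification

The protocol thresholds a Gaussian-filtered (5×5 kernel) copy of the
grating magnitude map to define visually responsive cortex, then measures
mean amplitudes of the **original** unfiltered map inside each area ∩ mask.
Two quantities are under-specified by that description and were decided
here:

* *Kernel shape:* "kernel size 5 × 5" fixes support, not SD; we use
  $\sigma = 1$ px truncated to 5×5 and normalized.
* *Threshold rule:* no value is stated. Default: 0.25 × the 99th
  percentile of the filtered map — scale-free (so a global gain change in
  acquisition cannot change the mask) and robust to outlier pixels. An
  absolute-value mode exists, and the rule is applied per animal (a
  scale-free per-animal rule is the only choice compatible with the
  stated purpose of the subsequent V1 normalization).

Each animal's HVA means are divided by its V1 mean (`normalize_to_v1()`),
removing global gain differences (illumination, anesthetic depth,
hemodynamic reactivity). Normalized values are invariant under any global
positive gain applied to the movie — a property the acceptance suite
checks end-to-end. V1 itself is compared across animals on raw fractional
amplitudes (its normalized value is 1 by construction).

## Statistics

One-way ANOVA (genotype at a single age) and two-way ANOVA
(genotype × age, or genotype × sex) with Bonferroni post hoc pairwise
t-tests on the pooled residual variance. Balanced designs use the
classical cell-means decomposition. The developmental design is unbalanced
(cells 7, 5, 6, 6, 7, 7); the sums-of-squares type is not stated in the
protocol, so the default is **Type III with sum-to-zero contrasts** (the
convention of the commercial packages typically used in this literature),
with Type II available. The interaction term is included by default: with
38 animals and 3 × 2 cells it reproduces the printed error df of 32, which
is consistent with the model that includes it. p-values come from the F
distribution; no permutation option is provided because none is described
in the protocol.

`rejection_rate()` wraps the response-level simulator for type-I-error and
power calibration: under a null design the genotype test rejects at the
nominal rate, and a programmed 30% dorsal-stream reduction with
between-animal SD of 15% and n = 7 per genotype is detected with power
above 0.9.

## The synthetic world, and what a green test establishes

`build_default_sheet()` lays out one large V1 and five HVA rectangles (LM,
LI, AL, RL, merged AM/PM) on a 128 × 128 px raw field with affine
retinotopy per area; mirror areas reverse the azimuth axis so the field
sign alternates across every shared border (LM, AL, RL, AM/PM border V1;
LI borders LM). Same-sign areas never touch: they are separated by
unresponsive gaps wide enough (≥ 8 raw px) that the responsive mask — not
the field sign — separates them, as in real cortex where non-responsive
tissue intervenes. Defaults chosen once and stated:

* $\Delta R/R$ amplitudes 0.005–0.008 (V1 strongest), baseline 3000
  counts: typical intrinsic-signal fractional changes with headroom under
  the 12-bit ceiling.
* Hemodynamic delay 1.5 s; raised-cosine response waveform with 0.5 duty
  cycle. Only the waveform's first-harmonic coefficient and delay matter
  downstream, because the analysis uses a single Fourier component —
  which is why no biophysical hemodynamic kernel is modeled.
* Noise: white $\sigma = 50$ counts (shot-noise scale at a 3000-count
  baseline, $\sqrt{3000}\approx 55$), global sinusoidal drift (30 counts,
  120 s) and a global 0.9 Hz physiological line (10 counts) — deliberately
  not harmonically related to the 0.125 Hz stimulus.
* Test movies run 10 cycles rather than the full 50, purely for runtime.

What the simulator does **not** emulate: vasculature artifacts, spatially
structured noise, motion, bleaching, real hemodynamic kernel shape,
curved cortex, or irregular area shapes. A green recovery test therefore
establishes that the pipeline inverts its own forward model under
realistic amplitude/noise ratios — parameter recovery, not biological
validity. Conversely, the statistics layer is validated against
brute-force oracles and an independent implementation, and the printed
degrees of freedom of the factorial designs are reproduced exactly.

The map-fidelity gate (`map_fidelity()`) stands in for the protocol's
qualitative "high-fidelity map not obtainable" exclusion: power at the
stimulus bin over mean power in a flank band above it (harmonic bins
excluded; the band sits above the stimulus bin because slow drift leaks
into the bins below), averaged over well-illuminated pixels. White-noise
movies score ≈ 1, clean simulated animals score orders of magnitude
higher; the exclusion threshold defaults to 3 and is configurable.

## Known limitations

* Hemodynamic delay is not estimated from data; real-data azimuth maps
  carry a constant offset unless the user supplies a delay.
* Area naming assumes a roughly normal mouse HVA arrangement relative to
  V1; grossly atypical layouts should use `import_labels()`.
* The TIFF codec covers the baseline uncompressed grayscale subset
  (16-bit unsigned, 32-bit float) — deliberate, since no R TIFF reader is
  assumed available; it is cross-validated against an independent Python
  reader in the tests.
* One seed drives each simulated movie; physiological noise is spatially
  uniform, so spatial noise correlations are absent by construction.
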