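---
title: "Methods: from sensor glucose to task-free DOT connectivity"
author: "glucodot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from sensor glucose to task-free DOT connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and of the
design decisions taken where the underlying methodology leaves choices
open. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The scientific question and the pipeline

Preterm neonates frequently traverse hypo- and hyperglycemic episodes in
their first days of life while continuous glucose monitoring (CGM) and
optical brain monitoring can run side by side. The pipeline asks: do
patients with larger glucose variability show larger changes in
task-free functional connectivity (tfFC) between an early euglycemic
window and a late one, days apart? Connectivity is estimated from
continuous-wave diffuse optical tomography (DOT): 8 sources and 8
detectors at approximate 10-5 scalp positions, 64 source-detector pairs
at two wavelengths (780/850 nm), 10 Hz.

The stages, in fixed order: CGM event analytics and patient inclusion;
delimitation of the first/last euglycemic spans; quality-driven
selection of one 5-min DOT window per span; optical-density conversion,
wavelet motion correction and 0.009–0.08 Hz band-pass; Tikhonov image
reconstruction and hemoglobin unmixing; surface mapping; nine-ROI
connectivity with Fisher-Z statistics; and the cohort-level association
between per-patient connectivity change ΔZ and eight glucose metrics.

## 2. CGM analytics

**Classification.** Euglycemia is 72–144 mg/dL inclusive. The published
severity thresholds are strict inequalities that leave 47–48 and
179–180 mg/dL unassigned; the package completes them half-open so that
every value has exactly one class — severe hypo (0, 47), mild hypo
[47, 72), mild hyper (144, 180], severe hyper (180, ∞) — preserving each
printed strict inequality. The completion is configurable
(`classify_sample(thresholds = ...)`).

**Events** are maximal runs of at least four consecutive samples (15 min
spanned) in one non-euglycemic class, broken by gaps. Two duration
conventions circulate: sample count × 5 min (four samples = 20 min of
coverage) and inter-sample span (15 min). `classify_events()` returns
both (`duration_min`, `span_min`); the sample-count figure is the
package default wherever a single number is needed, e.g. in the pooled
event-duration distribution whose first quartile defines the critical
gap. The quartile uses linear interpolation between order statistics
(type 7), with a nearest-rank option. Adjacent runs of different
severity (mild then severe) are distinct events by default;
`merge_severity = TRUE` pools each direction.

**Spans.** The first euglycemic span runs from acquisition start to the
first event's onset, the last from the first sample after the final
event to the end of the trace (or its last euglycemic sample). When the
separation falls below 510 min, the first span's end is anticipated
preferentially — that choice keeps the last window adjacent to the last
event, which is where the post-excursion connectivity change is expected
— and only if the first span would collapse below the minimum usable
window is the last span's start postponed.

**Metrics** (mean, SD, MIN, MAX, TIR, TOR, TBR, TAR) are computed over
present samples; percentages use present samples as the denominator,
since gap handling in the percentage denominators is not otherwise
specified. TIR + TOR = 100 and TOR = TBR + TAR hold by construction and
are asserted exactly in the tests.

## 3. Window quality and coverage

Channel pruning keeps a channel when its window-mean intensity lies in
[5e-4, 3] and its SNR (mean/SD) is at least 1; a source-detector pair is
usable only if both wavelengths pass, because two-wavelength unmixing
needs both. The spectral screen computes a Welch PSD — 60-s Hann
segments, 50% overlap, one-sided density — of the *demeaned* intensity
and flags peaks ≥ 0.09 W/Hz in 0.05–2 Hz or ≥ 0.01 W/Hz in 3–4 Hz.
Demeaning (rather than mean-normalizing) keeps the screen invariant
under constant offsets and treats the published thresholds as the
absolute spectral densities they are; the synthetic device emits
source-calibrated, order-one intensities, so the numbers are directly
comparable.

**Coverage threshold.** The threshold separating "covered" from
"uncovered" nodes is parameterized by the minimum measurable intensity
change (pthresh = 1%), the expected activation volume (10 mm³), the
median per-node volume V̂ of the model, and the expected absorption
change (0.001 /mm). Its published formula is typographically ambiguous
between dividing and multiplying by the activation-volume factor. The
package exposes both readings. `coverage_threshold()` defaults to the
division reading (a node must produce a measurable intensity change when
activated), but on the desk-scale synthetic hemisphere that reading
yields a threshold (~124 ΔOD per mm⁻¹ at V̂ = 125 mm³) far above any
attainable aggregate sensitivity (ROI means 4–21), so every window would
be infeasible and every ROI excluded. The pipeline-level defaults
(`analyze_cohort()`, `run_all()`) therefore use the multiplicative
reading, which lands below the sensitivity range and makes the coverage
rule permissive; forced-exclusion behavior is exercised in the tests by
passing explicit thresholds. Both readings remain configuration.

**Selection.** Candidate 5-min windows advance in 1-min steps. Feasible
candidates (all nine ROI mean sensitivities at or above the threshold)
compete on total sensitivity, earliest start breaking ties; if none is
feasible the fallback ranks by covered-ROI count, then total — a
two-key ordering documented here because the base method does not say
what happened when the threshold failed everywhere.

## 4. Preprocessing

Optical density is −ln(I/Ī) against the window-mean intensity, making
the result invariant to per-channel gain.

Wavelet motion correction uses the periodized orthogonal Daubechies-5
transform with per-level interquartile thresholding (coefficients
outside [Q1 − 1.2·IQR, Q3 + 1.2·IQR] are zeroed). The decomposition
depth defaults to 6 at 10 Hz: levels are added while each detail band's
upper edge stays above 0.08 Hz, the band-pass edge that follows. An
earlier rule — decompose until the detail band drops below 0.1 Hz,
i.e. one level deeper — was abandoned after implementation showed that
the seventh level of a 5-min window holds only 24 coefficients, too few
for stable quartile estimates: the bounds then zero legitimate
coefficients inside the 0.039–0.078 Hz portion of the analysis band,
visibly distorting recovered connectivity. At depth 6 every thresholded
level keeps ≥ 48 coefficients and the analysis band sits in the
untouched approximation; spike transients, whose energy lives at fine
scales, are still removed where they occur. Depth and family remain
arguments. The compiled core is checked against a pure-R reference
transform in the tests.

The band-pass is a cascade of order-3 Butterworth high- and low-pass
sections (0.009 and 0.08 Hz) applied forward–backward, with
odd-reflection edge padding; the cascade of two third-order sections is
numerically safe at the extreme 0.0018 normalized cutoff where a single
sixth-order band-pass polynomial is not. An FFT brick-wall alternative
(`method = "fft"`) exists for verification. Zero-phase behavior (peak
cross-correlation lag 0) and the ±5% passband / ≥20 dB stopband contract
are asserted in the tests.

The stage order OD → wavelet → band-pass is fixed; wavelet correction
operates on OD per wavelength.

## 5. Reconstruction

The Jacobian maps nodewise absorption change (per mm) to channel OD
change. For synthetic data it is the analytic adjoint (Rytov)
sensitivity of a homogeneous semi-infinite medium: J(ch, node) =
V · G(s, node) G(node, d) / G(s, d), with G the CW diffusion Green's
function with an extrapolated-boundary image source, optodes sunk one
transport length below the scalp along the local normal, node-optode
distances floored at 1 mm, and V the per-node volume. Defaults
μa = 0.01 /mm, μs′ = 1.0 /mm at both wavelengths, configurable per
wavelength. Precomputed Jacobians load through `read_jacobian()`.

Inversion is `J# = Jᵀ (J Jᵀ + λ·smax·I)⁻¹` with λ = 0.1 and smax the
largest eigenvalue of the symmetric J Jᵀ (equal to its largest singular
value), evaluated by a symmetric solve rather than explicit inversion.
The conventional placement of the regularizer inside the inverse is
used. Reconstruction is decoupled per wavelength followed by an exact
per-node 2×2 spectral unmixing with packaged base-10 extinction
coefficients (mm⁻¹ µM⁻¹: 780 nm — HbO 7.10e-5, HbR 1.075e-4; 850 nm —
HbO 1.058e-4, HbR 6.913e-5; ln 10 applied in the Beer–Lambert
conversion), overridable in `recon_config()`. Surface mapping assigns
each cortical node the mean of volumetric values within 3 mm; an empty
sphere (possible on coarse grids) falls back to the nearest volumetric
node and is flagged. Regularized reconstruction underestimates planted
peak amplitudes; the tests assert the direction of that bias rather than
pretending it away.

Because every stage after the (nonlinear) wavelet step is linear and
time-separable, reconstruction → unmixing → surface mapping → ROI
averaging collapses, for a fixed channel mask, into one 9 × channels
operator per wavelength and chromophore (`roi_projection()`). The
collapse is an algebraic identity, asserted against the explicit path at
1e-12, and is what makes cohort-scale Monte-Carlo validation affordable.

## 6. Connectivity and statistics

The nine ROIs are 15-mm spheres at the 10-20 positions. Each surface
node carries one label: nodes inside both a central (FZ/CZ/PZ) and a
lateral sphere go to the lateral one (the specified precedence); any
other overlap resolves to the nearest center, a choice this package
documents because only the central-lateral case is specified. An ROI
enters the analysis only if at least one third of its member nodes are
covered; ROI courses average covered nodes only.

Pearson R matrices become Fisher Z with |R| clipped to 1 − 1e-7, so
degenerate identical courses produce a finite sentinel (atanh(1 − 1e-7)
≈ 8.06) rather than infinity. Group t-values per window are
t = mean(Z)/(sd(Z)/√n) on n − 1 degrees of freedom with missing patients
dropped; the first-vs-last comparison is an unpaired pooled-variance
t-test by default, with Welch and paired variants available (the same
patients contribute to both windows, so a paired reading is plausible
but not what the base description states). BH step-up adjustment is
delegated to `stats::p.adjust(method = "BH")` and cross-checked in the
tests against a brute-force all-thresholds oracle.

## 7. The synthetic cohort: what it emulates and what it does not

The generator's defaults are the study conditions: 5-min CGM cadence,
euglycemic AR(1) baseline (mean 105 mg/dL, lag-1 coefficient 0.9,
patient-specific SD 6–14 mg/dL) clipped to range, excursions held inside
their class band, gaps as missing runs; 10-Hz two-wavelength recordings
on the 44-mm hemisphere (27.9-cm head circumference) with 64 pairs;
hemodynamics with HbO amplitude 1 µM, ΔHbR = −0.3·ΔHbO plus independent
per-ROI noise (0.2 of the HbR scale), band 0.01–0.08 Hz; multiplicative
measurement noise at 0.5% CV; motion spikes as 1–2 s OD transients;
narrowband 3–4 Hz light contamination of a few percent of the calibrated
intensity, optionally time-gated.

**Exact latent correlations.** ROI latents are built by band-pass
filtering white noise and then whitening the *realized* covariance
before mixing with a square root of the target matrix. Plain Cholesky
mixing is only exact in expectation; at 3000 samples a 0.01–0.08 Hz
process has ~40 effective degrees of freedom, so sample correlations
would wander ±0.08 around the target, and no downstream recovery check
could attribute misses to the pipeline. Whitening makes the planted
sample correlation exact so that every deviation measured after
reconstruction is attributable to the pipeline itself.

**HbR noise is planted per ROI, not per node.** That keeps the forward
model low-rank (ROI loadings × latents), which is what lets a cohort
replicate simulate in ~1 s; ground truth is used at ROI level anyway.

**The planted cohort relation.** Each patient's last-window target
correlation for the planted pair satisfies ΔZ = b·SD + ε with b scaled
so the systematic ΔZ spread across the cohort is `delta_sd` (default
0.75) and ε sized for the requested population correlation (default
0.9). The 0.75 default reproduces measured effect sizes of the magnitude
cohort studies of this kind report (ΔtfFC–SD correlations near 0.9 at
n = 12), which requires the true spread to sit well above the ~0.22
Fisher-Z estimation noise contributed by two 5-min windows at 0.009–0.08
Hz.

What the generator does **not** emulate: layered skull/CSF optics, a
realistic folded cortex or atlas mesh, infant motion biomechanics,
systemic physiology (cardiac, respiratory, Mayer waves), CGM sensor
drift and recalibration steps, or sleep states. Passing tests therefore
demonstrate the pipeline's correctness and statistical behavior under
its stated model, not performance on real neonatal data.

## 8. Validation design and problem sizes

The test suite runs the classifier against a brute-force scanner on
1,000 random traces (exact agreement), checks the Tikhonov residual
identity on random 20×50 systems at 1e-8 and the λ→0 pseudoinverse limit
at 1e-6, localizes planted absorption blobs at cortical depth (6–11 mm)
within two grid spacings in ≥18/20 seeds, recovers a planted r = 0.7
through the full chain within ±0.15 in ≥18/20 seeds, verifies FDR
control under a 500-replicate global null, requires artifact-avoiding
window selection in ≥95/100 trials, and runs the end-to-end
planted-effect experiment on 50 planted and 25 null 12-patient cohorts.
The 5-mm grid (≈970 volumetric, 600 surface nodes) keeps a full cohort
replicate around three seconds; all sizes are package choices recorded
here.

One clause of that experiment is expected to fail and is left failing.
With the association family at its default — all 36 ROI pairs × 8
metrics within a chromophore, m = 288 — the planted cell's BH-adjusted
p-value needs a raw p ≤ 0.05·rank/288. At population R = 0.9 and n = 12
the sample correlation's Fisher z is approximately N(atanh 0.9, 1/3), so
even an error-free ΔZ measurement passes that bar in only ~70–78% of
cohorts, below the 80% detection target; the pipeline's estimation noise
lowers it further. The detection clause is therefore unattainable under
this family for any implementation, and the package reports the honest
rate rather than narrowing the family after the fact. The effect-size
clause (estimated R ≥ 0.6) and the null-cohort false-positive control do
pass, and `correlate_with_metrics(fdr_family = "per_metric")` exposes
the smaller family for users who prefer it.

## 9. Known limitations

Welch segments shorter than 60 s would not resolve the 0.05 Hz band
edge, so `psd_flags()` requires 5-min windows. The hemispherical
geometry makes deep-ROI sensitivity optimistic relative to a folded
cortex. Reconstruction crosstalk inflates correlations between
neighboring ROIs (visible in the worked example in the README);
analyses of this kind should interpret short-distance edges cautiously.
The Fisher-Z sentinel makes identical courses yield Z ≈ 8.06 rather
than an error — downstream group statistics treat it as a legitimate
value. CGM device calibration against blood samples is out of scope;
traces are taken at face value.
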