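---
title: "Methods: ripple detection, gamma quantification and biomarker statistics in lfpmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ripple detection, gamma quantification and biomarker statistics in lfpmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lfpmark)
```

`lfpmark` re-implements, as tested R code over synthetic ground truth, a
quantitative analysis pipeline for hippocampal slice electrophysiology
and CSF biomarker cohorts: automatic sharp-wave-ripple (SWR) detection,
carbachol-gamma spectral quantification with unit/burst tiers, and the
diagnostic/correlation statistics used to evaluate CSF analytes such as
NPTX2. This vignette documents the models, the parameters that matter,
the numerical choices, and what the synthetic data do and do not show.

## Sharp-wave ripple detection

The detector operates on a single-channel extracellular trace sampled
at 10 kHz (µV):

1. **Band-pass** 150–250 Hz, 4th-order Butterworth applied
   forward-backward (zero phase). The filter family and order are our
   choice — standard for LFP work and phase-preserving, which the
   boundary logic needs.
2. **Sliding RMS** of the filtered trace, 5 ms centered window. The
   window length is our choice: shorter than the 10 ms minimum event,
   longer than one ripple cycle (4–6.7 ms).
3. **Candidate detection**: excursions of the RMS above
   `background mean + 4 SD`. "Background" is not further defined by
   the method we follow; we use the mean and SD of the RMS over the
   whole recording (`background = "moments"`), with a robust
   median/1.4826·MAD alternative (`"robust"`). Each excursion yields
   one candidate at its RMS apex (the local maximum nearest the
   threshold crossing); candidates closer than 50 ms merge, keeping
   the larger peak.
4. **Wavelet window**: 100 ms on either side of each candidate is cut
   from the *unfiltered* trace and transformed with a Morlet continuous
   wavelet transform (ω₀ = 6, grid 100–300 Hz in 2 Hz steps).
   Candidates whose window would cross the recording edge are discarded
   and counted in the QC log.
5. **Boundaries**: baseline power statistics come from the window's
   first 50 ms at 250 Hz; boundaries are the edges of the excursion of
   the boundary power trace above `baseline mean + 2 SD` that contains
   the window center. The sentence defining this rule fixes only the
   baseline; which power trace is thresholded is ambiguous, so it is a
   config enum: ripple-band mean power (default, the stable choice),
   power at 250 Hz only, or power at the window's peak frequency.
   A candidate with no crossing is dropped (QC-logged).
6. **Measurement**: peak frequency = the grid frequency with maximal
   time-averaged wavelet power inside the boundaries (ties break to the
   lower frequency, for determinism); amplitude = peak-to-trough of the
   band-passed trace inside the boundaries; `mean_rms_sd` = the
   boundary-average RMS in SDs above background.
7. **Rejection**: events shorter than 10 ms (single-unit contamination)
   or with `mean_rms_sd` < 1.5 are rejected; both rules are asserted
   directly in the test suite.

### Temporal resolution of the boundaries

The ω₀ = 6 Morlet at 200 Hz has an amplitude-envelope SD of ≈ 4.8 ms,
so measured boundary spans are the true envelope convolved with that
kernel and cut at a low (2 SD above noise baseline) threshold. Two
consequences users should know:

* Measured durations overestimate short events. A 30 ms ripple measures
  ≈ 28–37 ms (the threshold truncation and the smearing partly cancel);
  an 8 ms packet measures ≈ 12–18 ms at detectable amplitudes. The
  10 ms rejection rule therefore operates on *measured* span: it
  reliably removes events whose supra-threshold span is short (weak,
  spectrally diffuse transients), but a strong, genuinely short ripple
  packet can survive it. No setting of the fixed parameters (ω₀ = 6,
  2 SD boundary, 4 SD detection) avoids this: detection requires
  envelope amplitude ≳ 4× the band noise RMS, and at that amplitude the
  smeared span already exceeds 10 ms.
* Peak-frequency estimates are unbiased (the smearing is in time, not
  frequency); recovery tests bound the mean absolute error at ≤ 5 Hz.

With the default whole-recording moment background, dense event trains
inflate the background SD and raise the effective threshold, biasing
incidence downward at high rates (visible in `analysis/02_detect_swr.R`
at 1.46 events/s). The robust background resists that inflation and
recovers more events at high incidence, at the cost of admitting more
noise events near threshold; we keep moments as the default because it
is the parsimonious reading and behaves better at ordinary incidence.

## Gamma quantification

Power spectra use Welch's method — 2 s Hann segments, 50 % overlap
(0.5 Hz resolution over the 400 s analysis window); only the total
duration is prescribed by the method we follow, the segmentation is
ours. The raw density is whitened by multiplying power by frequency
(the only reading of "normalised by 1/f" consistent with flattening a
1/f background) and z-scored over 3–300 Hz. The gamma peak is the
maximal z inside 20–60 Hz — a symmetric band around the reported
30–40 Hz healthy peak that also captures slowed variants; the 20–60 Hz
band-mean z is reported alongside, since it is not stated whether
published z values are peaks or band averages.

Two structural properties of the z-score matter when interpreting it:

* **Floor**: with ≈ 595 bins in the normalization band, the largest
  noise bin sits at z ≈ 2–4. Tones whose z falls in that range may lose
  the argmax to a noise bin at some seeds.
* **Ceiling**: a single dominant bin saturates at
  z ≈ √(n_bins) ≈ 24, because the bin itself inflates the band SD.
  Monotonicity of peak z in tone amplitude is therefore reliable only
  between floor and ceiling; the test amplitudes (0.125–1 µV against
  the 10 µV default background) sit in that range.

Unit/burst detection high-passes the trace at 300 Hz and classifies
excursions of the absolute trace by peak amplitude relative to the
trace SD (equal to its RMS for the zero-mean filtered signal): 3–10 SD
events are single units, ≥ 10 SD events are hypersynchronous bursts,
deduplicated with a 20 ms refractory (our choice; prevents one
population spike registering repeatedly). Sub-millisecond gaps inside
one biphasic spike are bridged before classification. With a Gaussian
synthetic background the 3 SD tier also captures noise excursions —
real high-passed slice recordings are sparser — so unit *counts* on
synthetic data are dominated by threshold crossings of the background,
while implanted-spike classification (what the tests score) is exact.

## Biomarker statistics

* **ROC**: operating points at midpoints between consecutive distinct
  analyte values plus infinite endpoints; AUC by trapezoid, which
  equals the Mann–Whitney U/(n₁n₂) with ties counted ½ (asserted
  against an all-pairs oracle to 1e-9). Markers run both directions
  (NPTX2 falls in disease, tau rises), so direction `"auto"` orients
  the curve to AUC ≥ 0.5 and records the orientation.
* **Youden cutoff**: maximizes J = sensitivity + specificity − 1; ties
  break by higher accuracy, then lower cutoff (deterministic output).
  J and accuracy are snapped to a 1e-10 grid before comparison so
  floating-point noise cannot break ties that are exact in rational
  arithmetic. Accuracy is (TP+TN)/(TP+FP+TN+FN) at the chosen cutoff.
* **Ratio markers** (e.g., tau/NPTX2) divide per subject with a hard
  error naming any subject whose denominator is ≤ 0.
* **Hippocampal occupancy** HOC = h/(h + t) ∈ [0, 1].
* **Correlations**: pairwise-complete Pearson r with two-sided p from
  the t transform on n − 2 df, one row per (analyte, score) pair; raw
  p values are reported (no multiplicity adjustment, matching the
  convention of the tables this mirrors), with Benjamini–Hochberg as
  an opt-in extra column.
* **Group tests**: Student's pooled-variance two-tailed t test (the
  default of the original analysis software; Welch by flag) and the
  classical equal-variance one-way ANOVA F test. Both are wrappers
  over `stats::t.test`/`stats::oneway.test`; their type-I error is
  calibrated at 1000 null simulations in the acceptance suite.

## The synthetic generators

`generate_lfp()` builds 1/f^β Gaussian noise by FFT spectral shaping of
seeded white noise (exact slope control; the Welch slope of the output
is asserted within ±0.1), then superposes:

* **SWRs** — carrier sinusoid at a frequency drawn uniformly from
  150–250 Hz under a Hann envelope of the drawn duration, on a negative
  Gaussian sharp wave (σ = duration, amplitude 25 µV). Defaults follow
  reported slice statistics: duration 26.6 ± 4 ms (the reported
  between-slice spread is an SEM, so the within-recording SD is our
  choice), envelope amplitude 9 ± 2 µV so that measured peak-to-trough
  matches the reported ≈ 18 µV, incidence 0.5 events/s. Events are
  placed by a homogeneous Poisson process with a 200 ms refractory gap
  between centers, keeping ground truth non-overlapping so recall is
  well defined; whether real per-slice event trains are Poisson is
  unknown — this is a modeling choice, not an empirical claim.
* **Gamma** — a continuous sinusoid (default off; drug-free ripple
  recordings have none). 0.25 µV at the default 10 µV background gives
  peak z ≈ 3.5–6 across seeds, the reported healthy-tissue range.
* **Units/bursts** — biphasic ~1 ms spikes (1 kHz carrier) and ~5 ms
  high-frequency transients (800 Hz carrier), with amplitudes expressed
  as multiples of the 300 Hz high-passed trace SD; each packet template
  is normalized by its post-high-pass peak so the configured multiple
  is exact on the detector's scale. Units are kept ≥ 10 ms away from
  bursts so tier scoring is unambiguous.

The background noise SD default (10 µV) makes the ripple band
(150–250 Hz) noise RMS ≈ 1.9 µV, so default-amplitude ripples sit at
≈ 4–5× the band noise — a deliberately moderate SNR at which the
detector recovers 60–80 % of events; the recovery tests use 8× (the
regime the detection invariants assume), where sensitivity exceeds
0.95.

`generate_cohort()` draws, within each group, a multivariate Gaussian
whose correlation matrix carries the configured analyte–score
correlations (Gaussian copula; |ρ| = 1 handled by an eigenvalue square
root), then scales margins to group means/SDs. Correlations are imposed
*within* group — the clinical correlation tables this mirrors are
computed within the patient group, and a pooled correlation across
groups with different analyte means would not equal the configured ρ.
Analyte concentrations truncate at zero (an assay cannot report
negative picograms); at the default case NPTX2 (296 ± 150 pg/ml) about
2 % of draws truncate, attenuating the realized correlation by < 0.01.
NPTX2 group means default to the reported 1067 (control) and 296 (AD)
pg/ml; SDs (350/150) are our choice for moderate overlap, giving
AUC ≈ 0.97. Companion analytes (tau, p-tau181, Aβ42), the DRS score
(120 ± 12 points) and regional volumes use literature-typical values.

What the synthetic data do **not** emulate: non-Gaussian and
non-stationary backgrounds, electrode drift and line noise, spike
waveform diversity, multi-channel structure, cohort covariates (age,
sex) and missingness patterns. Passing tests therefore demonstrate
algorithmic correctness under the declared statistical model, not
field robustness.

## Problem sizes and determinism

The test suite runs signal tests at 1–2 kHz sampling and 10–120 s
durations; end-to-end ripple recovery uses the full 10 kHz / 100 s
condition over ten seeds, and the gamma acceptance check the full
400 s / 10 kHz condition. `scripts/acceptance.R` recomputes all
headline quantities from scratch at those sizes from a single `--seed`.
All generators consume an explicit integer seed and are bit-identical
across runs; every analysis driver writes a run manifest (package
version, config hash, seed, input checksums, counts) beside its
outputs.

## Known limitations

* Measured SWR durations carry the wavelet smearing described above;
  comparisons across conditions are valid, absolute durations are
  upper-bounded estimates.
* The moment-based background couples the detection threshold to event
  density; use the robust background for very high-incidence traces.
* The original analysis environment's filter type/order and RMS window
  are unpublished; results may differ in detail from the original
  implementation even where the rules match.
* z-scored gamma power compresses at both ends (floor/ceiling above);
  between-condition ordering is meaningful, ratios of z values are not.
* No DeLong confidence intervals for AUC and no post-hoc multiple
  comparison procedures are provided; the correlation table reports raw
  p values by design.
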