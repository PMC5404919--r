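# lfpmark

Analysis pipeline for hippocampal field-potential rhythms and CSF
biomarker diagnostics, for electrophysiologists and biomarker
statisticians who need the standard slice-electrophysiology
quantifications — automatic sharp-wave-ripple (SWR) detection and
carbachol-gamma spectral analysis — together with the clinical
statistics used to evaluate CSF analytes (NPTX2, tau, p-tau, Aβ42) as
dementia biomarkers. Because raw recordings and patient tables for this
kind of study are rarely shareable, the package ships seeded generators
that produce ground-truthed synthetic recordings and cohorts with the
published summary statistics, so every stage is testable end to end.

## What it computes

**SWR detection.** The trace is band-passed 150–250 Hz (zero-phase
4th-order Butterworth) and its 5 ms sliding RMS thresholded at
4 SD above background; each supra-threshold excursion yields a
candidate at its RMS apex. A ±100 ms window of the *unfiltered* trace
around each candidate is Morlet-transformed (ω₀ = 6, 100–300 Hz);
event boundaries are the crossings of ripple-band power above
`baseline mean + 2 SD`, with baseline statistics from the window's
first 50 ms at 250 Hz. Peak frequency comes from the wavelet
transform, amplitude is the peak-to-trough of the band-passed trace
within the boundaries, and events are rejected if the measured span is
< 10 ms or the boundary-average RMS is < 1.5 SD above background.
Summaries report incidence (events/s), mean peak frequency, amplitude
and duration.

**Gamma quantification.** Welch spectra (2 s Hann segments, 50 %
overlap) over 400 s of recording, whitened by multiplying power by
frequency (1/f normalization) and z-scored over 3–300 Hz:

    z(f) = (f·P(f) − mean)/SD,   moments over 3–300 Hz

with the gamma peak the maximal z in 20–60 Hz. Single units and
hypersynchronous bursts are detected on the 300 Hz high-passed trace
at 3 SD and 10 SD amplitude tiers.

**Biomarker statistics.** ROC curves with midpoint cutoffs, trapezoid
AUC (= Mann–Whitney U/(n₁n₂) with ties ½), Youden-index cutoff
J = sensitivity + specificity − 1 and accuracy
(TP+TN)/(TP+FP+TN+FN); ratio markers (tau/NPTX2); hippocampal
occupancy HOC = h/(h+t); pairwise-complete Pearson correlation tables
with t-transform p values; pooled-variance two-tailed t tests and
one-way ANOVA.

## Worked example

```r
library(lfpmark)

# --- simulate a 30 s slice recording with ground-truthed ripples ------
noise <- generate_lfp(synth_lfp_config(duration_s = 30, swr_rate_hz = 0, seed = 1))
sigma_band <- sd(band_pass(noise$recording, 150, 250)$samples)
cfg <- synth_lfp_config(duration_s = 30, swr_rate_hz = 0.5,
                        swr_amplitude_uv = c(8 * sigma_band, 2), seed = 1)
sim <- generate_lfp(cfg)

det <- detect_swrs(sim$recording)
str(det$summary)
#> $ n_events         : int 13
#> $ duration_s       : num 30
#> $ incidence_hz     : num 0.433
#> $ mean_peak_freq_hz: num 194
#> $ mean_amplitude_uv: num 28
#> $ mean_duration_ms : num 25.6

match_ground_truth(det$events[det$events$accepted, ], sim$events)[c("sensitivity", "fdr")]
#> sensitivity 0.867, fdr 0

# --- a synthetic CSF cohort at the published group means --------------
coh <- generate_cohort(cohort_config(seed = 1))   # control 1067, AD 296 pg/ml
r <- roc_curve(coh$NPTX2, coh$group)
y <- youden_cutoff(r)
sprintf("NPTX2 AUC %.3f (%s); cutoff %.0f pg/ml, J %.2f, accuracy %.2f",
        r$auc, r$direction, y$optimal_cutoff, y$youden_j, y$accuracy)
#> "NPTX2 AUC 0.961 (low_is_positive); cutoff 619 pg/ml, J 0.88, accuracy 0.94"

correlate(coh[coh$group == "case", ], "NPTX2", "DRS")
#>   analyte score_name  n pearson_r    p_value
#> 1   NPTX2        DRS 30 0.4446386 0.01382279
```

The detector recovers 13 of 15 implanted ripples with no false
positives at this SNR; the cohort stage reproduces the qualitative
diagnostic picture — NPTX2 is strongly reduced in cases (AUC ≈ 0.96,
low values call disease) and correlates with the Dementia Rating Scale
within the case group at the configured strength.

## Analysis workflow

Numbered drivers under `analysis/` run the full study-shaped analysis
and write tables to `results/` (recordings go to `scratch/`):

1. `01_simulate_lfp.R` — four genotype-like recording conditions with
   differing ripple incidence and peak frequency.
2. `02_detect_swr.R` — detection, ground-truth scoring and the
   incidence/frequency summary table.
3. `03_gamma.R` — 400 s gamma spectra across descending-amplitude
   conditions plus burst/unit detection on the hyperexcitable one.
4. `04_cohort_biomarkers.R` — two synthetic cohorts, per-analyte ROC
   with Youden cutoffs, group tests and the analyte-by-score
   correlation table.

Each driver writes a JSON run manifest (version, config hash, seed,
input checksums) beside its outputs.

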