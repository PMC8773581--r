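---
title: "Spectral and entropy analysis of EEG transitions during anaesthesia emergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral and entropy analysis of EEG transitions during anaesthesia emergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

When a patient emerges from general anaesthesia, the frontal EEG reorganises
in a way that depends on the maintenance anaesthetic. Under propofol the EEG
stays alpha-dominant until close to the behavioural return of responsiveness
(ROR), while under volatile agents (sevoflurane, isoflurane) power in the
beta range and above reappears long before ROR. Processed one-channel
depth-of-anaesthesia indices built from spectral features therefore signal
"awake" at very different lead times depending on the drug, which matters
for anyone using such a monitor to track emergence.

`emergeEEG` implements the full analysis chain needed to quantify this on
single-channel frontal EEG sampled at 100 Hz with a useful band of roughly
6–42 Hz (the band delivered by a common forehead monitor; there is no
delta/theta information in such recordings, and none is analysed):

1. windowed Welch power spectral densities stacked into density spectral
   arrays (DSA), band-power trends and normalized power;
2. permutation entropy (PeEn) trends with the standard parameterisation
   `m = 3`, `tau = 1` after a 30 Hz low-pass;
3. a transparent 0–100 depth index assembled from the published
   sub-parameter family (alpha-ratio, beta-ratio, their difference, burst
   suppression percentage);
4. paired pre/post statistics at loss and return of responsiveness
   (Wilcoxon signed rank, dependent-samples Hedges' *g*, bootstrap AUC);
5. between-group comparisons: per-bin PSD AUCs with a two-neighbouring-bin
   rule, pixel-wise AUC maps with cluster-based reporting, Kruskal–Wallis
   with Dunn's post-hoc comparisons, and the Freeman–Halton exact test for
   demographic tables;
6. a seeded synthetic cohort generator so that every stage is testable
   without clinical recordings.

## The synthetic generator

No public recordings exist for this kind of cohort, so the package ships a
generative model that reproduces the *statistical structure* the analyses
rely on, not the physiology. Each recording is a sum of three independent
band-shaped noise components, each synthesised by frequency-domain shaping
of white Gaussian noise (which gives an exact closed-form PSD, used as the
oracle in the spectral tests):

* **Background**: `1/f^exponent` broadband noise confined to the recorder
  band (default exponent 1, band 6–42 Hz, 50 µV² integrated power).
* **Alpha**: a narrowband component centred at 10 Hz (Gaussian profile,
  roughly 2 Hz wide, 100 µV² at full amplitude). Its amplitude declines
  linearly across emergence to `alpha_wane` (default 0.4) at ROR — the
  waning of anaesthetic alpha towards awakening is real but unquantified,
  so it is an explicit parameter rather than a fixed trajectory.
* **Fast activation**: noise spanning 13 Hz up to the band edge whose
  amplitude follows a logistic ramp with a 60 s rise time. The ramp starts
  a subject-specific *lead time* before ROR, drawn from a Gamma
  distribution with shape 4 around the group mean `beta_onset_mean_s`.
  The Gamma shape produces the right-skewed distribution of wake-like
  durations seen across groups. The component deliberately extends above
  30 Hz: emergence activation of fast activity is broadband, and the upper
  recorder band is exactly where the depth index's log-energy ratios look.
* **Burst suppression** (optional): with probability `bsr_prob`, 2–10 s
  stretches early in emergence have their envelope reduced to 5%.

Default group means place the propofol-like group at a 60 s beta-onset lead
and both volatile-like groups at 300 s, inside a 600 s emergence window
(the 10 min window analysed before ROR), with 60 s of awake-like signal
appended after ROR so that post-event windows exist. Between-subject
variability is log-normal with `subject_sd = 0.2` on component amplitudes;
amplitudes are scaled so typical RMS is 10–30 µV. Induction recordings
cross-fade from an awake-like mixture (fast activity on, alpha weak) to the
alpha-dominant anaesthetised mixture over about 60 s centred on LOR.

Every subject draws from an RNG substream derived by hashing the master
seed with the group label and subject id, so cohorts are bit-reproducible
and a subject's data do not depend on cohort size.

What the generator does **not** emulate: EMG contamination, electrode
artefacts, drug pharmacokinetics, delta/theta dynamics (outside the
recorder band anyway), inter-channel structure, or non-stationary alpha
morphology. Passing tests on this cohort therefore demonstrate that the
analysis chain recovers known structure of this kind; they are not evidence
about any particular clinical data set.

## Spectral conventions

* **Welch PSD**: 2 s Hamming sub-windows, 50% overlap, per-sub-window mean
  removal, one-sided density in µV²/Hz (0.5 Hz resolution at 100 Hz). A
  10 s analysis episode with a 1 s shift builds the DSA. Welch averaging
  was chosen over a single periodogram per episode to trade variance for
  resolution that still cleanly separates alpha from beta.
* **Window timestamps**: the window `[t, t + 10 s)` is indexed by its start
  `t`. "The value 15 s before LOR" is therefore the window *starting* 15 s
  before LOR, which contains exclusively pre-event signal — the point of
  the −15 s/+30 s offsets is that the pre-event sample reflects the
  responsive (or unresponsive) state only.
* **Band edges**: alpha 8–12 Hz, beta 13–30 Hz, reporting band 6–30 Hz
  (conventional edges; the upper reporting limit reflects the 30 Hz
  low-pass applied before entropy analysis and the EMG-prone range above).
* **Decibels** are display-only: `10 log10(power / 1 µV²/Hz)`.

## Permutation entropy

PeEn is the Shannon entropy of the distribution of ordinal patterns of
length `m = 3` at lag `tau = 1`, computed per 10 s episode after a
zero-phase 4th-order Butterworth low-pass at 30 Hz (applied once per
recording to avoid per-window edge transients). Two conventions are fixed
deliberately:

* **Units are bits.** With `m = 3` the maximum is `log2 6 ≈ 2.585` bits;
  reported anaesthesia values around 2.2–2.5 are only consistent with a
  base-2 logarithm (the natural-log maximum would be 1.79).
* **Ties rank by temporal order** (the earlier sample ranks lower) — the
  original ordinal-pattern convention. On continuous EEG ties are a
  measure-zero event, but quantized or synthetic data need a deterministic
  rule for reproducibility.

## The transparent depth index

The commercial index this stands in for is produced by a proprietary
adaptive neuro-fuzzy system; reimplementing it is explicitly out of scope.
Instead, the package computes the published sub-parameter family
transparently from trapezoid band energies floored at 10⁻⁶ µV² (so
suppressed windows stay finite):

* `alpha_ratio = log(E[30–42] / E[6–12])`
* `beta_ratio  = log(E[30–42] / E[11–21])`
* `beta_over_alpha = beta_ratio − alpha_ratio` — stored as a difference of
  logs (equal to the log of the energy-ratio quotient) so no signed logs
  are divided;
* `BS%`: percent of the window whose rectified, smoothed envelope stays
  below 5 µV for at least 2 s.

The composite maps a weighted sum of the three ratios through a logistic
onto 0–100 and then pulls the value towards 0 in proportion to BS%. The
weights (intercept 3.0; 1.2, 1.0 and 0.3 on alpha-ratio, beta-ratio and
their difference) were calibrated **once** on the synthetic generator so
that awake-like spectra map at or above 85 and deep alpha-dominant spectra
at or below 50, and are frozen as package constants — they are never refit
at analysis time. The map is monotone nondecreasing in each spectral ratio
and non-increasing in BS%; full suppression forces 0. No attempt is made to
mimic the commercial index's display smoothing; an optional moving-average
post-filter is available and off by default.

## Statistics

* **Paired transitions**: per subject, the trend value at event −15 s and
  +30 s. The Wilcoxon signed rank test drops zero differences (classic
  convention, count logged) and enumerates the exact null over all sign
  assignments up to n = 15 nonzero differences (midranks, so ties are
  handled exactly); beyond that a tie- and continuity-corrected normal
  approximation is used — the two paths agree within 0.02 at the
  crossover. Hedges' *g* for dependent data is
  `J · mean(d)/sd(d)` with `d = pre − post`, the `n − 1` denominator and
  `J = 1 − 3/(4(n−1) − 1)`; the sign convention makes a parameter
  *decrease* positive. Whether the original analyses used the sd of
  differences or an averaged-variance denominator is not stated anywhere;
  the sd-of-differences reading is implemented and flagged here for
  sensitivity analysis.
* **AUC**: Mann–Whitney `P(Y > X) + ½P(Y = X)`; identical (and tested
  equal) via rank formula and pair counting. For responsiveness the AUC is
  oriented as P(responsive-state value > unresponsive-state value).
* **Bootstrap**: percentile intervals from 10 000 seeded resamples of the
  stated resampling unit — subjects for paired statistics, subjects within
  group for two-group AUCs ("10k-fold" bootstrap with an unstated method
  is read as the minimal percentile bootstrap; Hedges' *g* additionally
  gets a bias-corrected percentile interval). Significance of an AUC means
  its 95% CI excludes 0.5; containment is closed, so an interval touching
  0.5 is *not* significant (conservative).
* **Multiplicity**: per-bin PSD findings are only retained where at least
  two neighbouring frequency bins are jointly significant; map pixels are
  only retained in 4-connected significant clusters of at least
  `cluster_min = 8` pixels. The cluster threshold was fixed by calibrating
  on the null generator (identical groups) so that the family-wise
  false-cluster rate stays within the tested bound; it lives in the
  analysis configuration. AUC maps are computed on a 10 s time grid
  (non-overlapping episodes) — overlapping 1 s-hop windows would make
  neighbouring map columns nearly identical and defeat the cluster null
  calibration, besides costing two orders of magnitude more bootstrap
  work.
* **Dunn's post-hoc** z-tests on mean ranks (tie-corrected) follow a
  significant Kruskal–Wallis test, with Holm step-down over the three
  pairwise comparisons (the adjustment variant is not named in the
  original description; Holm dominates Bonferroni at equal guarantees).
* **Freeman–Halton**: the exact conditional test enumerates every table
  with the observed margins and sums the multivariate hypergeometric
  probabilities of tables no more probable than the observed one
  (probability-ordering two-sided rule, the same convention as Fisher's
  exact test, to which it reduces for 2×2). A seeded Monte-Carlo fallback
  exists for tables beyond the enumeration budget.
* **Wake-like duration before ROR**: the maximal contiguous run of index
  ≥ 80 ending at the last fully pre-ROR window, measured back from ROR;
  a subject below 80 at ROR contributes 0 s. The alternative "total time
  ≥ 80" reading is available behind `contiguous = FALSE`; the
  run-to-ROR reading is the default because it is the only one consistent
  with the 0 s-at-ROR convention.

## Problem sizes and numerical tolerances

The test-suite runs everything on synthetic cohorts sized to what the
method needs rather than to the clinical study: 15 subjects per group for
recovery and direction checks (the study's group size), 600 s emergence
windows for the full pipeline, 60 s windows for the repeated null
calibrations (500 replicates). Spectral identities (Parseval, scaling,
normalization) are asserted at 10⁻⁹ relative where exact and 5–10% where
estimator variance is inherent; the ordinal-entropy implementation is
required to agree with a brute-force pattern dictionary to machine
precision. Energy floors (10⁻⁶ µV²), the closed-interval CI rule, and the
temporal tie policy above are the only places where degenerate inputs need
a convention, and each is tested.

## Known limitations

* The depth index is a transparent proxy: it shares the published inputs
  of the commercial index but not its fitted mapping, so absolute values
  are not comparable between the two — only qualitative behaviour.
* The generator's spectral stationarity within components means artefact
  rejection is limited to non-finite screening; real recordings need
  artefact handling upstream.
* EDF input is not implemented; recordings exchange as CSV (samples plus
  an events sidecar). The format is lossless for this single-channel,
  event-annotated use case.
* The exact Freeman–Halton enumeration is practical for small demographic
  tables (the 2×3 tables here enumerate a few hundred states); larger
  tables fall back to Monte-Carlo.

## A worked run

```{r}
library(emergeEEG)

cfg <- run_config(seed = 1)
study <- run_study(cfg)

study$paired_stats     # Wilcoxon / Hedges g / AUC rows at LOR and ROR
study$map_clusters     # which group comparisons produced retained clusters
study$duration_test    # Kruskal-Wallis over wake-like durations
tidy(study$duration_test)

autoplot(study$maps[["propofol vs isoflurane"]])
plot_durations(study$durations)
```
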