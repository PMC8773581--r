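# emergeEEG

Analysis of single-channel frontal EEG around anaesthetic state
transitions: loss of responsiveness (LOR) during induction and return of
responsiveness (ROR) during emergence. The package is aimed at researchers
studying processed-EEG depth-of-anaesthesia monitoring, where a central
question is how the emergence EEG — and any 0–100 index computed from it —
depends on the maintenance anaesthetic (propofol vs. volatile agents).

## What it computes

For recordings sampled at 100 Hz with a useful band of about 6–42 Hz:

* **Density spectral arrays**: Welch power spectral densities
  (2 s Hamming sub-windows, 50% overlap) of 10 s episodes shifted by 1 s,
  band-power trends, and per-window normalized power.
* **Permutation entropy** (PeEn): the Shannon entropy, in bits, of ordinal
  patterns with embedding dimension m = 3 and lag τ = 1 after a zero-phase
  30 Hz low-pass,

  H = −Σᵢ pᵢ log₂ pᵢ, over the m! ordinal pattern frequencies,

  ranging from 0 (monotone signal) to log₂ 6 ≈ 2.585 bits (iid noise).
* **A transparent depth index**: the published sub-parameter family
  α-ratio = log(E₃₀₋₄₂/E₆₋₁₂), β-ratio = log(E₃₀₋₄₂/E₁₁₋₂₁), their
  difference, and the burst suppression percentage, combined by a frozen
  monotone logistic map onto 0–100 (a proxy for proprietary monitor
  indices, built from the same stated inputs).
* **Paired transition statistics** at event −15 s vs. +30 s: Wilcoxon
  signed rank (exact up to n = 15), dependent-samples Hedges'
  g = J·mean(d)/sd(d) with J = 1 − 3/(4(n−1) − 1), and the Mann–Whitney
  AUC P(Y > X) + ½P(Y = X) with 95% percentile-bootstrap confidence
  intervals (10 000 seeded resamples; an AUC is significant when its CI
  excludes 0.5).
* **Group comparisons**: per-frequency-bin AUCs with a
  two-neighbouring-bin retention rule, pixel-wise time–frequency AUC maps
  with 4-connected cluster reporting, Kruskal–Wallis with Dunn's post-hoc
  (Holm-adjusted) comparisons, the duration the index stays ≥ 80 before
  ROR, and the Freeman–Halton exact test for r×c demographic tables.
* **A seeded synthetic cohort generator** (1/f background + waning 10 Hz
  alpha + logistically ramping beta/fast activation + optional burst
  suppression) so the entire pipeline runs and is tested without clinical
  data.

## Worked example

```r
library(emergeEEG)

study <- run_study(run_config(seed = 1))
study$paired_stats[, c("event", "parameter", "group", "pre_median",
                       "post_median", "p_value", "g", "auc")]
```

```
  event          parameter group    pre_median post_median  p_value      g   auc
1 LOR            peen_bits pooled         2.36        2.21  5.36e-9  3.24  1
2 LOR            csi_like  pooled        81.8        37.6   5.36e-9  3.30  1.00
3 ROR-propofol   peen_bits propofol       2.35        2.38  6.10e-5 -1.31  0.836
4 ROR-propofol   csi_like  propofol      81.4        91.6   6.10e-5 -1.04  0.836
5 ROR-sevoflur…  peen_bits sevoflur…      2.37        2.38  4.89e-1 -0.212 0.573
6 ROR-sevoflur…  csi_like  sevoflur…     83.6        89.8   4.27e-4 -1.13  0.76
7 ROR-isoflur…   peen_bits isoflur…       2.35        2.38  2.62e-3 -0.909 0.773
8 ROR-isoflur…   csi_like  isoflur…      86.6        90.8   3.05e-4 -0.823 0.796
```

Reading the rows: across LOR both parameters drop sharply (positive g is a
decrease by the pre − post convention; AUC near 1 means pre-LOR values
separate cleanly from post-LOR values), while across ROR the changes are
small — under the volatile-like groups the index already sits in the
wake-like range (median 84–87) before the behavioural response, because
the generator activates fast EEG frequencies long before ROR in those
groups. `study$maps` holds the pixel-wise AUC maps for the three group
pairs (`autoplot()` displays them with cluster marks), and
`study$durations` / `study$duration_test` carry the index ≥ 80 duration
analysis (Kruskal–Wallis χ² = 1.67, p = 0.43 on this cohort).

The demographics tables bundled as worked examples give Freeman–Halton
exact p-values of 0.3885 (sex) and 0.7954 (ASA):

```r
freeman_halton(demographics_tables()$sex)$p_value   # 0.3885
freeman_halton(demographics_tables()$asa)$p_value   # 0.7954
```

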