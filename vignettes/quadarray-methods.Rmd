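---
title: "Processing one-color arrays with on-chip replicates: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing one-color arrays with on-chip replicates: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadarray)
```

## The data and the problem

The package processes one-color expression arrays of a design in which
every non-control probe is printed four times on the slide ("on-chip
quadruplicates"), roughly 32,000 transcripts per array. The input is the
tabular output of the vendor's feature-extraction software: one row per
physical feature carrying the processed green-channel signal
(`gProcessedSignal`, in what we call RNA units, RU), a manual flag, a
software outlier flag, and the coefficient of variation of the pixel
intensities inside the feature. One array is hybridized per biological
sample; in the motivating design the samples are three functional iNKT
thymocyte subsets (iNKT1, iNKT2, iNKT17) from two mouse strains, each in
two fully independent experiments.

Arrays differ in overall brightness (labelling yield, scanner gain), so
signals must be placed on a common scale before probes can be compared
across samples; individual printed features fail sporadically, so the
four replicates must be screened before they are averaged; and the low
end of the intensity range is dominated by background, so very low values
carry no quantitative meaning.

## The processing model

**Global linear scaling.** Every signal of array $i$ is multiplied by

$$\mathrm{factor}_i = \frac{P_{75}^{\mathrm{ref}}}{P_{75}(\mathrm{gPS}_i)},
\qquad P_{75}^{\mathrm{ref}} = 1500\ \mathrm{RU},$$

where $P_{75}(\mathrm{gPS}_i)$ is the 75th percentile of the array's raw
non-control signals (all on-chip replicates, before any exclusion). After
scaling, the 75th percentile of every array equals 1500 RU exactly; this
single multiplicative correction assumes brightness differences between
arrays are global and linear, which is the standard assumption for
one-color designs without a reference channel.

**Replicate screening.** Within each probe's quadruplicate the four
exclusion rules are applied in a fixed order with first-match-wins
attribution: (i) manual flag; (ii) software outlier flag; (iii) value
outside $[Q_1 - k\cdot\mathrm{IQR},\ Q_3 + k\cdot\mathrm{IQR}]$ with
$k = 1.42$, the quartiles taken over the group members that survived
rules i–ii (the candidate included); (iv) pixel CV $> 0.5$. Rules i, ii
and iv are per-feature quality flags; rule iii is a distributional fence
that catches gross printing or hybridization failures that carry no flag.

**Collapse and floor.** Surviving members are averaged by the geometric
mean — the natural average for multiplicatively noisy intensities — to
one value per probe and sample. Collapsed values below the surrogate
floor of 20 RU are substituted by 20; the floor represents the intensity
below which the negative-control distribution dominates. A probe whose
four members are all excluded is reported missing (`NA`), not imputed
with the floor: the surrogate is a detection threshold, not a value
estimate.

**Pairwise classification.** On the collapsed matrix, for a pair of
subsets (A, B) a probe is *negligible* when both values are below
500 RU; *unique* to the higher subset when at least one value reaches
500 RU and the max/min fold exceeds 2; *shared* otherwise. Counts per
pair are aggregated across independent experiments as mean ± sample s.d.
Classification is computed per experiment and then averaged — not on
experiment-averaged expression — so that the reported dispersion reflects
true between-experiment variability.

**Group testing.** Accompanying group measurements are compared with a
gated tree: any comparison with $n \le 4$ in either group goes to a
two-tailed Mann–Whitney *U* test (exact when both $n \le 8$ and no ties
are present); with both groups larger, each group is checked for
normality and the unpaired two-tailed *t*-test is used only when both
pass, Mann–Whitney otherwise. With $n \le 4$ no normality check can be
meaningful, hence the hard size gate.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `reference_percentile_value` | 1500 | RU | common scale anchor of the series |
| `percentile` | 75 | % | quantile used for scaling |
| `surrogate_floor` | 20 | RU | lower detection threshold |
| `iqr_multiplier` | 1.42 | IQRs | width of the replicate fences |
| `pixel_cv_max` | 0.5 | — | per-feature pixel-CV cutoff |
| `expression_floor` | 500 | RU | negligible/expressed boundary |
| `fold_threshold` | 2 | fold | shared/unique boundary (strict) |
| `alpha_normality` | 0.05 | — | normality gate level |

All of these are configuration, not code: `pipeline_config()`,
`classify_config()` and `stats_config()` carry them, and the YAML config
file round-trips them for the command-line pipeline.

## Conventions and numerical choices

* **Quantiles.** The procedure's source describes percentiles and
  quartiles without fixing a convention. We use linear interpolation
  between order statistics (`stats::quantile` type 7) everywhere — the
  scaling percentile and the fence quartiles — with a nearest-rank
  (type 1) alternative selectable in the config. Acceptance-style checks
  recover the fence multiplier behaviorally, so they are insensitive to
  this choice as long as it is applied consistently.
* **Fence shape.** "Outside the interval of 1.42 × interquartile range"
  is read as Tukey-style quartile fences
  $[Q_1 - k\,\mathrm{IQR}, Q_3 + k\,\mathrm{IQR}]$ (default); a
  median-centered band $[\mathrm{med} \pm k\,\mathrm{IQR}]$ is provided
  as `fence_convention = "median_centered"` for sensitivity analysis.
  Membership is strict: a value exactly on a fence survives.
* **Rule order.** The four exclusion rules are stated as alternatives;
  we fix the order i→iv and attribute exactly one reason per excluded
  member (first match). Counts per reason in the audit log therefore
  partition the exclusions.
* **Boundary values.** A value of exactly 500 RU counts as expressed; a
  fold of exactly 2 is shared; a pixel CV of exactly 0.5 is tolerated
  ("exceeded"). Boundary-bisection tests locate all three thresholds to
  numerical precision, and are insensitive to the open/closed choice at
  the resolution they run at.
* **Floor placement.** The floor is applied to the collapsed value
  (after averaging), matching the order in which the procedure is
  described; `floor_stage = "pre_collapse"` floors each surviving
  replicate first, for sensitivity analysis. The two differ whenever a
  sub-floor member coexists with expressed members (e.g. members 4 and
  100: post-collapse gives 20, pre-collapse gives $\sqrt{20\cdot100}
  \approx 44.7$).
* **Degenerate groups.** Quadruplicates reduced to one or two members
  still collapse (no minimum-survivor rule); an all-excluded probe is
  `NA`; an all-zero array is a hard error (its percentile cannot anchor
  a scale); fully tied group comparisons return $p = 1$ with a warning
  flag.
* **Scaling population.** The scaling percentile is computed over all
  non-control features before any exclusion. Controls (including
  spike-ins) never enter the percentile or the matrix.

## The synthetic-data generator

`generate_dataset()` emulates the array structure end to end: one array
per strain × subset × experiment, quadruplicate non-control features,
single-copy controls, and a planted per-probe class — sub-floor (values
in 1–15 RU everywhere, exercising the surrogate), negligible (25–350 RU
everywhere), shared (log-normal, clipped to 700–40,000 RU, identical
across subsets), or unique to one subset (base 2,000–8,000 RU, elevated
by `planted_fold`, default 4, in its subset). Replicate values are the
probe mean times log-normal noise (`replicate_noise_log_sd`, default
0.05); planted value outliers multiply or divide by `outlier_magnitude`
(default 8) at rate 1%; manual and software flags and high pixel CVs are
planted at 0.5% each. Every array receives its own log-normal raw scale
factor (log-s.d. 0.25) so that raw 75th percentiles genuinely differ and
normalization has work to do.

The class bands are deliberately separated from the two fixed thresholds
(20 and 500 RU) by wide multiplicative margins, and the default mixture
places the noiseless 75th percentile of a column near 1500 RU, so the
residual scale factor after normalization is close to 1 and the planted
margins survive it. The recorded truth contains the planted class, the
noiseless per-subset means, the pairwise category implied by those means,
and the position of every planted artifact.

Determinism: array-level draws come from the base seed; each probe then
uses its own substream (seed mixed with the probe index) and draws all
its values in a fixed order, so enlarging `n_probes` leaves the draws of
existing probes untouched — fixtures stay stable as tests grow.

What the generator does **not** emulate: spatial scanner artifacts,
probe-sequence effects, correlated failures within slide regions, and
the empirical intensity distribution of any real accession. Passing
recovery tests on this generator therefore demonstrates the pipeline's
correctness under its own model assumptions, not performance on real
scanner output.

## Problem sizes used by the test suite

Desk-scale sizes keep the suite fast while exercising every rule: most
unit fixtures use 1–4 probes built in code; property runs use 1,000
random quadruplicates against brute-force oracles; the end-to-end
recovery run uses 2,000 probes × 6 arrays (three subsets, two
experiments) at planted fold 4 and replicate log-noise 0.05 and requires
≥ 99% agreement with the planted pairwise categories; the decision-tree
calibration runs 5,000 null replicates each for normal and exponential
data at n = 8 vs 8 and requires an empirical type-I error within
[0.03, 0.07] at nominal 0.05. Exhaustive Mann–Whitney enumeration covers
all group sizes up to 5.

## Known limitations

* The variance check mentioned alongside the normality check in the
  motivating protocol is unnamed and its consequence unspecified; it is
  not implemented, and the decision tree branches on normality alone.
* Classification is per probe; multi-probe genes are not collapsed, so
  probe-level Venn counts need not equal transcript-level counts.
* The Mann–Whitney normal approximation (used with ties or n > 8) is
  tie-corrected and continuity-corrected but not exact; the exact branch
  covers the small-n regime the size gate routes there.
* The parser reads the canonical minimal dialect only; genuine vendor
  exports must be adapted via the column mapping in `feature_dialect()`.
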