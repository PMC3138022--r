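---
title: "Methods: MCR screening of chemical mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MCR screening of chemical mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The screening model and its assumptions

`mcrscreen` implements Tier 1 mixture screening under **dose additivity**:
every chemical's risk ratio is assumed to add, regardless of mechanism of
action or target organ. For a mixture of $n$ chemicals with doses $D_j$
and chronic permitted doses $PD_j$,

$$HQ_j = D_j / PD_j, \qquad HI = \sum_j HQ_j, \qquad MHQ = \max_j HQ_j,$$
$$MCR = HI / MHQ, \qquad \text{missed fraction} = 1 - 1/MCR.$$

MCR is bounded by $1 \le MCR \le n$: 1 when a single chemical carries all
the toxicity, $n$ for an equitoxic mixture. It measures how much of the
cumulative (additive) toxicity a chemical-by-chemical assessment would
fail to see, which makes it a triage statistic: mixtures with high HI
*and* MCR near 1 are already caught by single-chemical assessment, while
high HI with larger MCR marks the cases where only a cumulative
assessment finds the problem.

Assumptions a user should keep in mind:

* **Additivity is conservative.** No antagonism or synergy; independent-
  action (response-addition) models are out of scope.
* **The exposure scenario is generic and conservative.** Measured surface
  water is treated as a drinking-water supply consumed at
  `ingestion_rate` = 2 L/day by a `body_weight` = 60 kg adult, and the
  grab-sample concentration is assumed constant over time so chronic
  permitted doses apply. Long-term averages would have narrower ranges,
  so high-concentration samples overestimate chronic HQs.
* **Permitted doses are taken verbatim.** The packaged table carries one
  chronic guidance value per chemical (mg/kg/day) with a source code.
  Three degradates carry PDs derived from the parent compound on a molar
  basis; the table stores the final printed values and the package does
  no molar-weight arithmetic.

## Parameters that matter

| parameter | unit | default | why |
|---|---|---|---|
| `ingestion_rate` | L/day | 2 | conservative adult drinking-water intake |
| `body_weight` | kg | 60 | conservative adult body weight |
| `min_detects` | chemicals | 5 | restricts the analysis to genuine multi-chemical exposures; counted on raw detections, before PD lookup, so filtering is policy-independent |
| `hi_cutoff` | — | 1 | the additive level of concern; classification is strict (`HI > cutoff` is "above", `HI == cutoff` is "below") |
| non-detect policy | — | both cases | Case 1 sets non-detects to 0; Case 2 to $DL/\sqrt{2}$, the usual mid-range substitution for left-censored values |
| `min_group_size` | samples | 10 | group medians by $n$ are not reported for smaller groups |

**The meaning of $n$ depends on the policy.** Under Case 1 the mixture is
the detected chemicals, so $n$ is the number of detects (with a PD);
under Case 2 the imputed non-detects join the mixture, so $n$ is the
number of analytes (with a PD). Chemicals with no permitted dose cannot
enter a dose-additive index at all, so they are excluded from HI, MHQ
*and* $n$ under both policies, with a warning that counts occurrences.
The two survey analytes without a PD occur in well under 1% of samples,
so their exclusion cannot move dataset-level conclusions.

Sophisticated censored-data estimators (regression on order statistics,
censored MLE) are deliberately not used: the point of running both
bounding cases is to show *whether* the non-detect treatment matters, and
for high-HI samples it does not.

## Undefined values and degenerate inputs

$MCR = HI/MHQ$ divides by zero when every HQ is zero — possible under
Case 1 for a sample whose detects all lack PDs, or in constructed data.
The package returns a typed undefined marker (`NA_real_`) with a warning,
propagates it (never coercing to 0 or 1), and excludes such records from
medians, summaries and correlations while counting them in the log.
Ties for the maximum HQ do not affect MCR; the reported `top_chemical`
is the alphabetically first tied name.

## Display rounding

All arithmetic is done in full double precision. Reported MCR values are
conventionally shown at one decimal with **half-up** rounding
(`round_half_up()`): 3.75 displays as 3.8. Base R's `round()` rounds
half-even, which differs at exact ties (0.25 → 0.2); the half-up
convention was chosen because it matches how screening MCRs are
customarily reported, and it is exposed as a plain function rather than
buried in formatting.

## Statistics

**Kendall tau-b** is implemented from the pairwise definition with tie
corrections in both variables, $\tau_b = S/\sqrt{(n_0-n_1)(n_0-n_2)}$,
and a two-sided p-value from the tie-adjusted normal approximation of
$S$ (no continuity correction). Asymptotic rather than exact p-values
were chosen because the statistic is used on hundreds-to-thousands of
samples where the approximation is excellent and exact enumeration is
infeasible; the trade-off is that p-values on very small group-median
series (fewer than ~10 points) are approximate. A completely tied
variable makes $\tau_b$ undefined; the undefined marker is returned with
a warning.

**The two-group comparison of MCR** (samples with HI below vs above the
cutoff — independent groups) uses the two-sample Wilcoxon **rank-sum**
(Mann–Whitney) form, not the signed-rank form, which applies only to
paired data. When both groups have ≤ 10 observations the two-sided
p-value is computed by exact enumeration of all assignments of the pooled
midranks, $p = P(|W - E[W]| \ge |w_{obs} - E[W]|)$; midrank enumeration
handles ties naturally (identical groups give exactly $p = 1$), so the
exact path is used for all small-sample inputs rather than only tie-free
ones. Larger groups use the normal approximation with tie-corrected
variance and a 0.5 continuity correction.

**The correlation suite** runs the six standard analyses per policy:
HI~n, MCR~n and MCR~HI on per-sample values, MCR~HI restricted to
samples above the HI cutoff, and HI~n and MCR~n on group medians
(defined-median groups only). No multiple-testing adjustment is applied;
results are reported with their raw p-values.

## The synthetic generator: a stated world

`generate_dataset()` emulates the *structure* of a national surface-water
pesticide survey so that every pipeline stage is testable without any
external download:

* analyte panels drawn per sample from sizes **{48, 80}** with equal
  weight — the two laboratory method sizes the survey used;
* each panel chemical independently detected with probability **9/70**,
  so an average (~70-analyte) panel yields about 9 detects against ~61
  non-detects, matching the survey's composition table;
* detected concentrations **lognormal** with median 0.05 µg/L
  (`log_mean = log(0.05)`) and `log_sd = 1.5` — detected pesticide
  concentrations in ambient water typically center in the 0.01–1 µg/L
  range and span several orders of magnitude across a national survey;
* a flat detection limit of **0.01 µg/L** (survey DLs mostly fall between
  0.001 and 0.05 µg/L); all four parameters accept per-chemical named
  overrides;
* the RNG is pinned (Mersenne-Twister, inversion normals, rejection
  sampling) under a mandatory seed, and the global RNG state is left
  untouched.

The `dominance_factor` knob models the regime where one chemical carries
nearly all the hazard: the designated chemical (by default the most
potent one, i.e. smallest PD, so the dominance acts on the HQ scale) is
included in every panel, always detected, and its concentration
multiplied by the factor. Forcing ubiquity is a modelling choice: a
"dominant contributor" that is usually absent would not describe the
dominated regime the knob exists to generate.

What the generator does **not** emulate: chemical co-occurrence
correlation (detections are independent), spatial and temporal structure
(sites and dates are decorative), per-chemical heterogeneity in detection
frequency and detection limits (defaults are shared), seasonal
application pulses, and serial samples at a site. Consequently a green
test establishes that the *methodology* behaves correctly on data with
the survey's marginal structure — it does not reproduce, and is not
compared against, the survey's published sample-level numbers, which
depend on the real joint distribution of the external dataset.

## Verification strategy

Every metric and test is checked against an independent oracle computed a
different way: elementwise sum/max recomputation for HI/MHQ; an $O(n^2)$
concordant/discordant/tie pair enumeration for tau-b (agreement to
1e-12); full bitmask enumeration of group assignments for the exact
rank-sum p-value; a flat end-to-end recomputation (policy substitution →
dose → HQ → summary formulas inlined) for the sample pipeline; and
closed forms for equitoxic mixtures ($MCR = n$, $HI = n \cdot hq$).
Property tests cover the invariants $HI = MHQ \times MCR$,
$1 \le MCR \le n$, scale invariance of MCR, monotone growth under
appended entries, Case 2 ≥ Case 1 ordering with equality exactly when no
non-detect is imputable, dominance recovery (factor 100 drives mean MCR
below 1.2), and the rank-sum test's type-I error under an i.i.d. null
(3–7% at $\alpha = 0.05$ over 1000 seeded replicates).

## Known limitations

* Single exposure route (drinking water); no dermal/inhalation, no
  intake or body-weight distributions.
* Permitted doses are point values; no uncertainty propagation.
* The survey-scale published results (sample counts, tau-b values, HI/MCR
  ranges of the real dataset) require the external monitoring download
  and are outside what this package asserts; the package reproduces the
  analyses' structure, not those numbers.
* Kendall tau-b on thousands of samples uses an $O(n^2)$ pair loop —
  fine for $10^3$–$10^4$ samples, not for $10^6$.
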