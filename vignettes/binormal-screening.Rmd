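---
title: "The binormal screening model behind polyscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The binormal screening model behind polyscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyscreen)
```

## The model and its assumptions

`polyscreen` treats a polygenic risk score as a Gaussian trait with unit
standard deviation in both the people who later become affected and those
who do not, the affected mean shifted upward by Δ SD units. This
equal-variance binormal model is the standard working model for continuous
screening markers, and it is attractive here for two reasons. First, it is
exactly the model under which the commonly reported discrimination metrics
are interchangeable, so one parameter captures them all:

- Δ = ln(OR per SD) — from a logistic model in the standardised score, the
  log odds are linear in the score with slope Δ under this model (exact in
  the rare-disease limit);
- Δ = ln(HR per SD) — hazard ratios are converted identically (see
  "Decisions" below);
- Δ = √2 · Φ⁻¹(AUC) — the binormal AUC identity; a C-index is treated as an
  AUC.

Second, every screening quantity becomes closed-form in Δ. With the cut-off
placed at the unaffected distribution's (1 − f) quantile
z = Φ⁻¹(1 − f), the false positive rate is f by construction and the
detection rate is DR_f = 1 − Φ(z − Δ). Three likelihood ratios follow, one
per use case:

| use | likelihood ratio | form |
|---|---|---|
| screening (positive result) | DR_f / f | tail-area ratio above the cut-off |
| individual prediction | exp(Δz − Δ²/2) | density ratio at centile z |
| stratification | [Φ(z₂−Δ) − Φ(z₁−Δ)] / (q₂−q₁) | area ratio over a quantile slice |

Posterior odds of becoming affected are always background odds × LR, with
the likelihood ratio multiplying the affected side only. Centiles and
quantile groups refer to the **unaffected** distribution throughout; where a
published figure could have used mixture-distribution centiles instead, we
adopt the unaffected-distribution convention because it is the one stated in
the methodological literature this model follows, and because it keeps the
cut-off's false positive rate exact.

## Parameters that matter

- **Δ (SD units)** — the only model parameter. Typical published scores sit
  around Δ ≈ 0.3–0.5 (OR per SD 1.3–1.6, AUC 0.58–0.64); a DR_5 of 80%
  needs Δ ≈ 2.49 (OR per SD ≈ 12, AUC ≈ 0.96). Negative Δ (a protectively
  oriented score) is accepted with a warning rather than rejected, so
  mis-oriented catalog records remain analysable.
- **False positive rate f** — default 0.05 (the conventional DR_5 cut-off at
  the unaffected 95th centile). We use the exact quantile
  Φ⁻¹(0.95) = 1.6449…, not the display-rounded 1.645; the difference is far
  below display precision.
- **Background odds** — the population's odds of becoming affected in the
  stated time window (e.g. 10-year odds 1:19 for coronary disease at age
  50). These are always inputs, sourced from external literature; the
  package does no age interpolation.
- **Intervention parameters** — relative risk reduction and adherence, both
  fractions in [0, 1] (e.g. 0.20 and 1 for statin scenarios). They enter
  only as a product scaling event counts.

## Numerical conventions

- **Odds display**: "1:N" normalises the numerator to 1 and rounds N to the
  nearest integer, half away from zero. JSON output carries full precision;
  rounding is presentation-only. Two published odds cells round one unit
  away from this rule (a 2.5th-centile odds recomputing to 54.6 but printed
  as 1:54, and a lowest-quintile odds recomputing to 72.7 but printed as
  1:72) — the source's own rounding pipeline is unstated, so tests allow ±1
  on exactly those two cells and are exact everywhere else.
- **Integer allocation**: stratification tables and screening flows print
  whole people. Expected counts are rounded half away from zero, then
  repaired by largest remainder so each column sums exactly to its total.
  Flow tables round at each stage and derive downstream counts by
  differencing, so the cohort is conserved exactly by construction.
- **Quantiles** in catalog summaries use linear interpolation between order
  statistics (`stats::quantile()` type 7, the R default), fixed so summary
  goldens are stable.
- **Plausibility filters**: continuous-trait records are dropped; then OR/HR
  per SD < 1, AUC < 0.5, and C-index outside (0.5, 1] are removed, each
  counted in its own bucket of the filter report. The C-index bound uses
  (0.5, 1] so that a wildly implausible value (such as a C-index of 632) is
  caught by the > 1 rule while a legitimate 1.0 boundary would not silently
  vanish into a different bucket.
- **Share of cases** in a group has two natural definitions — the continuous
  area under the affected density, or the ratio of rounded counts. The
  continuous definition is canonical; the count-based share is reported
  alongside (`share_of_cases_counts`) because the two can differ by rounding
  in small groups.

## Decisions where the design was open

- **HR per SD = OR per SD for conversion.** The exact treatment of hazard
  ratios in the worksheets this calculus descends from is not published;
  both ratio metrics are pooled through Δ = ln(ratio). This is a documented
  assumption, reasonable because both estimate the same log-linear
  association under rare outcomes; users with incidence data can convert
  externally and pass Δ directly.
- **Aggregation unit is the record**, not the score: published catalog
  summaries count metric estimates, and collapsing a score's multiple
  estimates first is offered (`collapse_scores = TRUE`) but not default.
- **Number needed to genotype** divides the cohort by the difference in
  per-arm prevented events. Passing the whole-event (rounded) prevented
  counts reproduces printed arithmetic — 100000/(974 − 957) = 5882 — while
  passing unrounded products gives the continuous alternative (~5747). The
  function takes the counts as given rather than exposing a rounding flag.
  When genotyping prevents no additional events it signals a classed
  condition (`polyscreen_no_incremental_benefit`) instead of returning an
  infinite or negative number.
- **Treat-all comparator rounding**: events prevented are
  round(rrr × adherence × events), half away from zero, always. A published
  treat-all figure of 1600 arises from applying 20% to the 8%-of-100 000
  background events (8000 × 0.2), not to the 7997 events actually tabulated
  (which gives 1599); the package computes, it does not reproduce rounding
  errors.
- **Two-stage flow background odds**: the published breast-screening flow of
  100 000 women aged 40 is only internally consistent (1538 affected =
  108 + 1430) with 10-year odds of 1:64, the age-40 odds given in the
  accompanying text, although the figure caption says 1:41. The examples and
  tests use 1:64 and treat the caption as an erratum. The stage 1 Δ is an
  input, not hard-coded: the printed 108 affected stage-1 positives implies
  Δ ≈ 0.486, and the reproduction tests check stability over
  Δ ∈ [0.480, 0.492] — the window over which the rounded count stays within
  107–109 (verified by direct enumeration).

## What the synthetic data does and does not emulate

`simulate_prs_cohort()` draws the stated world directly: affected status
Bernoulli(risk), scores N(Δ·affected, 1). It emulates the *phenotypic* score
model only — no genotypes, linkage disequilibrium, effect-size estimation
error, ascertainment, or covariate structure. A green round-trip test
(empirical AUC → Δ within ±0.02 at n = 2×10⁵, empirical screen-positive PPV
within 3 Monte-Carlo SEs of the analytic posterior odds at n = 10⁶)
therefore establishes that the closed forms and the estimators are mutually
consistent *under the model* — not that any real score is binormal, and not
that reported metrics were estimated without bias.

`make_mock_catalog()` plants known violations (OR/HR < 1, AUC < 0.5,
C-index > 1, continuous traits) in known numbers among records whose values
derive from a log-normal Δ distribution, by default median 0.42 and log-SD
0.5 with metric kinds mixed roughly as in public catalog data (31% OR, 10%
HR, 53% AUC, 6% C-index). Median Δ = 0.42 corresponds to a DR_5 near 11%,
a realistic centre for current disease scores; the log-SD of 0.5 spans
weak (Δ ≈ 0.15) to strong (Δ ≈ 1.1) scores within ±1.5 log-SD. These
defaults describe a plausible catalog slice and are not tuned to any
particular summary. The filter-report tests recover the planted counts
exactly, which validates the accounting, not the realism of the mix.

The OR-recovery tolerance is wider (±0.03 on the log scale, risk ≤ 5%)
than the AUC tolerance because ln(OR per SD) equals Δ only in the
rare-disease limit; at a 5% risk the logistic slope is attenuated by
roughly 1–2%.

## Known limitations

- Equal variances are assumed; scores with heavier affected-group tails will
  have their extreme-centile likelihood ratios misestimated.
- All calculations propagate point estimates; no confidence intervals on Δ
  or anything downstream.
- Background odds are taken as given per scenario — no competing risks, no
  age interpolation, no calibration of absolute risk.
- The catalog pipeline deliberately does no ontology traversal or trait
  synonym merging: per-trait groups are exact identifier matches.

```{r example}
cad <- risk_model(0.48)
detection_rate(cad)
format_one_in_n(apply_lr(parse_odds("1:19"), lr_positive(cad)))
```
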