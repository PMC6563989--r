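---
title: "Scoring and comparing animal disease models with fimd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and comparing animal disease models with fimd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fimd)
```

## The problem

Choosing an animal model for a drug-efficacy programme is usually done by
habit: the model most used in the literature wins, whether or not it
reproduces the aspects of the human disease that matter for the drug's
mechanism. `fimd` implements a structured alternative — the Framework to
Identify Models of Disease (FIMD) — in which a model is assessed for one
indication by a weighted questionnaire spanning eight validation domains:
epidemiological, symptomatology and natural history, genetic, biochemical,
aetiological, histological, pharmacological and endpoint validation. The
product is a *validation sheet*: answers with rationales and references,
justified exclusions, per-drug pharmacological evidence, and a score
summary that can be compared across models.

## The same-weight scoring system

The questionnaire distributes 100 points equally: 12.5 per domain, then
equally over the questions within a domain. Splits that terminate within
three decimals are kept exact (6.25, 2.5, 3.125, 12.5); a non-terminating
split is rounded half-up to two decimals with the remainder folded into the
domain's last question, which is the only convention that reproduces the
published 4.17 / 4.17 / 4.16 pattern while keeping every domain total
exactly 12.5.

```{r}
q <- default_questionnaire()
sum(q$questions$weight)
assign_question_weights(12.5, 3)
```

Each question is answered `YES` (full weight), `PARTIAL` (half weight),
`NO` (nothing) or `UNCLEAR`. The half-credit grade is deliberately coarse:
it flags partial mimicry without pretending to quantify its extent.
`UNCLEAR` also earns nothing. The framework defines credit only for full
and partial mimicry; scoring unknown evidence as absent is the
conservative choice and keeps the score no higher than what the definite
evidence supports. The answer is still distinguished from `NO` everywhere
else: it drives the uncertainty factor and the validation level, and the
per-question log in the score breakdown lets users audit the convention.

Questions may be excluded with a justification (for example the two
prognostic-biomarker questions in a disease with no known prognostic
biomarkers). Exclusion removes the question's weight from the attainable
maximum rather than redistributing it: the published worked example rescales
a raw total against 93.75 after two 3.125-point exclusions, which is only
coherent if surviving weights are untouched. Comparability across sheets is
restored by the *equivalent score*, `raw * 100 / max`, reported half-up to
two decimals:

```{r}
effective_weights(q, c("4.3", "4.4"))$max_total
equivalent_score(63.54, 93.75)
```

### Arithmetic choices

Weights and earned scores are carried internally as integer micro-points
(1 point = 10^6 units). Every weight the split rule can produce terminates
within three decimals and a partial grade halves it once, so all
intermediate sums are exact integer arithmetic; only the reported outputs
are rounded. All rounding is half-up (away from zero), not R's default
round-half-even — the published two-decimal scores and one-decimal
percentages (43.75 to 43.8, 34.375 to 34.4, 67.776 to 67.78) are only
reachable under half-up. The helper `round_half_up()` is exported because
downstream consumers comparing against the package's outputs need the same
convention.

## Factors, levels, and the two item modes

Two percentages contextualise the score. The **uncertainty factor** is the
share of items answered `UNCLEAR` in one sheet; the **similarity factor**
is the share of comparable items answered identically in two sheets of the
same indication. Items excluded in either sheet have no answer and leave
both numerator and denominator. Two `UNCLEAR` answers count as agreement by
default — they are the same answer — with `strict = TRUE` available to
restrict agreement to definite evidence.

Both factors accept an `item_mode`. In `"flat"` mode (the default) the
items are the non-excluded questionnaire questions. In `"expanded"` mode
the two drug-response questions are counted once per drug recorded in the
sheet, each drug item answered by the concordance of its model outcome
with its human status (concordant `YES`, mixed `PARTIAL`, discordant `NO`,
no evidence `UNCLEAR`); drug items are matched across sheets by drug name.
Both modes exist because published factor values for the worked
two-model muscular-dystrophy validation (6.1%, 18.2%, 48.5%) are not
expressible over the 19 non-excluded questions but are exactly the
fractions 2/33, 6/33 and 16/33 over an expanded item set
(17 questions + 16 drug items). The package implements both and defaults
to the simpler flat mode rather than guessing which counting a given
author used; the acceptance checks exercise the expanded mode against
those published fractions.

The **validation level** depends only on the percentage of definite
answers, rounded half-up to an integer first (the published bands are
printed on an integer grid) and then banded 0–40 insufficiently, 41–60
slightly, 61–80 moderately, 81–100 highly validated. The bands partition
every attainable percentage.

## Study-level quality assessment

Each drug-intervention study behind the pharmacological domain carries a
reporting-quality checklist (19 tri-state parameters adapted from the
ARRIVE guidelines, `yes`/`no`/`na`) and a risk-of-bias checklist (10 items
adapted from SYRCLE's tool, `low`/`high`/`unclear`). Aggregation is per
model plus a pooled column: reporting cells are the percentage of eligible
(`na`-free) studies answering `yes`; risk-of-bias cells are the low and
unclear percentages, with high risk as the implicit remainder — published
tables print only the low/unclear pair, and rows where the pair sums below
100 imply exactly such a third state. The package never turns per-study
quality or per-drug concordance into questionnaire answers: no aggregation
rule is defined for that step, so it remains the validator's judgment,
surfaced by `drug_concordance()` as evidence.

The packaged `dmd_*` marginal tables hold the published aggregated
percentages for the 32 mdx mouse and 3 GRMD dog studies of the worked DMD
case. `dmd_assessments()` reconstructs 35 synthetic per-study rows whose
counts match those marginals (each count recovered as
`round(pct * N / 100)`); rows are synthetic — matched marginally, not
jointly — which is sufficient for every aggregation the package computes,
including the pooled column:

```{r}
tab <- aggregate_reporting(dmd_assessments())
tab[tab$parameter == "any_blinding", c("label", "mdx mouse", "GRMD dog", "pooled")]
```

## Synthetic sheets

`generate_sheet()` draws one answer per non-excluded question,
independently, from a configurable distribution. The default
(`YES` 0.5, `PARTIAL` 0.2, `NO` 0.2, `UNCLEAR` 0.1) describes a moderately
validated model with a realistic residue of unanswerable questions; the
defaults are fixed once here and the tests recover the configured rates
statistically rather than tuning them. Each generator call uses one
pseudo-random stream derived from its seed only (via `withr::with_seed`),
so fixtures are reproducible across sessions and platforms. The generator
emulates the *statistical* structure of completed sheets — answer mixes,
exclusions, drug evidence, reference years — and none of the content
correlations of real evidence (e.g. a model failing histologically will
not preferentially fail symptomatically). Passing tests therefore
demonstrate the arithmetic and plumbing, not validity judgments on any
real model.

## Rendering

Radar plots show the eight per-domain ratios (earned over attainable
weight, the published worked ratio being 6.25/12.5 = 0.5) with axes in
registry order, first domain at the top, clockwise — no canonical axis
order is published, so the registry order is fixed here to keep plots of
different models superimposable. Fully excluded domains are drawn as axis
gaps, never as zeros: "excluded" must not read as "fails to mimic".
`radar_svg()` writes the SVG as text directly, so identical inputs give
byte-identical files on any R build; `plot_radar()` offers a conventional
ggplot2 polar view for interactive work. Reports print every number
verbatim from the score breakdown — the renderer never re-rounds.

## Problem sizes and tolerances

The test-suite and acceptance checks run at desk scale: the full
21-question registry, weight splits up to 50 questions per domain, 1 000
seeded sheets for score monotonicity, 40–60 sheets for rate recovery
(three binomial standard errors of the mean), and 2 000–10 000 synthetic
studies for compliance recovery (within 2 percentage points of the
configured 40%). Exact quantities (weights, totals, rescales, published
table cells) are asserted exactly at their printed precision.

## Known limitations

* Weights are uniform within domains. Indication-specific weighting would
  need a calibration model linking questionnaire answers to translational
  outcomes, which requires many completed validations; the registry file
  format anticipates variant questionnaires via the version string.
* The half-credit partial grade compresses very different degrees of
  partial mimicry into one value.
* Sheets are single-rater documents; the package computes no inter-rater
  statistics.
* Quality aggregation reports percentages without verdicts: no published
  guidance exists for interpreting them, so none is invented here.
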