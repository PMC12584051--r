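---
title: "A point-based reimbursement model for diagnostic AI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A point-based reimbursement model for diagnostic AI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddssfee)
```

AI-based diagnostic decision support systems (DDSS) — triage of chest
radiographs, autonomous ECG reads, slide-level pathology review — deliver
measurable clinical value but mostly sit outside established fee schedules,
so there is no routine way to bill for them. `ddssfee` implements a
structured valuation pipeline that plugs such services into point-based
billing logic of the kind used by the German GOÄ (private) and EBM
(statutory) schedules, and translates the resulting point values into
RVU-based fee-for-service and capitated systems.

This vignette documents the model itself: the scoring rubric, the fee
engine, the cost–benefit calculator, the crosswalks, the simulator that
verifies the closed forms, and the numerical and design choices made where
the procedure left room.

## The scoring rubric and canonical tiers

A service is rated on four dimensions, each an integer from 1 (low) to
5 (high): data complexity/diversity, disease complexity, clinical-question
complexity, and degree of AI involvement. `dimension_anchors()` carries the
endpoint descriptions raters consult; the anchors are documentation, not
computable constraints — the package validates only that ratings are
integers in 1–5.

The four ratings enter with equal weight: the tier is driven by the plain
arithmetic mean, and a rounded mean of 1–2 maps to **50 points**
(assistive), 3 to **100 points** (augmentative), and 4–5 to **150 points**
(high-complexity augmentative or autonomous). A small fixed tier set is
deliberate — it avoids over-fitting point values to individual services and
keeps the schedule auditable.

```{r}
tier <- assign_tier(score_vector(2, 2, 3, 3))
tier
```

**Rounding the mean.** Means end in .0, .25, .5 or .75, so the only
genuinely ambiguous case is the exact half. The package rounds half away
from zero by default (2.5 → 3), a deterministic and widely understood
commercial rule; IEEE half-to-even can be selected via
`rounding = "half_even"` for sensitivity analysis. The choice only matters
at means of exactly 2.5 or 3.5.

**Perturbation stability.** `perturbation_stability()` enumerates all
eight ±1 single-dimension perturbations and reports whether the tier is
invariant. Perturbations that would leave the 1–5 scale are clipped back to
it and marked in the attached trace; clipping (rather than dropping the
perturbation) keeps the check defined at the scale boundaries. A vector
such as (2,2,2,3) is *unstable*: raising any 2 lifts the mean to exactly
2.5, which tips the tier from 50 to 100 under half-up rounding.

**Level suggestion.** The billing-code prefix encodes the AI contribution
level (I assistive, II augmentative, III autonomous). Those levels are
defined narratively, not as a score formula, so `suggest_level()` offers
only an advisory mapping from the involvement rating alone (1–2 → I,
3–4 → II, 5 → III; autonomy requires the maximal involvement rating). A
registry's recorded level is always authoritative over the suggestion.

## The fee engine

Fees follow the schedule formula

$$\text{Fee} = \text{Points} \times \text{PointValue} \times \text{Factor},$$

rounded half-up to whole cents once, at the end. Intermediate products are
never rounded; whether the factor multiplies before or after cent rounding
is not prescribed anywhere, and multiplying before (as here) can differ
from the alternative by at most one cent.

Three point-value regimes ship as presets:

```{r}
for (r in fee_regimes()) print(r)
```

* `goa` uses the exact statutory point value 0.0582873 EUR rather than the
  commonly quoted "about €0.058", because only the exact value reproduces
  the published base fees for the reference imaging codes (280 points →
  €16.32, 2000 → €116.57, 4400 → €256.46). Its factor policy is the legacy
  1.0–3.5 range with 2.3 as the customary rate.
* `ebm-2025` uses the 2025 orientation value 0.123934 EUR/point
  (82 points → €10.16).
* `ebm-simplified` uses a rounded 0.12 EUR/point and is the regime behind
  the packaged AI code table's Base € column. For AI services both EBM
  regimes cap the multiplier at 2.0: deviations from 1.0 are meant to be
  exceptional, documented, and visible on the invoice.

One published EBM comparison (cranial CT, 534 points, €66.20) is internally
inconsistent with the 82-point value above (534 × 0.123934 = €66.18) and is
therefore not used as a reference fixture anywhere in the package.

The packaged registry holds five illustrative AI codes across the three
levels:

```{r}
regenerate_table(ai_code_table(), "ebm-simplified")
```

Registry point values are *authoritative*: two of the five codes (60 and
80 points) sit off the canonical 50/100/150 tiers because they were
anchor-calibrated against existing comparator codes, and
`tier_consistency_report()` flags them as registry-authoritative deviations
rather than errors. Likewise the autonomous ECG code carries 100 points —
anchored to the established valuation of autonomous retinal screening —
even though a literal reading of the rubric's top tier could suggest 150.

`itemize_invoice()` enforces the transparency rules at billing time: an
unknown code is rejected, any factor ≠ 1.0 requires a non-empty
justification note that is carried on the fee line, and factors above the
AI policy cap (2.0 by default, configurable but always enforced) are
rejected even where a legacy regime would allow them.

## The cost–benefit and break-even calculator

The calculator runs the six-step illustrative payer check: choose accuracy
under standard of care (SoC) and with AI, turn them into expected
misclassification counts, attach flat downstream costs, add the AI fee,
and report the net payer impact and the break-even fee. For a cohort of
$n$ cases with prevalence $\pi$,

$$\mathbb{E}[\mathrm{FN}] = \pi n (1 - \mathrm{Se}), \qquad
  \mathbb{E}[\mathrm{FP}] = (1-\pi) n (1 - \mathrm{Sp}),$$

per scenario. Avoided counts are SoC minus AI; the avoided downstream cost
is `avoided_fn * cost_fn + avoided_fp * cost_fp`; AI spend is
`ai_fee * n`; and

$$\text{net payer impact} = \text{AI spend} - \text{avoided downstream cost},$$

so a *negative* value is a payer saving. The sign convention is stated on
every report because the two orders of subtraction are both in circulation;
the package fixes the convention that matches the worked example's
"minus €2,050" reading. The break-even fee `avoided_downstream_cost / n`
is the unique zero of the net impact, which is linear in the AI fee with
slope $n$.

```{r}
cost_benefit(worked_example_inputs())
```

Expected counts are kept as real numbers — rounding 4.7 avoided cases to 5
belongs in display, not in the arithmetic. Results are reported both at
the requested $n$ and normalized per 1,000 cases, the customary reporting
unit. Downstream costs enter as flat per-event averages; no discounting,
risk adjustment, QALYs or cohort modelling — this is an auditable
feasibility check, not a full health-economic evaluation. The provider
side is limited to staff-time hours (`minutes_saved * n / 60`); wages are
deliberately not monetized by default.

`one_way_sensitivity()` varies a single named input over a grid with
everything else at baseline, which is how the linearity of the net impact
in the AI fee (and its zero at the break-even fee) is exercised in the
test suite.

## Crosswalks into RVU and capitated systems

Points are a currency-neutral relative valuation, so other systems attach
via a single slope. For RVU systems,

$$\mathrm{RVU} = \kappa \cdot \text{Points}, \qquad
  \text{Payment} = \mathrm{RVU} \times \mathrm{CF}.$$

`calibrate_kappa()` fits κ from anchors — services with an established RVU
or payment valuation. One anchor gives the exact ratio; several are fitted
by least squares *through the origin*, because a zero-point service must
map to zero RVU. The fit can be volume-weighted; per-anchor residuals are
always reported, and no acceptance threshold on residuals is imposed — the
choice among conflicting anchors is a policy judgement the package
surfaces rather than makes. Payment ratios between services equal their
point ratios for any κ and CF, preserving the schedule's relative
valuations. An RVU may be split into work / practice-expense / malpractice
components with `split_rvu()`, but only with caller-supplied fractions
summing to one: how much of an AI service is "work" depends on the level
of AI involvement and carries no defensible default.

```{r}
anchor <- crosswalk_anchor("autonomous screening comparator", 100,
                           payment = 45, conversion_factor = 30)
kappa <- calibrate_kappa(anchor)$kappa
map_payment(150, kappa, conversion_factor = 30)
```

For capitated systems the service enters as a per-member-per-month add-on,

$$\mathrm{PMPM} = \rho \cdot u \cdot \text{Points} \cdot
  \text{PointValue} / 12,$$

with pathway prevalence ρ and expected annual uses per eligible member u.
Quality-linked capitation bonuses (payments keyed to verifiable
outcome thresholds) are a recognised extension of this mechanism but have
no agreed formula, so they are named here and not implemented.

## The cohort simulator

`simulate_cohort()` is the Monte-Carlo oracle for the closed forms above:
disease status is Bernoulli(prevalence), and each arm tests positive with
its sensitivity given disease, or 1 − specificity given no disease. Seeds
are mandatory and the caller's RNG state is restored, so cohorts are
bit-reproducible. The two arms are drawn independently given disease
status by default: only the marginal accuracies are specified by the
model, and between-arm correlation changes the variance of paired
comparisons but not the expected counts that the cost–benefit check rests
on. A comonotone option (`correlation = 1`) is provided for users who want
the variance-extreme case.

What the simulator emulates — and what it does not: it reproduces the
statistical structure the cost–benefit check assumes (fixed accuracies,
flat costs, independent cases). Real deployments add case-mix drift,
reader–AI interaction, correlated errors and cost heterogeneity, so a
passing Monte-Carlo check validates the arithmetic of the model, not the
model's fidelity to any particular clinical setting.

The test suite checks agreement between empirical and closed-form FN/FP
counts at $n = 10^5$ within three binomial standard errors — large enough
that the check is sharp (relative error under ~8% on the rarest cell),
small enough to run in well under a second. `generate_registry_fixture()`
produces seeded synthetic registries (always valid, spanning all levels
and tiers) for exercising the schedule machinery.

## Input, output and the command line

Registries read and write as CSV or JSON (`read_code_table()`,
`write_code_table()`) with row-level error reporting and lossless round
trips. `write_report()` serializes any result as JSON, CSV or a markdown
table with deterministic field order; money renders with two decimals in
textual formats, and JSON values are scrubbed of sub-nanoeuro floating
noise so repeated runs are byte-identical. `load_config()` reads a YAML
run configuration (regime definitions, rounding rule, factor cap, default
cohort size, seed, output format) with defaults for absent keys, warnings
for unknown ones, and hard errors for undefined regime references.

A thin command-line wrapper ships at
`system.file("cli", "ddssfee.R", package = "ddssfee")` with subcommands
`score`, `fee`, `invoice`, `table`, `validate`, `cba`, `crosswalk-rvu`,
`crosswalk-pmpm`, `simulate-cohort` and `simulate-registry`; reports go to
stdout or `--out`, log and audit lines to stderr.

## Known limitations

* The per-code dimension ratings behind the packaged registry are not
  published, so the rubric's ±1 stability claim can be tested as an
  operator on arbitrary vectors, but not re-derived for the five shipped
  codes.
* The calculator is an illustrative payer check: flat per-event costs, no
  time horizon, no uncertainty propagation beyond one-way sensitivity.
* Crosswalk outputs carry a currency tag but no FX conversion, and real
  RVU valuations (work/PE/MP geography adjustments, budget neutrality) are
  out of scope.
* Claims adjudication, eligibility, VAT and the full legacy fee catalogues
  are out of scope; only the handful of comparator conversions used to
  pin down the regimes are represented.
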