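# ddssfee

Point-based reimbursement modelling for AI diagnostic decision support
systems (DDSS).

AI tools that triage chest X-rays, read ECGs autonomously or pre-screen
pathology slides deliver measurable clinical value, but most fee schedules
have no code to bill them under. `ddssfee` implements a structured
valuation pipeline for such services, aimed at health-economics analysts,
payers and AI vendors who need auditable numbers rather than ad-hoc license
pricing:

1. **Rubric → tier.** A service is rated 1–5 on four dimensions (data
   complexity/diversity, disease complexity, clinical-question complexity,
   AI involvement). The unweighted mean, rounded, maps onto canonical point
   tiers: rounded mean 1–2 → 50 points, 3 → 100, 4–5 → 150. A ±1
   perturbation check reports whether the tier is robust to single-rating
   changes.
2. **Registry → fee.** Billing codes (`AI-1xx`/`AI-2xx`/`AI-3xx` for
   assistive/augmentative/autonomous services) carry point values that
   convert to money under a point-value regime via
   `Fee = Points × PointValue × Factor`, with half-up cent rounding and a
   documented multiplier policy. Presets cover the German GOÄ
   (0.0582873 EUR/point, factors 1.0–3.5) and EBM (0.123934 EUR/point, and
   a simplified 0.12 EUR/point used by the packaged five-code AI table).
3. **Payer check.** A diagnostic-accuracy cost–benefit calculator turns
   prevalence, sensitivity/specificity under standard of care vs. AI, and
   flat downstream costs per false negative/positive into avoided
   misclassification counts, net payer impact
   (`AI spend − avoided downstream cost`; negative = saving) and the
   break-even AI fee.
4. **Crosswalks.** Points translate into RVU systems via an
   anchor-calibrated slope (`RVU = κ·Points`, `Payment = RVU × CF`) and
   into capitated systems as a per-member-per-month add-on
   (`PMPM = ρ·u·Points·PointValue/12`).

A seedable Monte-Carlo cohort simulator verifies the closed-form expected
counts, and everything reads/writes CSV, JSON, YAML config and markdown
reports. See `vignettes/reimbursement-model.Rmd` for the full model
description and design rationale.

## Worked example

```r
library(ddssfee)

# 1. Rate a service and get its tier
assign_tier(score_vector(2, 3, 3, 4))
#> Tier assignment (half_up rounding)
#>   scores      : 2, 3, 3, 4
#>   mean        : 3.00 (rounds to 3)
#>   tier        : 100 points [augmentative]
#>   stable +/-1 : TRUE
#>   level (adv.): II

# 2. Bill a registry code under the simplified EBM orientation value
itemize_invoice("AI-301", ai_code_table(), "ebm-simplified")
#> AI-301 (Level III): 100 points x regime 'ebm-simplified' x factor 1.00 = 12.00 EUR

# 3. Check the payer economics of deploying that service
cost_benefit(worked_example_inputs())
#> Cost-benefit check over 1000 cases
#>   avoided false negatives : 5
#>   avoided false positives : 27
#>   avoided downstream cost : EUR 14050.00
#>   AI spend                : EUR 12000.00
#>   net payer impact        : EUR -2050.00 (negative = saving)
#>   break-even AI fee       : EUR 14.05 per case
#>   staff hours saved       : 50 h
```

Reading the numbers: with prevalence 0.10 and accuracy moving from
0.85/0.90 (standard of care) to 0.90/0.93 (with AI), AI avoids 5 false
negatives and 27 false positives per 1,000 cases, worth €14,050 in avoided
downstream costs against €12,000 of AI fees at €12/case — a net payer
saving of €2,050. The fee could rise to €14.05/case before the payer view
stops being cost-neutral, and providers save 50 staff hours per 1,000
cases.

## Command line

A thin CLI over the same functions ships with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","ddssfee.R",package="ddssfee"))')" \
  fee --code AI-301 --regime ebm-simplified --factor 1.0
```

Subcommands: `score`, `fee`, `invoice`, `table`, `validate`, `cba`,
`crosswalk-rvu`, `crosswalk-pmpm`, `simulate-cohort`, `simulate-registry`.

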