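#' Diagnostic accuracy profile
#'
#' Sensitivity and specificity of one testing scenario (standard of care or
#' AI-supported).
#'
#' @param sensitivity Probability a diseased case tests positive, in `[0, 1]`.
#' @param specificity Probability a non-diseased case tests negative, in
#'   `[0, 1]`.
#' @return An `accuracy_profile` list.
#' @export
accuracy_profile <- function(sensitivity, specificity) {
  assert_rate(sensitivity, "sensitivity")
  assert_rate(specificity, "specificity")
  structure(list(sensitivity = sensitivity, specificity = specificity),
            class = "accuracy_profile")
}

#' Inputs for the illustrative payer-perspective cost-benefit check
#'
#' Bundles the minimal, auditable input set the check runs on: condition
#' prevalence, accuracy under standard of care (SoC) and with AI support,
#' flat average downstream costs per false negative and per false positive,
#' the per-case AI fee, optional staff minutes saved per case, and the
#' cohort size.
#'
#' @param prevalence Condition prevalence in `[0, 1]`.
#' @param soc,ai [accuracy_profile()]s for the two scenarios.
#' @param cost_fn Average downstream cost of one false negative (EUR).
#' @param cost_fp Average downstream cost of one false positive (EUR).
#' @param ai_fee AI fee per case (EUR), typically points x point value at
#'   factor 1.0.
#' @param minutes_saved Staff minutes saved per case (optional provider-side
#'   step; default 0).
#' @param n Cohort size (default 1000, the reporting unit).
#' @return A `cost_benefit_inputs` list.
#' @seealso [cost_benefit()], [worked_example_inputs()] for the packaged example set
#' @export
cost_benefit_inputs <- function(prevalence, soc, ai, cost_fn, cost_fp,
                                ai_fee, minutes_saved = 0, n = 1000) {
  assert_rate(prevalence, "prevalence")
  stopifnot(inherits(soc, "accuracy_profile"),
            inherits(ai, "accuracy_profile"))
  assert_nonneg(cost_fn, "cost_fn")
  assert_nonneg(cost_fp, "cost_fp")
  assert_nonneg(ai_fee, "ai_fee")
  assert_nonneg(minutes_saved, "minutes_saved")
  n <- assert_count(n, "n", min = 1)
  structure(
    list(prevalence = prevalence, soc = soc, ai = ai,
         cost_fn = cost_fn, cost_fp = cost_fp, ai_fee = ai_fee,
         minutes_saved = minutes_saved, n = n),
    class = "cost_benefit_inputs"
  )
}

#' Packaged example input set
#'
#' Loads the worked-example parameter set shipped with the package:
#' prevalence 0.10, SoC sensitivity/specificity 0.85/0.90, with-AI
#' 0.90/0.93, EUR 2000 per false negative, EUR 150 per false positive,
#' EUR 12 AI fee per case, 3 staff minutes saved per case, cohort of 1000.
#'
#' @return A `cost_benefit_inputs` object.
#' @export
worked_example_inputs <- function() {
  path <- system.file("extdata", "costbenefit_example.json",
                      package = "ddssfee", mustWork = TRUE)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cost_benefit_inputs(
    prevalence = p$prevalence,
    soc = accuracy_profile(p$soc$sensitivity, p$soc$specificity),
    ai = accuracy_profile(p$ai$sensitivity, p$ai$specificity),
    cost_fn = p$cost_fn, cost_fp = p$cost_fp, ai_fee = p$ai_fee,
    minutes_saved = p$minutes_saved, n = p$n
  )
}

#' Expected confusion-matrix counts
#'
#' Closed-form expected counts for a cohort of `n` cases screened by a test
#' with the given accuracy profile:
#' `fn = prevalence * n * (1 - sensitivity)`,
#' `fp = (1 - prevalence) * n * (1 - specificity)`, with `tp` and `tn` the
#' complements. Counts are kept as real numbers; rounding to whole cases
#' happens only in display.
#'
#' @param prevalence Condition prevalence in `[0, 1]`.
#' @param profile An [accuracy_profile()].
#' @param n Cohort size.
#' @return An `expected_counts` list with fields `tp`, `fn`, `fp`, `tn`.
#' @examples
#' expected_counts(0.10, accuracy_profile(0.85, 0.90), 1000)  # fn 15, fp 90
#' @export
expected_counts <- function(prevalence, profile, n) {
  assert_rate(prevalence, "prevalence")
  stopifnot(inherits(profile, "accuracy_profile"))
  n <- assert_count(n, "n", min = 1)
  diseased <- prevalence * n
  healthy <- (1 - prevalence) * n
  structure(
    list(tp = diseased * profile$sensitivity,
         fn = diseased * (1 - profile$sensitivity),
         fp = healthy * (1 - profile$specificity),
         tn = healthy * profile$specificity),
    class = "expected_counts"
  )
}

#' Run the six-step cost-benefit check
#'
#' Computes, for the given inputs: expected false negatives and false
#' positives under standard of care and with AI; the counts avoided by AI;
#' the avoided downstream cost (`avoided_fn * cost_fn + avoided_fp *
#' cost_fp`); the AI spend (`ai_fee * n`); the net payer impact, defined as
#' AI spend minus avoided downstream cost so that a negative value is a
#' payer saving; the break-even AI fee at which the payer view is exactly
#' cost-neutral; and the provider-side staff hours saved. Results are also
#' normalized per 1000 cases, the customary reporting unit.
#'
#' @param inputs A [cost_benefit_inputs()] object.
#' @return A `cost_benefit_result` list with fields `avoided_fn`,
#'   `avoided_fp`, `avoided_downstream_cost`, `ai_spend`,
#'   `net_payer_impact`, `break_even_fee`, `staff_hours_saved`, `n`,
#'   `counts` (the two `expected_counts`), and `per_1000` (the money and
#'   count fields rescaled to 1000 cases).
#' @examples
#' cost_benefit(worked_example_inputs())
#' @export
cost_benefit <- function(inputs) {
  stopifnot(inherits(inputs, "cost_benefit_inputs"))
  soc <- expected_counts(inputs$prevalence, inputs$soc, inputs$n)
  ai <- expected_counts(inputs$prevalence, inputs$ai, inputs$n)
  avoided_fn <- soc$fn - ai$fn
  avoided_fp <- soc$fp - ai$fp
  avoided_cost <- avoided_fn * inputs$cost_fn + avoided_fp * inputs$cost_fp
  ai_spend <- inputs$ai_fee * inputs$n
  net <- ai_spend - avoided_cost
  scale <- 1000 / inputs$n
  structure(
    list(
      avoided_fn = avoided_fn,
      avoided_fp = avoided_fp,
      avoided_downstream_cost = avoided_cost,
      ai_spend = ai_spend,
      net_payer_impact = net,
      break_even_fee = break_even_fee(inputs),
      staff_hours_saved = staff_time_savings(inputs$minutes_saved, inputs$n),
      n = inputs$n,
      counts = list(soc = soc, ai = ai),
      per_1000 = list(
        avoided_fn = avoided_fn * scale,
        avoided_fp = avoided_fp * scale,
        avoided_downstream_cost = avoided_cost * scale,
        ai_spend = ai_spend * scale,
        net_payer_impact = net * scale,
        staff_hours_saved =
          staff_time_savings(inputs$minutes_saved, inputs$n) * scale
      )
    ),
    class = "cost_benefit_result"
  )
}

#' @export
print.cost_benefit_result <- function(x, ...) {
  cat(sprintf("Cost-benefit check over %d cases\n", x$n))
  cat(sprintf("  avoided false negatives : %.6g\n", x$avoided_fn))
  cat(sprintf("  avoided false positives : %.6g\n", x$avoided_fp))
  cat(sprintf("  avoided downstream cost : EUR %.2f\n",
              x$avoided_downstream_cost))
  cat(sprintf("  AI spend                : EUR %.2f\n", x$ai_spend))
  cat(sprintf("  net payer impact        : EUR %.2f (negative = saving)\n",
              x$net_payer_impact))
  cat(sprintf("  break-even AI fee       : EUR %.2f per case\n",
              x$break_even_fee))
  cat(sprintf("  staff hours saved       : %.6g h\n", x$staff_hours_saved))
  invisible(x)
}

#' Break-even AI fee
#'
#' The per-case AI fee at which avoided downstream costs exactly equal AI
#' spend: `avoided_downstream_cost / n`. At or below it, the payer view is
#' cost-neutral or saving.
#'
#' @param inputs A [cost_benefit_inputs()] object.
#' @return Break-even fee in EUR per case.
#' @examples
#' break_even_fee(worked_example_inputs())  # 14.05
#' @export
break_even_fee <- function(inputs) {
  stopifnot(inherits(inputs, "cost_benefit_inputs"))
  soc <- expected_counts(inputs$prevalence, inputs$soc, inputs$n)
  ai <- expected_counts(inputs$prevalence, inputs$ai, inputs$n)
  avoided <- (soc$fn - ai$fn) * inputs$cost_fn +
    (soc$fp - ai$fp) * inputs$cost_fp
  avoided / inputs$n
}

#' Staff time saved
#'
#' Converts per-case staff minutes saved into total hours over the cohort.
#'
#' @param minutes_saved Minutes saved per case (>= 0).
#' @param n Cohort size.
#' @return Hours saved.
#' @examples
#' staff_time_savings(3, 1000)  # 50 hours
#' @export
staff_time_savings <- function(minutes_saved, n) {
  assert_nonneg(minutes_saved, "minutes_saved")
  n <- assert_count(n, "n", min = 1)
  minutes_saved * n / 60
}

#' One-way sensitivity analysis
#'
#' Re-runs the cost-benefit check varying a single input over a grid while
#' holding all other inputs at baseline.
#'
#' @param inputs Baseline [cost_benefit_inputs()].
#' @param parameter One of `"prevalence"`, `"soc_sensitivity"`,
#'   `"soc_specificity"`, `"ai_sensitivity"`, `"ai_specificity"`,
#'   `"cost_fn"`, `"cost_fp"`, `"ai_fee"`, `"minutes_saved"`, `"n"`.
#' @param grid Non-empty numeric vector of values for that parameter.
#' @return Data frame with columns `value`, `net_payer_impact`,
#'   `break_even_fee`.
#' @examples
#' one_way_sensitivity(worked_example_inputs(), "ai_fee", c(12, 14.05, 16))
#' @export
one_way_sensitivity <- function(inputs, parameter, grid) {
  stopifnot(inherits(inputs, "cost_benefit_inputs"))
  allowed <- c("prevalence", "soc_sensitivity", "soc_specificity",
               "ai_sensitivity", "ai_specificity", "cost_fn", "cost_fp",
               "ai_fee", "minutes_saved", "n")
  if (!is.character(parameter) || length(parameter) != 1 ||
      !parameter %in% allowed) {
    stop("unknown parameter; must be one of: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  }
  if (length(grid) == 0) stop("grid must be non-empty", call. = FALSE)
  rows <- lapply(grid, function(val) {
    mod <- inputs
    if (parameter == "soc_sensitivity") {
      mod$soc <- accuracy_profile(val, mod$soc$specificity)
    } else if (parameter == "soc_specificity") {
      mod$soc <- accuracy_profile(mod$soc$sensitivity, val)
    } else if (parameter == "ai_sensitivity") {
      mod$ai <- accuracy_profile(val, mod$ai$specificity)
    } else if (parameter == "ai_specificity") {
      mod$ai <- accuracy_profile(mod$ai$sensitivity, val)
    } else {
      mod[[parameter]] <- val
    }
    mod <- cost_benefit_inputs(mod$prevalence, mod$soc, mod$ai, mod$cost_fn,
                               mod$cost_fp, mod$ai_fee, mod$minutes_saved,
                               mod$n)
    res <- cost_benefit(mod)
    data.frame(value = val, net_payer_impact = res$net_payer_impact,
               break_even_fee = res$break_even_fee)
  })
  do.call(rbind, rows)
}
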