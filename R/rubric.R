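#' Score vector for an AI diagnostic service
#'
#' An AI diagnostic decision support service is rated on four qualitative
#' dimensions, each on an integer 1 (low) to 5 (high) scale:
#' data complexity/diversity, disease complexity, complexity of the clinical
#' question, and degree of AI involvement. The unweighted mean of the four
#' ratings drives the canonical point tier (see [assign_tier()]).
#'
#' @param data_complexity Integer 1-5. Complexity and diversity of the input
#'   data (1 = single, low-variance data source; 5 = multi-modal,
#'   high-resolution data across diverse sites and populations).
#' @param disease_complexity Integer 1-5. Intrinsic diagnostic difficulty of
#'   the condition (1 = common, well-delimited; 5 = rare or multifactorial
#'   with a broad differential).
#' @param question_complexity Integer 1-5. Scope of the clinical question
#'   (1 = narrow binary detection; 5 = open-ended reasoning such as
#'   differential diagnosis or next-step guidance).
#' @param ai_involvement Integer 1-5. Share of the diagnostic work carried by
#'   the AI (1 = assistive pre-interpretation/triage; 5 = near-autonomous
#'   diagnostic report with minimal real-time human input).
#' @return An object of class `score_vector`: a named integer vector of the
#'   four ratings.
#' @seealso [assign_tier()], [perturbation_stability()], [suggest_level()],
#'   [dimension_anchors()]
#' @examples
#' score_vector(3, 5, 2, 4)
#' @export
score_vector <- function(data_complexity, disease_complexity,
                         question_complexity, ai_involvement) {
  v <- c(data_complexity = data_complexity,
         disease_complexity = disease_complexity,
         question_complexity = question_complexity,
         ai_involvement = ai_involvement)
  validate_scores(v)
}

#' Validate a score vector
#'
#' Checks that all four dimension ratings are integers in 1-5 and returns the
#' vector unchanged. The error message names the first offending dimension.
#'
#' @param vector A `score_vector`, or a (named or positional) numeric vector
#'   of the four ratings in the order data, disease, question, involvement.
#' @return The validated `score_vector`, unchanged.
#' @examples
#' validate_scores(c(1, 1, 1, 1))
#' @export
validate_scores <- function(vector) {
  dims <- c("data_complexity", "disease_complexity",
            "question_complexity", "ai_involvement")
  if (length(vector) != 4) {
    stop("a score vector has exactly four dimension ratings", call. = FALSE)
  }
  v <- unclass(vector)
  if (is.null(names(v)) || !setequal(names(v), dims)) {
    names(v) <- dims          # unnamed/foreign names: positional order
  }
  v <- v[dims]
  for (d in dims) {
    x <- v[[d]]
    if (!is.numeric(x) || is.na(x) || x != trunc(x)) {
      stop(sprintf("%s must be an integer score, got %s", d, deparse(x)),
           call. = FALSE)
    }
    if (x < 1 || x > 5) {
      stop(sprintf("%s out of range: score %s is not in [1, 5]", d, x),
           call. = FALSE)
    }
  }
  structure(vapply(v, as.integer, integer(1)), class = "score_vector")
}

# Internal: tier for a rounded mean. 1-2 -> 50, 3 -> 100, 4-5 -> 150.
tier_for_rounded_mean <- function(rounded) {
  stopifnot(rounded %in% 1:5)
  if (rounded <= 2) 50L else if (rounded == 3) 100L else 150L
}

tier_label_for_points <- function(points) {
  switch(as.character(points),
         "50" = "assistive",
         "100" = "augmentative",
         "150" = "high_complexity_or_autonomous",
         stop("no canonical tier label for ", points, " points"))
}

#' Assign the canonical point tier
#'
#' Takes the unweighted arithmetic mean of the four dimension ratings, rounds
#' it, and maps the rounded mean onto the canonical tier set: rounded mean
#' 1-2 gives 50 points (assistive), 3 gives 100 points (augmentative), and
#' 4-5 gives 150 points (high-complexity augmentative or autonomous).
#'
#' The default rounding rule is half away from zero (2.5 -> 3); half-to-even
#' can be selected for sensitivity analysis. The result also records whether
#' the tier is stable under unit perturbation of any single dimension
#' ([perturbation_stability()]) and the advisory AI-involvement level
#' ([suggest_level()]).
#'
#' @param vector A `score_vector` (or coercible four-element vector).
#' @param rounding `"half_up"` (default; half away from zero) or
#'   `"half_even"`.
#' @return A `tier_assignment` list: `mean_score`, `rounded_mean`,
#'   `tier_points` (50/100/150), `tier_label`,
#'   `stable_under_unit_perturbation`, `suggested_level`, `rounding`.
#' @examples
#' assign_tier(score_vector(3, 3, 3, 3))   # 100 points
#' assign_tier(c(2, 2, 3, 3))              # mean 2.5 rounds up -> 100 points
#' @export
assign_tier <- function(vector, rounding = c("half_up", "half_even")) {
  rounding <- match.arg(rounding)
  v <- validate_scores(vector)
  m <- mean(as.numeric(v))
  r <- as.integer(round_mean(m, rounding))
  points <- tier_for_rounded_mean(r)
  structure(
    list(
      scores = v,
      mean_score = m,
      rounded_mean = r,
      tier_points = points,
      tier_label = tier_label_for_points(points),
      stable_under_unit_perturbation =
        perturbation_stability(v, rounding = rounding),
      suggested_level = suggest_level(v)$level,
      rounding = rounding
    ),
    class = "tier_assignment"
  )
}

#' @export
print.tier_assignment <- function(x, ...) {
  cat("Tier assignment (", x$rounding, " rounding)\n", sep = "")
  cat("  scores      :", paste(x$scores, collapse = ", "), "\n")
  cat(sprintf("  mean        : %.2f (rounds to %d)\n",
              x$mean_score, x$rounded_mean))
  cat(sprintf("  tier        : %d points [%s]\n", x$tier_points, x$tier_label))
  cat("  stable +/-1 :", x$stable_under_unit_perturbation, "\n")
  cat("  level (adv.):", x$suggested_level, "\n")
  invisible(x)
}

#' Tier stability under unit perturbation
#'
#' Checks whether varying any single dimension by +1 or -1 (holding the other
#' three constant) leaves the assigned tier unchanged. Perturbed scores that
#' would leave the 1-5 range are clipped back to it; clipped perturbations
#' are marked in the trace.
#'
#' @inheritParams assign_tier
#' @return `TRUE` if all eight perturbations keep the tier, else `FALSE`.
#'   The attribute `"trace"` holds a data frame with one row per perturbation
#'   (dimension, delta, clipped flag, perturbed tier).
#' @examples
#' perturbation_stability(c(3, 3, 3, 3))  # TRUE
#' perturbation_stability(c(2, 2, 2, 3))  # FALSE: a 2 raised to 3 tips tier
#' @export
perturbation_stability <- function(vector,
                                   rounding = c("half_up", "half_even")) {
  rounding <- match.arg(rounding)
  v <- validate_scores(vector)
  base_tier <- tier_for_rounded_mean(
    as.integer(round_mean(mean(as.numeric(v)), rounding)))
  dims <- names(v)
  trace <- do.call(rbind, lapply(dims, function(d) {
    do.call(rbind, lapply(c(-1L, 1L), function(delta) {
      w <- as.numeric(v)
      names(w) <- dims
      raw <- w[[d]] + delta
      w[[d]] <- min(5, max(1, raw))
      tier <- tier_for_rounded_mean(
        as.integer(round_mean(mean(w), rounding)))
      data.frame(dimension = d, delta = delta,
                 clipped = raw < 1 || raw > 5,
                 perturbed_tier = tier,
                 stringsAsFactors = FALSE)
    }))
  }))
  stable <- all(trace$perturbed_tier == base_tier)
  structure(stable, trace = trace)
}

#' Suggest the AI contribution level
#'
#' Advisory mapping from the AI-involvement rating alone onto the three
#' contribution levels used by the billing-code prefix: involvement 1-2
#' suggests Level I (assistive pre-interpretation), 3-4 Level II
#' (augmentative review support), and 5 Level III (autonomous reporting).
#' The suggestion never overrides a registry entry's recorded level.
#'
#' @inheritParams assign_tier
#' @return A `level_suggestion` list with field `level` ("I", "II" or "III").
#' @examples
#' suggest_level(score_vector(1, 1, 1, 5))$level  # "III"
#' @export
suggest_level <- function(vector) {
  v <- validate_scores(vector)
  inv <- v[["ai_involvement"]]
  level <- if (inv <= 2) "I" else if (inv <= 4) "II" else "III"
  structure(list(level = level), class = "level_suggestion")
}

#' Rubric dimension anchors
#'
#' Human-readable anchor descriptions for the 1 and 5 endpoints of each
#' rubric dimension. These are documentation, not computable constraints:
#' raters consult them when assigning scores.
#'
#' @return Named character vector, one anchor string per dimension.
#' @export
dimension_anchors <- function() {
  c(
    data_complexity =
      "1 = single, low-variance data source; 5 = multi-modal/high-resolution data across diverse sites and populations",
    disease_complexity =
      "1 = common, well-delimited condition; 5 = rare/multifactorial condition with a broad differential",
    question_complexity =
      "1 = narrow/binary detection task; 5 = open-ended reasoning (differential diagnosis, next-step guidance)",
    ai_involvement =
      "1 = assistive pre-interpretation or triage; 5 = near-autonomous diagnostic report with minimal real-time human input"
  )
}
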