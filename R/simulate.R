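#' Simulate a screening cohort
#'
#' Draws per-case disease status and test outcomes under both scenarios:
#' disease ~ Bernoulli(prevalence); given disease, each arm tests positive
#' with its sensitivity; given no disease, with 1 - specificity. The two
#' arms are drawn independently given disease status by default
#' (only the marginal accuracies are specified by the model; correlation
#' between arms changes the variance of paired comparisons but not the
#' expected counts the closed forms predict). Setting `correlation` to 1
#' makes the arms share the same latent uniform draw, the comonotone
#' extreme.
#'
#' A seed is mandatory so that cohorts are reproducible: the same seed and
#' parameters give a bit-identical cohort. The caller's RNG state is left
#' untouched.
#'
#' @param n Cohort size (>= 1).
#' @param prevalence Condition prevalence in `[0, 1]`.
#' @param soc,ai [accuracy_profile()]s for the two arms.
#' @param seed Integer seed.
#' @param correlation 0 (default, independent arms given status) or 1
#'   (comonotone arms).
#' @return Data frame of class `cohort` with logical columns `diseased`,
#'   `soc_positive`, `ai_positive`.
#' @examples
#' head(simulate_cohort(100, 0.1, accuracy_profile(0.85, 0.90),
#'                      accuracy_profile(0.90, 0.93), seed = 1))
#' @export
simulate_cohort <- function(n, prevalence, soc, ai, seed, correlation = 0) {
  n <- assert_count(n, "n", min = 1)
  assert_rate(prevalence, "prevalence")
  stopifnot(inherits(soc, "accuracy_profile"),
            inherits(ai, "accuracy_profile"))
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required for reproducible cohorts", call. = FALSE)
  }
  if (!correlation %in% c(0, 1)) {
    stop("correlation must be 0 (independent) or 1 (comonotone)",
         call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    diseased <- stats::runif(n) < prevalence
    p_soc <- ifelse(diseased, soc$sensitivity, 1 - soc$specificity)
    p_ai <- ifelse(diseased, ai$sensitivity, 1 - ai$specificity)
    u1 <- stats::runif(n)
    u2 <- if (correlation == 1) u1 else stats::runif(n)
    cohort <- data.frame(diseased = diseased,
                         soc_positive = u1 < p_soc,
                         ai_positive = u2 < p_ai)
    class(cohort) <- c("cohort", "data.frame")
    cohort
  })
}

#' Tabulate empirical confusion-matrix counts
#'
#' Counts TP/FN/FP/TN for both arms of a simulated cohort. Per arm the four
#' counts partition the cohort: `tp + fn + fp + tn = n`.
#'
#' @param cohort A data frame with logical columns `diseased`,
#'   `soc_positive`, `ai_positive` (as from [simulate_cohort()]).
#' @return List with elements `soc` and `ai`, each an `expected_counts`
#'   object holding the empirical counts.
#' @export
empirical_counts <- function(cohort) {
  required <- c("diseased", "soc_positive", "ai_positive")
  if (!all(required %in% names(cohort))) {
    stop("cohort must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  tab <- function(positive) {
    structure(
      list(tp = sum(cohort$diseased & positive),
           fn = sum(cohort$diseased & !positive),
           fp = sum(!cohort$diseased & positive),
           tn = sum(!cohort$diseased & !positive)),
      class = "expected_counts"
    )
  }
  list(soc = tab(cohort$soc_positive), ai = tab(cohort$ai_positive))
}

#' Generate a synthetic billing-code registry
#'
#' Constructs `k` syntactically valid billing codes for testing the
#' schedule machinery: unique ids cycling through the three contribution
#' levels, specialties drawn from a small pool, and points on the canonical
#' tiers. The output always passes [validate_registry()] with zero
#' violations, and the same seed reproduces the same registry.
#'
#' @param k Number of codes (>= 1).
#' @param seed Integer seed.
#' @return A `billing_registry` of `k` codes.
#' @examples
#' generate_registry_fixture(9, seed = 42)
#' @export
generate_registry_fixture <- function(k, seed) {
  k <- assert_count(k, "k", min = 1)
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required for reproducible registries", call. = FALSE)
  }
  specialties <- c("Radiology", "Cardiology", "Laboratory diagnostics",
                   "Pathology", "Ultrasound imaging", "Dermatology")
  tiers <- c(50L, 100L, 150L)
  withr::with_seed(as.integer(seed), {
    level_digit <- rep_len(1:3, k)                 # spans all three levels
    idx <- stats::ave(seq_len(k), level_digit, FUN = seq_along)
    if (any(idx > 99)) {
      stop("at most 99 synthetic codes per level", call. = FALSE)
    }
    code_id <- sprintf("AI-%d%02d", level_digit, idx)
    level <- c("I", "II", "III")[level_digit]
    specialty <- sample(specialties, k, replace = TRUE)
    points <- if (k >= 3) {
      # guarantee every canonical tier appears at least once
      c(tiers, sample(tiers, k - 3, replace = TRUE))
    } else {
      sample(tiers, k, replace = TRUE)
    }
    billing_registry(
      code_id = code_id, level = level, specialty = specialty,
      description = sprintf("Synthetic %s AI service (%s, Level %s)",
                            tolower(specialty), code_id, level),
      points = points
    )
  })
}
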