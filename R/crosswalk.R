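#' Crosswalk anchor
#'
#' One anchor pairing a point valuation with an established fee-for-service
#' valuation in an RVU-based system. Supply either the RVU directly or a
#' payment together with the conversion factor, in which case the implied
#' RVU is `payment / conversion_factor`.
#'
#' @param label Free-text description of the anchor service.
#' @param points Point valuation of the service (> 0).
#' @param rvu Relative value units of the comparator (exclusive with
#'   `payment`/`conversion_factor`).
#' @param payment Payment amount of the comparator.
#' @param conversion_factor Currency per RVU used with `payment`.
#' @param currency Currency tag for payment-based anchors.
#' @return A `crosswalk_anchor` list with the implied `rvu` filled in.
#' @export
crosswalk_anchor <- function(label, points, rvu = NULL, payment = NULL,
                             conversion_factor = NULL, currency = "USD") {
  points <- assert_count(points, "points", min = 1)
  has_rvu <- !is.null(rvu)
  has_pay <- !is.null(payment) || !is.null(conversion_factor)
  if (has_rvu && has_pay) {
    stop("supply either rvu or (payment, conversion_factor), not both",
         call. = FALSE)
  }
  if (!has_rvu) {
    if (is.null(payment) || is.null(conversion_factor)) {
      stop("payment-based anchors need both payment and conversion_factor",
           call. = FALSE)
    }
    assert_nonneg(payment, "payment")
    assert_nonneg(conversion_factor, "conversion_factor")
    if (conversion_factor <= 0) {
      stop("conversion_factor must be > 0", call. = FALSE)
    }
    rvu <- payment / conversion_factor
  }
  if (!is.numeric(rvu) || length(rvu) != 1 || is.na(rvu) || rvu <= 0) {
    stop("implied RVU must be a single positive number", call. = FALSE)
  }
  structure(
    list(label = label, points = points, rvu = rvu,
         payment = payment, conversion_factor = conversion_factor,
         currency = currency),
    class = "crosswalk_anchor"
  )
}

#' Calibrate the RVU-per-point slope
#'
#' Fits the proportional mapping `RVU = kappa * points` to one or more
#' anchors. A single anchor gives `kappa = rvu / points` exactly. Multiple
#' anchors are fitted by least squares through the origin (the intercept is
#' forced to zero because a 0-point service must map to 0 RVU), optionally
#' weighted by anchor volume; per-anchor residuals (implied minus fitted
#' RVU) are reported.
#'
#' @param anchors A list of [crosswalk_anchor()]s (a single anchor may be
#'   passed bare).
#' @param weights Optional positive weights, one per anchor (e.g. service
#'   volumes); default equal weights.
#' @return A `kappa_calibration` list: `kappa`, `residuals` (named by anchor
#'   label), `anchors`.
#' @examples
#' a <- crosswalk_anchor("autonomous screening", 100, rvu = 1.5)
#' calibrate_kappa(a)$kappa  # 0.015
#' @export
calibrate_kappa <- function(anchors, weights = NULL) {
  if (inherits(anchors, "crosswalk_anchor")) anchors <- list(anchors)
  if (!is.list(anchors) || length(anchors) == 0) {
    stop("at least one anchor is required", call. = FALSE)
  }
  ok <- vapply(anchors, inherits, logical(1), what = "crosswalk_anchor")
  if (!all(ok)) stop("anchors must be crosswalk_anchor objects", call. = FALSE)
  p <- vapply(anchors, `[[`, numeric(1), "points")
  r <- vapply(anchors, `[[`, numeric(1), "rvu")
  if (is.null(weights)) weights <- rep(1, length(anchors))
  if (length(weights) != length(anchors) || any(weights <= 0)) {
    stop("weights must be positive, one per anchor", call. = FALSE)
  }
  # weighted least squares through the origin, closed form
  kappa <- sum(weights * p * r) / sum(weights * p^2)
  residuals <- r - kappa * p
  names(residuals) <- vapply(anchors, `[[`, character(1), "label")
  structure(list(kappa = kappa, residuals = residuals, anchors = anchors),
            class = "kappa_calibration")
}

#' @export
print.kappa_calibration <- function(x, ...) {
  cat(sprintf("RVU-per-point calibration: kappa = %.6g (%d anchor%s)\n",
              x$kappa, length(x$anchors),
              if (length(x$anchors) == 1) "" else "s"))
  if (any(abs(x$residuals) > 1e-12)) {
    cat("  residuals (implied - fitted RVU):\n")
    for (nm in names(x$residuals)) {
      cat(sprintf("    %s: %+.4g\n", nm, x$residuals[[nm]]))
    }
  }
  invisible(x)
}

#' Map points to an RVU-system payment
#'
#' Standard fee-for-service mechanics after calibration:
#' `payment = kappa * points * conversion_factor`. Payment ratios between
#' services equal their point ratios for any kappa and conversion factor,
#' preserving the relative valuations of the point schedule.
#'
#' @param points Point valuation (> 0 integer; 0 is admitted as the
#'   degenerate no-service limit).
#' @param kappa RVU per point (> 0), from [calibrate_kappa()].
#' @param conversion_factor Currency per RVU (> 0).
#' @return Payment amount (unrounded; round at presentation).
#' @examples
#' map_payment(150, kappa = 0.015, conversion_factor = 30)  # 67.5
#' @export
map_payment <- function(points, kappa, conversion_factor) {
  if (!is.numeric(points) || length(points) != 1 || is.na(points) ||
      points < 0 || points != trunc(points)) {
    stop("points must be a single non-negative integer", call. = FALSE)
  }
  assert_nonneg(kappa, "kappa")
  assert_nonneg(conversion_factor, "conversion_factor")
  if (kappa <= 0 || conversion_factor <= 0) {
    stop("kappa and conversion_factor must be > 0", call. = FALSE)
  }
  kappa * points * conversion_factor
}

#' Split an RVU into work, practice-expense and malpractice components
#'
#' RVU systems decompose each valuation into work, practice-expense and
#' malpractice components. How an AI service's RVU should be allocated
#' depends on the level of AI involvement and is a policy choice, so no
#' default split is provided: the caller supplies fractions that must sum
#' to 1.
#'
#' @param rvu Total RVU (> 0).
#' @param fractions Named numeric vector with elements `work`,
#'   `practice_expense`, `malpractice`, summing to 1.
#' @return Named numeric vector of component RVUs.
#' @export
split_rvu <- function(rvu, fractions) {
  assert_nonneg(rvu, "rvu")
  required <- c("work", "practice_expense", "malpractice")
  if (!is.numeric(fractions) || !setequal(names(fractions), required)) {
    stop("fractions must be named work, practice_expense, malpractice",
         call. = FALSE)
  }
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be non-negative and sum to 1", call. = FALSE)
  }
  rvu * fractions[required]
}

#' Per-member-per-month capitation add-on
#'
#' Embeds a point-valued AI service into a capitated system as a small
#' monthly add-on: `PMPM = rho * u * points * euro_per_point / 12`, where
#' `rho` is the prevalence of the care pathway in the covered population and
#' `u` the expected annual uses per eligible member.
#'
#' Quality-linked capitation bonuses (e.g. keyed to avoided misclassification
#' thresholds) are a recognised extension of this mechanism but carry no
#' agreed formula, so they are deliberately not implemented here.
#'
#' @param rho Pathway prevalence in `[0, 1]`.
#' @param u Expected uses per eligible member per year (>= 0).
#' @param points Point valuation of the service (> 0).
#' @param euro_per_point Currency per point.
#' @return PMPM amount (currency per member per month, unrounded).
#' @examples
#' pmpm(rho = 0.10, u = 1, points = 100, euro_per_point = 0.12)  # 0.10
#' @export
pmpm <- function(rho, u, points, euro_per_point) {
  assert_rate(rho, "rho")
  assert_nonneg(u, "u")
  points <- assert_count(points, "points", min = 1)
  assert_nonneg(euro_per_point, "euro_per_point")
  rho * u * points * euro_per_point / 12
}
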