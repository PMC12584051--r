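#' Point-value regime
#'
#' A named conversion from schedule points to euros, together with the factor
#' (multiplier) policy that governs case-complexity surcharges. Fees follow
#'
#'   fee = points x euro_per_point x factor
#'
#' rounded half-up to cents at the end (intermediate products are never
#' rounded).
#'
#' @param name Regime identifier.
#' @param euro_per_point Euros per schedule point (> 0).
#' @param factor_min,factor_max Allowed multiplier range.
#' @param typical_factor Customary multiplier within that range.
#' @param currency Currency tag carried through to fee lines.
#' @return A `point_value_regime` list.
#' @seealso [fee_regimes()] for the built-in presets, [compute_fee()]
#' @export
point_value_regime <- function(name, euro_per_point,
                               factor_min = 1, factor_max = 1,
                               typical_factor = 1, currency = "EUR") {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  assert_nonneg(euro_per_point, "euro_per_point")
  if (euro_per_point <= 0) stop("euro_per_point must be > 0", call. = FALSE)
  if (!(factor_min <= typical_factor && typical_factor <= factor_max)) {
    stop("factor policy requires factor_min <= typical_factor <= factor_max",
         call. = FALSE)
  }
  structure(
    list(name = name, euro_per_point = euro_per_point,
         factor_min = factor_min, factor_max = factor_max,
         typical_factor = typical_factor, currency = currency),
    class = "point_value_regime"
  )
}

#' @export
print.point_value_regime <- function(x, ...) {
  cat(sprintf("Point-value regime '%s': %.7g %s/point, factor %.2g-%.2g (typical %.2g)\n",
              x$name, x$euro_per_point, x$currency,
              x$factor_min, x$factor_max, x$typical_factor))
  invisible(x)
}

#' Built-in point-value regimes
#'
#' Three presets cover the German fee-schedule conversions plus the
#' simplified orientation value used for the illustrative AI code table:
#'
#' * `goa` — the private-medicine schedule at the statutory point value
#'   0.0582873 EUR/point with case multipliers 1.0-3.5 (typical 2.3). The
#'   exact statutory value is used rather than the commonly quoted
#'   "about 0.058": only the exact value reproduces the published base fees
#'   (280 points -> 16.32, 2000 -> 116.57, 4400 -> 256.46).
#' * `ebm-2025` — the statutory-insurance orientation value 0.123934
#'   EUR/point (82 points -> 10.16). EBM fees carry no case multiplier, but
#'   AI services may justify up to 2.0x with documentation, so the policy
#'   range is 1.0-2.0 with typical 1.0.
#' * `ebm-simplified` — a rounded 0.12 EUR/point orientation value used for
#'   the reference AI code table (100 points -> 12.00); same factor policy
#'   as `ebm-2025`.
#'
#' @param name Optional single regime name; if given, that preset is
#'   returned, otherwise the full named list.
#' @return A `point_value_regime` or a named list of them.
#' @examples
#' fee_regimes("goa")
#' @export
fee_regimes <- function(name = NULL) {
  presets <- list(
    "goa" = point_value_regime("goa", 0.0582873,
                               factor_min = 1, factor_max = 3.5,
                               typical_factor = 2.3),
    "ebm-2025" = point_value_regime("ebm-2025", 0.123934,
                                    factor_min = 1, factor_max = 2,
                                    typical_factor = 1),
    "ebm-simplified" = point_value_regime("ebm-simplified", 0.12,
                                          factor_min = 1, factor_max = 2,
                                          typical_factor = 1)
  )
  if (is.null(name)) return(presets)
  if (inherits(name, "point_value_regime")) return(name)
  if (!name %in% names(presets)) {
    stop(sprintf("unknown regime '%s'; built-ins are %s", name,
                 paste(names(presets), collapse = ", ")), call. = FALSE)
  }
  presets[[name]]
}

# Internal: accept either a regime object or a preset name.
resolve_regime <- function(regime) {
  if (inherits(regime, "point_value_regime")) regime else fee_regimes(regime)
}

#' Compute a reimbursement fee
#'
#' Applies the fee formula `points x euro_per_point x factor` and rounds the
#' result half-up to whole cents. The factor must lie within the regime's
#' policy range.
#'
#' @param points Positive integer point valuation of the service.
#' @param regime A `point_value_regime` or the name of a built-in preset.
#' @param factor Case-complexity multiplier (default 1.0, the base fee).
#' @return Fee in euros, rounded to 2 decimals.
#' @examples
#' compute_fee(100, "ebm-simplified")        # 12.00
#' compute_fee(2000, "goa")                  # 116.57
#' compute_fee(280, "goa", factor = 2.3)     # 37.54
#' @export
compute_fee <- function(points, regime, factor = 1) {
  points <- assert_count(points, "points", min = 1)
  regime <- resolve_regime(regime)
  assert_nonneg(factor, "factor")
  if (factor < regime$factor_min || factor > regime$factor_max) {
    stop(sprintf(
      "factor %.3g outside regime '%s' policy range [%.3g, %.3g]",
      factor, regime$name, regime$factor_min, regime$factor_max),
      call. = FALSE)
  }
  round_half_away(points * regime$euro_per_point * factor, 2)
}

#' Construct a billing-code registry
#'
#' A registry is a data frame of billing codes with columns `code_id`,
#' `level`, `specialty`, `description`, `points`. Code ids follow the
#' pattern `AI-` + level digit + two digits, where the level digit encodes
#' the AI contribution level (1 = Level I assistive, 2 = Level II
#' augmentative, 3 = Level III autonomous). Registry point values are
#' authoritative: rubric tiers attach only as advisory metadata.
#'
#' @param code_id,level,specialty,description,points Column vectors of equal
#'   length.
#' @return A `billing_registry` (also a data frame).
#' @seealso [ai_code_table()] for the packaged reference table,
#'   [validate_registry()]
#' @export
billing_registry <- function(code_id, level, specialty, description, points) {
  reg <- data.frame(code_id = as.character(code_id),
                    level = as.character(level),
                    specialty = as.character(specialty),
                    description = as.character(description),
                    points = as.integer(points),
                    stringsAsFactors = FALSE)
  class(reg) <- c("billing_registry", "data.frame")
  reg
}

#' Packaged reference AI code table
#'
#' Loads the five-code reference registry shipped with the package: two
#' Level I assistive codes (chest X-ray triage, ultrasound feature
#' detection), two Level II augmentative codes (laboratory result analysis,
#' pathology slide review) and one Level III autonomous code (ECG
#' interpretation with preliminary report).
#'
#' @return A `billing_registry` of 5 codes.
#' @examples
#' regenerate_table(ai_code_table(), "ebm-simplified")
#' @export
ai_code_table <- function() {
  path <- system.file("extdata", "ai_codes.csv", package = "ddssfee",
                      mustWork = TRUE)
  read_code_table(path, format = "csv")
}

# Internal: expected level for a code id, from the first digit after "AI-".
level_from_code_id <- function(code_id) {
  digit <- substr(code_id, 4, 4)
  unname(c("1" = "I", "2" = "II", "3" = "III")[digit])
}

#' Validate a billing-code registry
#'
#' Report-based validation: returns one row per violation of the registry
#' rules (code-id format, code-id uniqueness, prefix digit consistent with
#' the recorded level, positive integer points). An empty report means the
#' registry is valid. The check is idempotent and independent of row order.
#'
#' @param registry A `billing_registry` or equivalent data frame.
#' @return Data frame with columns `code_id`, `rule`, `message`; zero rows
#'   when the registry is valid.
#' @examples
#' nrow(validate_registry(ai_code_table()))  # 0
#' @export
validate_registry <- function(registry) {
  required <- c("code_id", "level", "specialty", "description", "points")
  missing <- setdiff(required, names(registry))
  if (length(missing) > 0) {
    stop("registry is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  issues <- list()
  note <- function(code_id, rule, message) {
    issues[[length(issues) + 1]] <<- data.frame(
      code_id = code_id, rule = rule, message = message,
      stringsAsFactors = FALSE)
  }
  dup <- unique(registry$code_id[duplicated(registry$code_id)])
  for (id in dup) note(id, "unique_code_id", "code_id appears more than once")
  for (i in seq_len(nrow(registry))) {
    id <- registry$code_id[i]
    if (!grepl("^AI-[123][0-9]{2}$", id)) {
      note(id, "code_id_format",
           "code_id must match AI-<level digit><two digits>")
    } else {
      expected <- level_from_code_id(id)
      if (registry$level[i] != expected) {
        note(id, "prefix_level_consistency",
             sprintf("prefix digit implies Level %s but registry says %s",
                     expected, registry$level[i]))
      }
    }
    pts <- registry$points[i]
    if (is.na(pts) || pts <= 0 || pts != trunc(pts)) {
      note(id, "positive_points",
           sprintf("points must be a positive integer, got %s", pts))
    }
  }
  if (length(issues) == 0) {
    return(data.frame(code_id = character(), rule = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, issues)
  out <- out[order(out$code_id, out$rule), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Itemize one invoice line
#'
#' Produces an auditable fee line for a registry code under a regime. The
#' multiplier is recorded explicitly on the line: any factor other than 1.0
#' requires a non-empty justification note, and under the default AI policy
#' factors above 2.0 are rejected outright regardless of the regime's legacy
#' range.
#'
#' @param code_id Code to bill; must exist in `registry`.
#' @param registry A `billing_registry`.
#' @param regime A `point_value_regime` or preset name.
#' @param factor Multiplier (default 1.0).
#' @param note Justification for a non-unit factor.
#' @param factor_cap Policy cap on the multiplier for AI services
#'   (default 2.0); configurable but always enforced and recorded.
#' @return A `fee_line` list: `code_id`, `level`, `points`, `regime`,
#'   `factor`, `fee`, `currency`, `justification_note`.
#' @examples
#' itemize_invoice("AI-202", ai_code_table(), "ebm-simplified")  # 18.00 EUR
#' @export
itemize_invoice <- function(code_id, registry, regime, factor = 1,
                            note = NULL, factor_cap = 2) {
  regime <- resolve_regime(regime)
  row <- registry[registry$code_id == code_id, , drop = FALSE]
  if (nrow(row) == 0) {
    stop(sprintf("unknown code '%s' (not in registry)", code_id),
         call. = FALSE)
  }
  if (factor > factor_cap) {
    stop(sprintf(
      "factor %.3g exceeds the AI policy cap of %.3g", factor, factor_cap),
      call. = FALSE)
  }
  if (factor != 1 && (is.null(note) || !nzchar(trimws(note)))) {
    stop("a factor other than 1.0 requires a justification note",
         call. = FALSE)
  }
  fee <- compute_fee(row$points, regime, factor)
  structure(
    list(code_id = row$code_id, level = row$level, points = row$points,
         regime = regime$name, factor = factor, fee = fee,
         currency = regime$currency,
         justification_note = if (factor == 1) NULL else note),
    class = "fee_line"
  )
}

#' @export
print.fee_line <- function(x, ...) {
  cat(sprintf("%s (Level %s): %d points x regime '%s' x factor %.2f = %.2f %s\n",
              x$code_id, x$level, x$points, x$regime, x$factor, x$fee,
              x$currency))
  if (!is.null(x$justification_note)) {
    cat("  justification:", x$justification_note, "\n")
  }
  invisible(x)
}

#' Regenerate the billing table with base fees
#'
#' Appends a base-fee column (factor 1.0) to a registry under a regime,
#' reproducing the published schedule layout.
#'
#' @param registry A `billing_registry`.
#' @param regime A `point_value_regime` or preset name.
#' @return Data frame with columns `code_id`, `level`, `specialty`,
#'   `description`, `points`, `base_eur`.
#' @examples
#' regenerate_table(ai_code_table(), "ebm-simplified")$base_eur
#' @export
regenerate_table <- function(registry, regime) {
  regime <- resolve_regime(regime)
  if (nrow(registry) == 0) {
    out <- registry
    out$base_eur <- numeric(0)
    return(as.data.frame(out))
  }
  out <- as.data.frame(registry)
  out$base_eur <- vapply(out$points, compute_fee, numeric(1),
                         regime = regime, factor = 1)
  out
}

#' Report registry codes off the canonical tiers
#'
#' The rubric assigns canonical tiers 50/100/150, but registry point values
#' are authoritative and may deviate (anchor-calibrated codes). This report
#' flags every code whose points are not a canonical tier, annotated as a
#' registry-authoritative deviation rather than an error.
#'
#' @param registry A `billing_registry`.
#' @return Data frame with columns `code_id`, `points`, `nearest_tier`,
#'   `annotation`; zero rows when all codes sit on canonical tiers.
#' @examples
#' tier_consistency_report(ai_code_table())  # flags the 60- and 80-point codes
#' @export
tier_consistency_report <- function(registry) {
  tiers <- c(50L, 100L, 150L)
  off <- registry[!registry$points %in% tiers, , drop = FALSE]
  if (nrow(off) == 0) {
    return(data.frame(code_id = character(), points = integer(),
                      nearest_tier = integer(), annotation = character(),
                      stringsAsFactors = FALSE))
  }
  nearest <- vapply(off$points, function(p) tiers[which.min(abs(tiers - p))],
                    integer(1))
  data.frame(code_id = off$code_id, points = off$points,
             nearest_tier = nearest,
             annotation = "registry-authoritative deviation from canonical tier",
             stringsAsFactors = FALSE, row.names = NULL)
}
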