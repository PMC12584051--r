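test_that("fee formula reproduces the published schedule conversions", {
  # statutory private-schedule point value
  expect_equal(compute_fee(280, "goa"), 16.32)
  expect_equal(compute_fee(2000, "goa"), 116.57)
  expect_equal(compute_fee(4400, "goa"), 256.46)
  # statutory-insurance orientation value, 2025
  expect_equal(compute_fee(82, "ebm-2025"), 10.16)
  # simplified orientation value used by the AI code table
  expect_equal(compute_fee(100, "ebm-simplified"), 12.00)
  # multiplier applies before cent rounding
  expect_equal(compute_fee(280, "goa", factor = 2.3), 37.54)
})

test_that("fees are linear in points before cent rounding and at factor 1", {
  reg <- point_value_regime("toy", 0.37, factor_max = 3)
  for (p in c(1L, 7L, 50L, 360L)) {
    expect_equal(compute_fee(p, reg), round_half_away(p * 0.37, 2))
    expect_equal(compute_fee(10L * p, reg),
                 round_half_away(10 * p * 0.37, 2))
  }
})

test_that("factor policy bounds are enforced by regime", {
  expect_error(compute_fee(100, "goa", factor = 4), "outside regime")
  expect_error(compute_fee(100, "ebm-simplified", factor = 2.5),
               "outside regime")
  expect_error(compute_fee(0, "goa"), "points")
  expect_silent(compute_fee(100, "goa", factor = 3.5))
})

test_that("regime presets carry the documented factor policies", {
  goa <- fee_regimes("goa")
  expect_equal(goa$euro_per_point, 0.0582873)
  expect_equal(c(goa$factor_min, goa$typical_factor, goa$factor_max),
               c(1, 2.3, 3.5))
  expect_error(fee_regimes("no-such-regime"), "unknown regime")
  expect_error(point_value_regime("bad", 0.1, factor_min = 2,
                                  factor_max = 1),
               "factor policy")
})

test_that("packaged code table regenerates its base-fee column exactly", {
  reg <- ai_code_table()
  expect_equal(nrow(reg), 5)
  tab <- regenerate_table(reg, "ebm-simplified")
  expect_identical(tab$base_eur, c(6.0, 7.2, 9.6, 18.0, 12.0))
  # base fee is the factor-1 fee, row by row
  expect_equal(tab$base_eur,
               vapply(reg$points, compute_fee, numeric(1),
                      regime = "ebm-simplified", factor = 1))
  # linearity in the point value: doubled regime doubles every base fee
  double <- point_value_regime("double", 0.24)
  expect_equal(regenerate_table(reg, double)$base_eur, tab$base_eur * 2)
  # empty registry gives an empty table
  empty <- regenerate_table(reg[0, ], "ebm-simplified")
  expect_equal(nrow(empty), 0)
  expect_true("base_eur" %in% names(empty))
})

test_that("invoice itemization records the factor and enforces justification", {
  reg <- ai_code_table()
  line <- itemize_invoice("AI-202", reg, "ebm-simplified")
  expect_equal(line$fee, 18.00)
  expect_equal(line$factor, 1)
  expect_null(line$justification_note)
  # factor != 1 without a note is rejected
  expect_error(itemize_invoice("AI-101", reg, "ebm-simplified", factor = 1.5),
               "justification")
  expect_error(itemize_invoice("AI-101", reg, "ebm-simplified", factor = 1.5,
                               note = "  "),
               "justification")
  # justified factor at the AI cap
  line2 <- itemize_invoice("AI-301", reg, "ebm-simplified", factor = 2,
                           note = "repeat analysis, difficult trace")
  expect_equal(line2$fee, 24.00)
  expect_equal(line2$justification_note, "repeat analysis, difficult trace")
  # above the default AI policy cap, even where the regime would allow it
  expect_error(itemize_invoice("AI-101", reg, "goa", factor = 2.3,
                               note = "complex case"),
               "policy cap")
  # unknown code
  expect_error(itemize_invoice("AI-999", reg, "ebm-simplified"),
               "unknown code")
})

test_that("registry validation reports format, prefix and point violations", {
  expect_equal(nrow(validate_registry(ai_code_table())), 0)
  bad <- billing_registry(
    code_id = c("AI-105", "AI-105", "AI-4X1", "AI-202"),
    level = c("II", "I", "I", "II"),
    specialty = rep("Radiology", 4),
    description = rep("synthetic test code", 4),
    points = c(50L, 50L, 50L, -10L))
  report <- validate_registry(bad)
  expect_true("unique_code_id" %in% report$rule)
  expect_true(any(report$rule == "prefix_level_consistency" &
                    report$code_id == "AI-105"))
  expect_true(any(report$rule == "code_id_format" &
                    report$code_id == "AI-4X1"))
  expect_true(any(report$rule == "positive_points" &
                    report$code_id == "AI-202"))
  # idempotent and order-independent
  shuffled <- bad[c(3, 1, 4, 2), ]
  expect_identical(validate_registry(bad), validate_registry(shuffled))
  expect_identical(validate_registry(bad), validate_registry(bad))
})

test_that("tier consistency report flags codes off the canonical tiers", {
  report <- tier_consistency_report(ai_code_table())
  expect_setequal(report$code_id, c("AI-102", "AI-201"))
  expect_equal(report$points[report$code_id == "AI-102"], 60L)
  expect_equal(report$nearest_tier[report$code_id == "AI-102"], 50L)
  expect_equal(report$nearest_tier[report$code_id == "AI-201"], 100L)
  # registries entirely on canonical tiers yield an empty report
  canon <- billing_registry("AI-301", "III", "Cardiology", "synthetic", 150L)
  expect_equal(nrow(tier_consistency_report(canon)), 0)
})

test_that("half-away cent rounding differs from banker's rounding where it must", {
  expect_equal(round_half_away(0.125, 2), 0.13)  # round() would give 0.12
  expect_equal(round_half_away(-0.125, 2), -0.13)
  expect_equal(round_half_away(2.5), 3)
  expect_equal(round_half_away(3.5), 4)
  expect_equal(round_half_away(37.537, 2), 37.54)
})
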