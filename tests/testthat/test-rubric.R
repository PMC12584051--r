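test_that("valid score vectors pass through validation unchanged", {
  cases <- list(c(1, 1, 1, 1), c(3, 5, 2, 4), c(5, 5, 5, 5))
  for (v in cases) {
    out <- validate_scores(v)
    expect_equal(unname(unclass(out)), as.integer(v))
  }
  sv <- score_vector(3, 5, 2, 4)
  expect_s3_class(sv, "score_vector")
  expect_named(sv, c("data_complexity", "disease_complexity",
                     "question_complexity", "ai_involvement"))
})

test_that("out-of-range or non-integer scores are rejected naming the dimension", {
  expect_error(validate_scores(c(0, 3, 3, 3)), "data_complexity out of range")
  expect_error(validate_scores(c(3, 6, 3, 3)), "disease_complexity out of range")
  expect_error(validate_scores(c(3, 3, 2.5, 3)), "question_complexity")
  expect_error(validate_scores(c(3, 3, 3, NA)), "ai_involvement")
  expect_error(validate_scores(c(3, 3, 3)), "four dimension")
})

test_that("tier mapping follows the canonical rounded-mean rule", {
  expect_equal(assign_tier(c(1, 1, 1, 1))$tier_points, 50)
  expect_equal(assign_tier(c(3, 3, 3, 3))$tier_points, 100)
  expect_equal(assign_tier(c(5, 5, 5, 5))$tier_points, 150)
  # mean 2.5 rounds up under half-up
  t <- assign_tier(c(2, 2, 3, 3))
  expect_equal(t$mean_score, 2.5)
  expect_equal(t$rounded_mean, 3)
  expect_equal(t$tier_points, 100)
  # mean 2.75 rounds to 3 regardless of tie rule
  t2 <- assign_tier(c(2, 3, 3, 3))
  expect_equal(t2$rounded_mean, 3)
  expect_equal(t2$tier_points, 100)
  # tier labels follow the tier
  expect_equal(assign_tier(c(1, 1, 1, 1))$tier_label, "assistive")
  expect_equal(assign_tier(c(3, 3, 3, 3))$tier_label, "augmentative")
  expect_equal(assign_tier(c(5, 5, 4, 4))$tier_label,
               "high_complexity_or_autonomous")
})

test_that("half-even rounding is selectable and only changes exact halves", {
  # mean 2.5: half-up -> 3 (tier 100), half-even -> 2 (tier 50)
  expect_equal(assign_tier(c(2, 2, 3, 3), rounding = "half_even")$tier_points,
               50)
  # mean 3.5: half-up -> 4, half-even -> 4 (even) — identical here
  expect_equal(assign_tier(c(3, 3, 4, 4), rounding = "half_even")$tier_points,
               150)
  # non-half means are unaffected by the rule
  for (v in list(c(2, 3, 3, 3), c(1, 1, 1, 2), c(4, 4, 4, 5))) {
    expect_equal(assign_tier(v)$tier_points,
                 assign_tier(v, rounding = "half_even")$tier_points)
  }
})

test_that("assign_tier agrees with the brute-force oracle on all 625 vectors", {
  grid <- all_score_vectors()
  got <- apply(grid, 1, function(v) assign_tier(v)$tier_points)
  want <- apply(grid, 1, oracle_tier)
  expect_equal(got, want)
})

test_that("tier is monotone non-decreasing and permutation invariant", {
  grid <- all_score_vectors()
  tiers <- apply(grid, 1, function(v) assign_tier(v)$tier_points)
  for (i in seq_len(nrow(grid))) {
    v <- grid[i, ]
    for (d in 1:4) {
      if (v[d] < 5) {
        w <- v
        w[d] <- w[d] + 1L
        expect_gte(assign_tier(w)$tier_points, tiers[i])
      }
    }
  }
  set.seed(11)
  for (rep in 1:25) {
    v <- sample(1:5, 4, replace = TRUE)
    p <- sample(v)
    expect_equal(assign_tier(p)$mean_score, assign_tier(v)$mean_score)
    expect_equal(assign_tier(p)$tier_points, assign_tier(v)$tier_points)
  }
})

test_that("perturbation stability matches explicit enumeration", {
  expect_true(perturbation_stability(c(3, 3, 3, 3)))
  expect_true(perturbation_stability(c(1, 1, 1, 1)))
  expect_false(perturbation_stability(c(2, 2, 2, 3)))
  # full agreement with the enumeration oracle over all 625 vectors
  grid <- all_score_vectors()
  got <- apply(grid, 1, function(v) as.logical(perturbation_stability(v)))
  want <- apply(grid, 1, oracle_stability)
  expect_equal(got, want)
})

test_that("stability trace records clipping at the scale boundaries", {
  tr <- attr(perturbation_stability(c(1, 1, 1, 1)), "trace")
  expect_equal(nrow(tr), 8)
  expect_equal(sum(tr$clipped), 4)  # the four -1 perturbations clip at 1
  tr5 <- attr(perturbation_stability(c(5, 5, 5, 5)), "trace")
  expect_equal(sum(tr5$clipped), 4)
})

test_that("level suggestion maps involvement 1-2/3-4/5 onto Levels I/II/III", {
  expect_equal(suggest_level(c(3, 3, 3, 1))$level, "I")
  expect_equal(suggest_level(c(3, 3, 3, 2))$level, "I")
  expect_equal(suggest_level(c(1, 1, 1, 3))$level, "II")
  expect_equal(suggest_level(c(1, 1, 1, 4))$level, "II")
  expect_equal(suggest_level(c(1, 1, 1, 5))$level, "III")
  # Level III arises only from involvement 5
  grid <- all_score_vectors()
  lvl <- apply(grid, 1, function(v) suggest_level(v)$level)
  expect_true(all((lvl == "III") == (grid[, 4] == 5)))
})

test_that("dimension anchors document all four dimensions", {
  anchors <- dimension_anchors()
  expect_named(anchors, c("data_complexity", "disease_complexity",
                          "question_complexity", "ai_involvement"))
  expect_true(all(nzchar(anchors)))
})
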