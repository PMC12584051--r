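# Independent brute-force oracles and fixture builders used across tests.
# These stay deliberately naive and separate from the package code paths.

# Oracle tier: explicit table lookup on the rounded mean, with halves up.
oracle_tier <- function(scores) {
  m <- sum(scores) / 4
  r <- floor(m + 0.5)                     # scores >= 1, so half-up == away
  unname(c(`1` = 50L, `2` = 50L, `3` = 100L, `4` = 150L, `5` = 150L)[
    as.character(r)])
}

# Oracle stability: enumerate all 8 unit perturbations with clipping.
oracle_stability <- function(scores) {
  base <- oracle_tier(scores)
  for (d in 1:4) {
    for (delta in c(-1L, 1L)) {
      w <- scores
      w[d] <- min(5L, max(1L, w[d] + delta))
      if (oracle_tier(w) != base) return(FALSE)
    }
  }
  TRUE
}

# All 625 score vectors, one per row.
all_score_vectors <- function() {
  as.matrix(expand.grid(a = 1:5, b = 1:5, c = 1:5, d = 1:5))
}

# Worked-example cost-benefit inputs, constructed in code (not the packaged
# fixture loader, so fixture-loading itself can be tested against this).
example_inputs <- function(...) {
  defaults <- list(prevalence = 0.10,
                   soc = accuracy_profile(0.85, 0.90),
                   ai = accuracy_profile(0.90, 0.93),
                   cost_fn = 2000, cost_fp = 150, ai_fee = 12,
                   minutes_saved = 3, n = 1000)
  args <- utils::modifyList(defaults, list(...))
  do.call(cost_benefit_inputs, args)
}
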