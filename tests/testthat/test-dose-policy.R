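test_that("BSA sampling respects its moments and truncation", {
  set.seed(4)
  expect_equal(sample_bsa(5, 1.8, 0), rep(1.8, 5))
  x <- sample_bsa(10000, 1.8, 0.2)
  expect_true(all(x >= 1.2 & x <= 2.6))
  expect_lt(abs(mean(x) - 1.8), 3 * 0.2 / sqrt(10000) + 0.005)
  expect_error(sample_bsa(5, -1, 0.2), "domain")
})

test_that("adjustment rules validate and look up occurrence fractions", {
  r <- smpc_rule()
  expect_equal(mctmm:::rule_fraction(r, 0, 0), 1)
  expect_equal(mctmm:::rule_fraction(r, 1, 3), 1)
  expect_equal(mctmm:::rule_fraction(r, 2, 2), 0.75)
  expect_equal(mctmm:::rule_fraction(r, 3, 2), 0.5)
  expect_true(is.na(mctmm:::rule_fraction(r, 3, 3)))  # discontinuation
  expect_error(smpc_rule(grade2 = c(0.5, 0.75)), "non-increasing")
})

test_that("paired scenarios share draws and only diverge through the rule", {
  p <- ref_params()
  s_no <- run_scenario(150, 6, p, rule = NULL, seed = 17)
  s_ad <- run_scenario(150, 6, p, rule = smpc_rule(), seed = 17)
  expect_identical(s_no$bsa, s_ad$bsa)
  # no adjustment is possible before cycle 2
  expect_identical(s_no$probs[, 1, ], s_ad$probs[, 1, ])
  expect_identical(s_no$dose[, 1], s_ad$dose[, 1])
  # a zero dose effect makes the rule irrelevant
  p0 <- mctmm_params(1.81, -1.8, -2.08, 1.09, 0, 1.12, 0.542)
  a <- run_scenario(100, 6, p0, rule = NULL, seed = 5)
  b <- run_scenario(100, 6, p0, rule = smpc_rule(), seed = 5)
  expect_identical(a$probs, b$probs)
  expect_identical(a$transitions, b$transitions)
})

test_that("dose trails never re-escalate and bookkeeping is consistent", {
  s <- run_scenario(200, 6, ref_params(), rule = smpc_rule(), seed = 23)
  expect_true(all(apply(s$dose, 1, function(d) all(diff(d) <= 1e-9))))
  expect_equal(sum(s$transitions), 200 * 5)
  # per patient-cycle the recorded distribution is normalized
  expect_equal(apply(s$probs, c(1, 2), sum),
               matrix(1, 200, 6), tolerance = 1e-9)
  # single-cycle scenarios have no transitions and no adjustments
  s1 <- run_scenario(50, 1, ref_params(), rule = smpc_rule(), seed = 2)
  expect_equal(sum(s1$transitions), 0)
})

test_that("label-style dose adjustments reduce sustained severe toxicity", {
  p <- ref_params()
  s_no <- run_scenario(400, 6, p, rule = NULL, seed = 41)
  s_ad <- run_scenario(400, 6, p, rule = smpc_rule(), seed = 41)
  expect_lt(s_ad$transitions[4, 4], s_no$transitions[4, 4])
  # median grade-3 probability in the later cycles drops under the rule
  med3 <- function(s, cyc) stats::median(s$probs[, cyc, 4])
  for (cyc in 4:6) expect_lte(med3(s_ad, cyc), med3(s_no, cyc))
})

test_that("tablet rounding produces achievable doses", {
  expect_equal(mctmm:::round_to_tablets(4500), 4500)  # 2 x (3x500 + 5x150)
  d <- mctmm:::round_to_tablets(4321)
  half <- d / 2
  combos <- outer(0:20 * 150, 0:6 * 500, "+")
  expect_true(any(abs(combos - half) < 1e-9))
})
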