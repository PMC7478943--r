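test_that("generated designs hit the marginal dose target across seeds", {
  med <- vapply(1:10, function(s) {
    dat <- mctmm:::records_to_data(generate_design(cohort_design(), seed = s))
    stats::median(dat$DOSE[dat$CYCLE > 0 & dat$DOSE > 0])
  }, 0)
  expect_true(all(abs(med - 3000) <= 250))
})

test_that("design counts and discontinuation rules are respected", {
  d <- cohort_design()
  recs <- generate_design(d, seed = 1)
  expect_length(recs, 150)
  expect_equal(sum(vapply(recs, function(r) r$sex == "male", TRUE)), 39)
  expect_equal(sum(vapply(recs, function(r) r$mono, TRUE)), 150 - 79)
  ents <- table(vapply(recs, function(r) r$entity, ""))
  expect_equal(unname(ents[c("colorectal", "breast", "other")]),
               c(71, 67, 12), ignore_attr = TRUE)
  # dose is zero for every cycle after a discontinuation and never before
  for (r in recs) {
    z <- which(r$cycles$dose == 0)
    if (length(z)) expect_equal(z, seq(min(z), nrow(r$cycles)))
  }
  # without discontinuations no zero doses occur
  recs0 <- generate_design(cohort_design(n_discontinue = 0), seed = 2)
  expect_false(any(unlist(lapply(recs0, function(r) r$cycles$dose == 0))))
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_cohort(cohort_design(n_patients = 25), seed = 33)
  b <- generate_cohort(cohort_design(n_patients = 25), seed = 33)
  expect_identical(a, b)
  c <- generate_cohort(cohort_design(n_patients = 25), seed = 34)
  expect_false(identical(a, c))
})

test_that("cohorts parse through the estimation reader", {
  dat <- generate_cohort(cohort_design(n_patients = 30), seed = 8)
  expect_silent(validate_dataset(dat))
  recs <- mctmm:::records_from_data(dat)
  expect_length(recs, 30)
})

test_that("simulated transition structure is diagonal-dominated", {
  dat <- generate_cohort(cohort_design(), default_params(), seed = 11)
  tab <- transition_counts(dat)
  # staying put dominates each occupied origin grade, as in observed data
  expect_equal(unname(which.max(tab[1, ])), 1)
  expect_equal(unname(which.max(tab[2, ])), 2)
  expect_gt(tab[1, 1], 100)
  expect_gt(tab[2, 2], 50)
  # frozen dynamics keep everyone at the asymptomatic baseline
  frozen <- mctmm_params(1.81, -1.8, -2.08, 1e9, 8.33e-4, 0, 0)
  datf <- generate_cohort(cohort_design(n_patients = 30), frozen, seed = 5)
  expect_true(all(datf$DV == 0, na.rm = TRUE))
})

test_that("larger IIV widens the spread of per-patient maximum grade", {
  mg <- function(d) tapply(d$DV[d$CYCLE > 0], d$ID[d$CYCLE > 0], max,
                           na.rm = TRUE)
  wide <- mctmm_params(1.81, -1.8, -2.08, 1.09, 8.33e-4, 2, 1.5)
  none <- mctmm_params(1.81, -1.8, -2.08, 1.09, 8.33e-4, 0, 0)
  s_wide <- mean(vapply(1:4, function(s)
    stats::sd(mg(generate_cohort(cohort_design(), wide, seed = s))), 0))
  s_none <- mean(vapply(1:4, function(s)
    stats::sd(mg(generate_cohort(cohort_design(), none, seed = s))), 0))
  expect_gt(s_wide, s_none)
})
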