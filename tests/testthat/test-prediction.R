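test_that("MAP estimation returns the prior mode without information", {
  p <- ref_params()
  empty <- manual_record(grades = c(NA_integer_, NA_integer_))
  expect_equal(unname(map_eta(empty, p)), c(0, 0), tolerance = 1e-8)
  # degenerate prior forces eta to zero whatever the data
  p0 <- mctmm_params(1.81, -1.8, -2.08, 1.09, 8.33e-4, 0, 0)
  rec <- manual_record(grades = c(3L, 3L, 3L))
  expect_equal(unname(map_eta(rec, p0)), c(0, 0))
})

test_that("MAP estimates recover simulated random effects with shrinkage", {
  p <- ref_params()
  set.seed(5)
  n <- 200
  recs <- lapply(seq_len(n), function(i) {
    r <- manual_record(grades = rep(0L, 6))  # all occasions observed
    r$id <- i
    r
  })
  eta_true <- cbind(rnorm(n, 0, p$omega_alpha), rnorm(n, 0, p$omega_met))
  sims <- lapply(seq_len(n), function(i)
    simulate_subject(recs[[i]], p, eta = eta_true[i, ]))
  maps <- t(vapply(sims, map_eta, c(0, 0), params = p))
  expect_gt(stats::cor(eta_true[, 1], maps[, 1]), 0.25)
  expect_gt(stats::cor(eta_true[, 2], maps[, 2]), 0.25)
  # shrinkage: MAP values are less dispersed than the prior draws
  expect_lt(stats::sd(maps[, 1]), stats::sd(eta_true[, 1]))
})

test_that("next-cycle prediction propagates from the last observed grade", {
  # frozen dynamics predict persistence of the last observation
  frozen <- mctmm_params(1.81, -1.8, -2.08, 1e9, 8.33e-4, 1.12, 0.542)
  rec <- manual_record(grades = c(2L, NA_integer_))
  pred <- predict_next_cycle(rec, 2, frozen)
  expect_equal(pred$modal, 2)
  expect_equal(unname(pred$dist[3]), 1, tolerance = 1e-8)
  expect_equal(sum(pred$dist), 1, tolerance = 1e-10)
  # missing dosing row for the target cycle is an error
  expect_error(predict_next_cycle(rec, 3, frozen), "missing next dose")
  # dose withdrawal with instant equilibration recovers toward grade 0
  fast <- mctmm_params(1.81, -1.8, -2.08, 1e-4, 8.33e-4)
  rec0 <- manual_record(grades = c(3L, NA_integer_), doses = c(3000, 0))
  pred0 <- predict_next_cycle(rec0, 2, fast)
  expect_lte(pred0$modal, 3)
  expect_equal(unname(pred0$dist),
               unname(grade_distribution(cumulative_logits(fast, 0))),
               tolerance = 1e-6)
  # a questionnaire gap propagates piecewise over the per-cycle doses
  p <- ref_params()
  gap <- manual_record(grades = c(1L, NA, NA), doses = c(3000, 2000, 1000))
  pg <- predict_next_cycle(gap, 3, p)
  Tg <- transition_matrix(p, c(2000, 1000), c(1, 1))
  expect_equal(unname(pg$dist), unname(Tg[2, ]), tolerance = 1e-12)
})

test_that("prediction tables exclude baseline and flag the clinical grouping", {
  p <- ref_params()
  dat <- small_cohort_data(n = 15, seed = 27)
  tab <- prediction_table(dat, p)
  expect_true(all(tab$cycle >= 2))
  expect_true(all(tab$predicted %in% 0:3 & tab$observed %in% 0:3))
  expect_equal(tab$predicted_ge2, tab$predicted >= 2)
  # every predicted cycle is genuinely observed in the data
  obs <- dat[!is.na(dat$DV) & dat$CYCLE >= 2, ]
  expect_equal(nrow(tab), nrow(obs))
})

test_that("predictive values count the grade >= 2 grouping correctly", {
  tab <- data.frame(predicted = c(rep(2, 8), rep(0, 4)),
                    observed = c(rep(2, 2), rep(1, 6), rep(0, 3), 3))
  v <- ppv_npv(tab)
  expect_equal(unname(v["ppv"]), 0.25)
  expect_equal(unname(v["npv"]), 0.75)
  perfect <- data.frame(predicted = c(0, 2, 3, 1), observed = c(0, 2, 3, 1))
  expect_equal(unname(ppv_npv(perfect)), c(1, 1))
  onlypos <- data.frame(predicted = c(2, 3), observed = c(2, 1))
  expect_true(is.na(ppv_npv(onlypos)["npv"]))
  byc <- ppv_npv(cbind(tab, cycle = rep(2:3, 6)), by_cycle = TRUE)
  expect_equal(nrow(byc), 3)
  expect_equal(byc$cycle[3], "pooled")
})

test_that("saturated models give perfect predictive values", {
  # everyone driven to grade 3: all predictions and observations agree
  hi <- mctmm_params(30, -0.01, -0.01, 0.01, 0, 0, 0)
  dat <- generate_cohort(cohort_design(n_patients = 10), hi, seed = 3)
  tab <- prediction_table(dat, hi)
  expect_equal(unname(ppv_npv(tab)["ppv"]), 1)
  # everyone asymptomatic: perfect negative predictions
  lo <- mctmm_params(-30, -0.01, -0.01, 0.01, 0, 0, 0)
  dat2 <- generate_cohort(cohort_design(n_patients = 10), lo, seed = 3)
  tab2 <- prediction_table(dat2, lo)
  expect_equal(unname(ppv_npv(tab2)["npv"]), 1)
})
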