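test_that("individual log-likelihood is the sum of log transition terms", {
  p <- ref_params()
  rec <- manual_record(grades = c(0L, 1L, 2L), doses = c(3000, 3000, 4000))
  # hand-computed oracle from the interval transition matrices
  T1 <- transition_matrix(p, 3000, 1)
  T3 <- transition_matrix(p, 4000, 1)
  expected <- log(T1[1, 1]) + log(T1[1, 2]) + log(T3[2, 3])
  expect_equal(individual_loglik(rec, p), expected, tolerance = 1e-10)
  # repeating an identical transition doubles the log-likelihood
  one <- manual_record(grades = 0L)
  two <- manual_record(grades = c(0L, 0L))
  expect_equal(individual_loglik(two, p), 2 * individual_loglik(one, p),
               tolerance = 1e-12)
  # a questionnaire gap spans the interval with piecewise dose
  gap <- manual_record(grades = c(NA, 2L), doses = c(3000, 1000))
  Tg <- transition_matrix(p, c(3000, 1000), c(1, 1))
  expect_equal(individual_loglik(gap, p), log(Tg[1, 3]), tolerance = 1e-12)
})

test_that("marginal OFV collapses to the conditional one without IIV", {
  p0 <- mctmm_params(1.81, -1.8, -2.08, 1.09, 8.33e-4, 0, 0)
  dat <- small_cohort_data(n = 15, seed = 3, params = p0)
  recs <- mctmm:::records_from_data(validate_dataset(dat))
  ll <- sum(vapply(recs, individual_loglik, 0, params = p0))
  expect_equal(marginal_ofv(dat, p0), -2 * ll, tolerance = 1e-10)
  # a subject with no post-baseline observations contributes nothing
  p <- ref_params()
  base <- marginal_ofv(recs, p)
  empty <- manual_record(grades = c(NA_integer_, NA_integer_))
  expect_equal(marginal_ofv(c(recs, list(empty)), p), base, tolerance = 1e-9)
})

test_that("Gauss-Hermite rule integrates exactly where it must", {
  gh <- mctmm:::gauss_hermite(5)
  # moments of exp(-x^2): integral x^4 exp(-x^2) = 3 sqrt(pi) / 4
  expect_equal(sum(gh$weights), sqrt(pi), tolerance = 1e-12)
  expect_equal(sum(gh$weights * gh$nodes^4), 3 * sqrt(pi) / 4,
               tolerance = 1e-12)
  # against base R's adaptive integrator on a non-polynomial integrand
  f <- function(x) stats::plogis(1.5 * x + 0.3)
  gh21 <- mctmm:::gauss_hermite(21)
  # x = mu + sqrt(2) sigma z with mu = 0.2, sigma = 1/sqrt(2)
  agq_val <- sum(gh21$weights * f(gh21$nodes + 0.2)) / sqrt(pi)
  ref <- stats::integrate(function(x) f(x) * dnorm(x, 0.2, 1 / sqrt(2)),
                          -Inf, Inf, rel.tol = 1e-12)$value
  expect_equal(agq_val, ref, tolerance = 1e-9)
})

test_that("Laplace approximation tracks adaptive quadrature per subject", {
  p <- ref_params()
  dat <- small_cohort_data(n = 20, seed = 7)
  recs <- mctmm:::records_from_data(validate_dataset(dat))
  spec <- mctmm_covspec(intercept = "dose")
  cfg <- mctmm:::model_config(p, spec)
  subs <- mctmm:::build_subjects(recs, spec, 3000)
  gaps <- vapply(subs, function(s) {
    em <- mctmm:::cpp_eta_mode(s, cfg$alpha1, cfg$b2, cfg$b3, cfg$met,
                               cfg$beta_int, cfg$beta_met, cfg$wa, cfg$wm)
    em$laplace_contrib - mctmm:::agq_subject_nll(s, cfg, 21)
  }, 0)
  expect_lt(max(abs(gaps)), 0.1)
  # quadrature itself is converged: 21 and 41 nodes agree closely
  g41 <- mctmm:::agq_subject_nll(subs[[2]], cfg, 41)
  g21 <- mctmm:::agq_subject_nll(subs[[2]], cfg, 21)
  expect_equal(g21, g41, tolerance = 1e-7)
})

test_that("fixed effects are recovered without IIV on a large cohort", {
  truth <- mctmm_params(1.81, -1.8, -2.08, 1.09, 8.33e-4, 0, 0)
  dat <- generate_cohort(cohort_design(n_patients = 250), truth, seed = 31)
  fit <- mctmm_fit(dat, fix_omega = c(omega_alpha = 0, omega_met = 0),
                   quiet = TRUE, se = FALSE)
  est <- setNames(fit$table$estimate, fit$table$parameter)
  tr <- c(alpha1 = 1.81, b2 = -1.8, b3 = -2.08, met = 1.09)
  for (nm in names(tr)) {
    expect_lt(abs(est[nm] - tr[nm]) / abs(tr[nm]), 0.15)
  }
  expect_lt(abs(est["theta_dose"] - 8.33e-4) / 8.33e-4, 0.5)
  # starting from the generating values never lands above the truth OFV
  fit2 <- mctmm_fit(dat, start = truth,
                    fix_omega = c(omega_alpha = 0, omega_met = 0),
                    quiet = TRUE, se = FALSE)
  expect_lte(fit2$ofv, marginal_ofv(dat, truth) + 1e-6)
})

test_that("likelihood-ratio decisions follow the chi-square reference", {
  lrt <- likelihood_ratio_test(1000, 1000 - 23.45, df = 1)
  expect_true(lrt$significant)
  expect_lt(lrt$p_value, 1e-5)
  lrt2 <- likelihood_ratio_test(1000, 1000 - 3.454, df = 1)
  expect_false(lrt2$significant)
  expect_equal(lrt2$p_value, 0.063, tolerance = 1e-2)
  # an OFV increase can never be significant
  expect_false(likelihood_ratio_test(1000, 1001.006, df = 1)$significant)
  expect_equal(likelihood_ratio_test(1000, 1000, df = 1)$p_value, 1)
  # the threshold itself: 6.64 is the df = 1 critical drop at p = 0.01
  expect_false(likelihood_ratio_test(1000, 1000 - 6.63, df = 1)$significant)
  expect_true(likelihood_ratio_test(1000, 1000 - 6.64, df = 1)$significant)
  expect_error(likelihood_ratio_test(1, 1, df = 3), "df")
})

test_that("OFV is invariant to subject order and reproducible", {
  p <- ref_params()
  dat <- small_cohort_data(n = 12, seed = 9)
  recs <- mctmm:::records_from_data(validate_dataset(dat))
  expect_equal(marginal_ofv(recs, p), marginal_ofv(rev(recs), p),
               tolerance = 1e-10)
  expect_identical(marginal_ofv(recs, p), marginal_ofv(recs, p))
})

test_that("bootstrap machinery resamples, refits and summarizes", {
  dat <- small_cohort_data(n = 12, seed = 9)
  fit <- mctmm_fit(dat, quiet = TRUE, se = FALSE,
                   control = list(iter.max = 60))
  boot <- mctmm_bootstrap(dat, fit, n_replicates = 3, seed = 21,
                          control = list(iter.max = 40))
  expect_s3_class(boot, "mctmm_bootstrap")
  expect_equal(nrow(boot$replicates) + boot$n_fail, 3)
  expect_equal(boot$summary$parameter, fit$table$parameter)
  with(boot$summary, expect_true(all(lo95 <= median & median <= hi95)))
  # medians sit inside their own replicate band by construction
  expect_true(all(boot$summary$median >=
                    apply(boot$replicates, 2, min) - 1e-12))
})

test_that("the covariate screen tabulates single-effect LRTs", {
  dat <- small_cohort_data(n = 20, seed = 5)
  screen <- covariate_screen(dat, effects = list(c("dose", "intercept"),
                                                 c("sex", "met")))
  expect_equal(nrow(screen), 2)
  expect_equal(screen$df, c(1, 1))
  # adding a parameter can only improve the fit
  expect_true(all(screen$delta_ofv <= 1e-3, na.rm = TRUE))
  expect_equal(screen$significant,
               screen$p_value <= 0.01 & !is.na(screen$p_value))
  # a null effect on MET stays clearly non-significant
  expect_false(screen$significant[2])
})
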