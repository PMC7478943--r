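test_that("cumulative logits follow the ordered-intercept dose model", {
  p <- ref_params()
  expect_equal(cumulative_logits(p, 3000), c(1.81, 0.01, -2.07),
               tolerance = 1e-12)
  # 1000 mg more shifts every logit by theta_dose * 1000
  shift <- cumulative_logits(p, 4000) - cumulative_logits(p, 3000)
  expect_equal(shift, rep(0.833, 3), tolerance = 1e-9)
  # at the centering dose the slope drops out entirely
  p2 <- mctmm_params(0.5, -1, -1, 1, theta_dose = 0.123)
  expect_equal(cumulative_logits(p2, 3000), c(0.5, -0.5, -1.5))
  expect_true(all(diff(cumulative_logits(p, 5000)) < 0))
  expect_error(cumulative_logits(p, -5), "daily_dose")
  expect_error(cumulative_logits(p, NaN), "daily_dose")
})

test_that("grade distribution is the expit-difference map and saturates", {
  gd <- grade_distribution(c(1.81, 0.01, -2.07))
  expect_equal(sum(gd), 1, tolerance = 1e-12)
  # P(grade >= 1) computed independently via plogis
  expect_equal(unname(sum(gd[2:4])), stats::plogis(1.81), tolerance = 1e-12)
  expect_equal(unname(gd[4]), stats::plogis(-2.07), tolerance = 1e-12)
  expect_equal(unname(grade_distribution(c(32, 31, 30))[4]), 1,
               tolerance = 1e-9)
  expect_equal(unname(grade_distribution(c(-30, -31, -32))[1]), 1,
               tolerance = 1e-9)
  expect_error(grade_distribution(c(1, 1, 0)), "ordering")
  expect_error(grade_distribution(c(2, 1)), "3 finite")
})

test_that("distribution properties hold across random parameter draws", {
  set.seed(1)
  for (k in 1:100) {
    p <- mctmm_params(alpha1 = rnorm(1, 0, 2), b2 = -rexp(1) - 0.01,
                      b3 = -rexp(1) - 0.01, met = rexp(1) + 0.05,
                      theta_dose = runif(1, 1e-5, 2e-3))
    eta <- rnorm(1)
    d1 <- runif(1, 0, 4000)
    d2 <- d1 + runif(1, 10, 1000)
    g1 <- grade_distribution(cumulative_logits(p, d1, eta_alpha = eta))
    g2 <- grade_distribution(cumulative_logits(p, d2, eta_alpha = eta))
    expect_true(all(g1 >= 0))
    expect_lt(abs(sum(g1) - 1), 1e-12)
    # increasing dose strictly increases every cumulative probability
    c1 <- rev(cumsum(rev(g1)))[2:4]
    c2 <- rev(cumsum(rev(g2)))[2:4]
    expect_true(all(c2 > c1))
  }
})

test_that("covariate adjustments evaluate the configured effects", {
  none <- covariate_adjustment(mctmm_covspec(), cov = list(daily_dose = 2000))
  expect_equal(none$logit, 0)
  expect_equal(none$met_mult, 1)
  adj <- covariate_adjustment(mctmm_covspec(intercept = "dose"),
                              coefs = list(intercept = c(dose = 8.33e-4)),
                              cov = list(daily_dose = 2000))
  expect_equal(adj$logit, -0.833, tolerance = 1e-9)
  adj2 <- covariate_adjustment(mctmm_covspec(met = "sex"),
                               coefs = list(met = c(sex_female = 0.7)),
                               cov = list(sex = "female"))
  expect_equal(adj2$met_mult, exp(0.7))
  adj3 <- covariate_adjustment(mctmm_covspec(met = "sex"),
                               coefs = list(met = c(sex_female = 0.7)),
                               cov = list(sex = "male"))
  expect_equal(adj3$met_mult, 1)
  expect_error(mctmm_covspec(intercept = "bmi"), "unknown covariate")
})

test_that("parameter container enforces its constraints", {
  expect_error(mctmm_params(1, 0.1, -1, 1), "negative")
  expect_error(mctmm_params(1, -1, -1, 0), "met")
  expect_error(mctmm_params(1, -1, -1, 1, omega_alpha = -0.1), "omega")
  expect_error(mctmm_params(NA, -1, -1, 1), "finite")
  p <- default_params()
  expect_s3_class(p, "mctmm_params")
  expect_equal(p$alpha1 + p$b2, 0.01)
})

test_that("parameter files round-trip", {
  p <- default_params()
  f <- tempfile(fileext = ".cfg")
  write_params(p, f)
  q <- read_params(f)
  expect_equal(unclass(q), unclass(p))
  writeLines(c("alpha1 = 1", "junk = 2"), f)
  expect_error(read_params(f), "unknown parameter")
})
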