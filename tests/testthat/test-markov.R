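test_that("generator is tridiagonal, conservative and detailed-balanced", {
  gd <- grade_distribution(cumulative_logits(ref_params(), 3000))
  q <- build_generator(gd, 1.09)
  # no direct transitions between non-adjacent grades
  expect_equal(unname(q[cbind(c(1, 1, 2, 3, 4, 4), c(3, 4, 4, 1, 1, 2))]),
               rep(0, 6))
  expect_equal(unname(rowSums(q)), rep(0, 4), tolerance = 1e-12)
  # pairwise-normalized rates: uniform target, met = 1 -> all adjacent 0.5
  qu <- build_generator(rep(0.25, 4), 1)
  expect_equal(unname(qu[1, 2]), 0.5)
  expect_equal(unname(qu[2, 1]), 0.5)
  # doubling met halves every rate
  expect_equal(build_generator(gd, 2), build_generator(gd, 1) / 2)
  expect_error(build_generator(gd, 0), "domain")
  expect_error(build_generator(c(0.5, 0.5), 1), "domain")
})

test_that("detailed balance and stationarity hold for random targets", {
  set.seed(2)
  for (k in 1:50) {
    x <- rexp(4)
    p <- x / sum(x)
    met <- rexp(1) + 0.05
    q <- build_generator(p, met)
    flux <- p * q
    expect_lt(max(abs(flux - t(flux))), 1e-15)
    # stationary distribution recovered by an independent null-space solve
    expect_equal(unname(stationary_distribution(q)), p, tolerance = 1e-10)
  }
})

test_that("propagation solves the probability compartment system", {
  gd <- grade_distribution(cumulative_logits(ref_params(), 3000))
  q <- build_generator(gd, 1.09)
  # zero elapsed time returns the indicator of the start grade
  expect_equal(unname(propagate(q, 2, 0)), c(0, 0, 1, 0))
  # ergodic limit: long horizons reach the stationary target from any grade
  for (g in 0:3) {
    expect_equal(unname(propagate(q, g, 1000)), unname(gd), tolerance = 1e-8)
  }
  # independent ODE-solver oracle for a finite interval
  deriv <- function(t, y, parms) list(as.numeric(y %*% parms))
  for (g in c(0, 3)) {
    y0 <- as.numeric(diag(4)[g + 1, ])
    sol <- deSolve::ode(y0, times = c(0, 1), func = deriv, parms = q,
                        rtol = 1e-10, atol = 1e-12)
    expect_equal(unname(propagate(q, g, 1)), unname(sol[2, 2:5]),
                 tolerance = 1e-8)
  }
  expect_error(propagate(q, 0, -1), "domain")
  expect_error(propagate(q, 5, 1), "start_grade")
})

test_that("interval transition matrices are stochastic and Markov-consistent", {
  p <- ref_params()
  set.seed(3)
  for (k in 1:20) {
    pp <- mctmm_params(rnorm(1, 1, 1), -rexp(1) - 0.1, -rexp(1) - 0.1,
                       rexp(1) + 0.1, theta_dose = runif(1, 0, 1.5e-3))
    ea <- rnorm(1, 0, 0.8)
    em <- rnorm(1, 0, 0.5)
    dose <- runif(1, 500, 5000)
    a <- runif(1, 0.2, 2)
    b <- runif(1, 0.2, 2)
    Ta <- transition_matrix(pp, dose, a, ea, em)
    Tb <- transition_matrix(pp, dose, b, ea, em)
    Tab <- transition_matrix(pp, dose, a + b, ea, em)
    expect_equal(unname(rowSums(Ta)), rep(1, 4), tolerance = 1e-10)
    # Chapman-Kolmogorov on a constant-dose interval
    expect_lt(max(abs(Ta %*% Tb - Tab)), 1e-9)
  }
  # frozen dynamics: enormous MET leaves the grade unchanged over one cycle
  frozen <- mctmm_params(1.81, -1.8, -2.08, 1e9, 8.33e-4)
  expect_equal(unname(transition_matrix(frozen, 3000, 1)), diag(4),
               tolerance = 1e-8)
  # instant equilibration: tiny MET sends every row to the stationary target
  fast <- mctmm_params(1.81, -1.8, -2.08, 1e-4, 8.33e-4)
  Tf <- transition_matrix(fast, 3000, 1)
  gd <- grade_distribution(cumulative_logits(p, 3000))
  for (g in 1:4) expect_equal(unname(Tf[g, ]), unname(gd), tolerance = 1e-6)
  # non-adjacent jumps vanish faster than the interval length
  Teps <- transition_matrix(p, 3000, 1e-6)
  expect_lt(Teps[1, 3] / 1e-6, 1e-4)
  expect_lt(Teps[1, 4] / 1e-6, 1e-8)
  # piecewise dose equals the product of the per-segment matrices
  Tpw <- transition_matrix(p, c(3000, 0), c(1, 1))
  expect_equal(Tpw,
               transition_matrix(p, 3000, 1) %*% transition_matrix(p, 0, 1),
               tolerance = 1e-12)
})
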