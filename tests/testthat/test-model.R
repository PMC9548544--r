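test_that("typical clearance reproduces the published covariate model", {
  th <- theta_final()
  at <- function(egfr, wt, mann)
    typical_cl(th, data.frame(egfr = egfr, wt = wt, mannitol = mann))
  expect_equal(at(115.2, 70, FALSE), 7.98)
  expect_equal(at(90, 65, TRUE), 7.2952099, tolerance = 1e-6)
  expect_equal(at(15, 65, TRUE), 1.7398700, tolerance = 1e-6)
  # mannitol scales clearance by exactly exp(0.13)
  expect_equal(at(90, 65, TRUE) / at(90, 65, FALSE), exp(0.13))
})

test_that("typical clearance is strictly increasing in eGFR and body weight", {
  th <- theta_final()
  egfr <- seq(5, 240, by = 5)
  cl <- typical_cl(th, data.frame(egfr = egfr, wt = 70, mannitol = FALSE))
  expect_true(all(diff(cl) > 0))
  wt <- seq(40, 130, by = 5)
  cl <- typical_cl(th, data.frame(egfr = 100, wt = wt, mannitol = FALSE))
  expect_true(all(diff(cl) > 0))
})

test_that("typical_cl validates its covariate inputs", {
  expect_error(typical_cl(theta_final(), data.frame(egfr = 90, wt = 70)),
               "mannitol")
  expect_error(typical_cl(theta_final(),
                          data.frame(egfr = -5, wt = 70, mannitol = FALSE)),
               "positive")
  expect_error(theta_vector(cl_tv = 8, beta_cont = c(egfr = 0.8)),
               "centering")
})

test_that("individual clearance applies the log-normal random effect", {
  expect_equal(individual_cl(7.98, 0), 7.98)
  expect_equal(individual_cl(7.98, log(2)), 15.96)
  expect_equal(individual_cl(7.2952, -0.2), 5.9728046, tolerance = 1e-6)
  expect_error(individual_cl(-1, 0), "positive")
})

test_that("concentration handles empty schedules and pre-dose times", {
  expect_equal(concentration(NULL, 8, 60.2, c(0, 5, 10)), c(0, 0, 0))
  d <- regimen_doses(1000, 12, 5)
  expect_equal(concentration(d, 8, 60.2, 0), 0)  # infusion not yet started
  expect_error(concentration(d, -8, 60.2, 1), "positive")
  expect_error(concentration(d, 8, 60.2, -1), "non-negative")
})

test_that("concentration is linear in dose amounts", {
  d <- regimen_doses(1000, 12, 8)
  d2 <- d; d2$amt <- 2 * d2$amt
  t <- c(0.5, 1, 6, 12.5, 50, 90)
  expect_equal(concentration(d2, 7.98, 60.2, t),
               2 * concentration(d, 7.98, 60.2, t))
})

test_that("closed-form superposition agrees with a numerical ODE oracle", {
  skip_if_not_installed("deSolve")
  set.seed(7)
  for (rep in 1:4) {
    nd <- sample(3:20, 1)
    doses <- dose_events(start_time = cumsum(runif(nd, 2, 14)) - 2,
                         amount = sample(c(250, 500, 1000), nd, TRUE),
                         duration = runif(nd, 0.5, 2.5))
    cl <- runif(1, 1, 15); v <- runif(1, 30, 90)
    times <- sort(runif(8, 1, max(doses$time) + 24))
    got <- concentration(doses, cl, v, times)
    ref <- ode_conc(doses, cl, v, times)
    expect_equal(got, ref, tolerance = 1e-6)
  }
})

test_that("steady-state AUC24 equals daily dose over clearance and matches quadrature", {
  expect_equal(auc24_steady_state(1000, 1000), 1)
  expect_equal(auc24_steady_state(2900, 7.2952), 397.52, tolerance = 1e-4)
  # trapezoidal integral of the simulated steady-state profile over one
  # 24-h window agrees to < 0.5%
  cl <- 7.98; v <- 60.2
  d <- regimen_doses(1000, 12, 40)
  tt <- seq(36 * 12, 36 * 12 + 24, by = 0.01)
  cc <- concentration(d, cl, v, tt)
  trap <- sum((cc[-1] + cc[-length(cc)]) / 2 * diff(tt))
  expect_equal(trap, auc24_steady_state(2000, cl), tolerance = 0.005)
})

test_that("trough approaches the geometric-series steady state", {
  cl <- 7.98; v <- 60.2; k <- cl / v
  d <- regimen_doses(1000, 12, 60)
  trough_late <- concentration(d, cl, v, 59 * 12)
  ss <- 1000 / cl * (1 - exp(-k * 1)) * exp(-k * 11) / (1 - exp(-k * 12))
  expect_equal(trough_late, ss, tolerance = 1e-6)
})
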