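test_that("cohort generation is deterministic under a fixed seed", {
  a <- generate_cohort(cohort_config(n_subjects = 25, seed = 9))
  b <- generate_cohort(cohort_config(n_subjects = 25, seed = 9))
  expect_identical(a, b)
  c1 <- generate_cohort(cohort_config(n_subjects = 1, seed = 3))
  expect_equal(n_subjects(c1), 1)
  expect_gte(nrow(c1$obs), 1)
})

test_that("generated covariate marginals match the cohort summary targets", {
  co <- generate_cohort(cohort_config(n_subjects = 5000, seed = 21))
  cv <- co$covariates
  n <- nrow(cv)
  # three standard errors of the stated mean/SD targets
  expect_lt(abs(mean(cv$age) - 52.41), 3 * 15.11 / sqrt(n) + 0.15)
  expect_lt(abs(mean(cv$wt) - 69.74), 1)          # stated example tolerance
  expect_lt(abs(mean(cv$ht) - 167.88), 3 * 7.98 / sqrt(n) + 0.1)
  expect_lt(abs(mean(cv$egfr) - 112.74), 3 * 30.91 / sqrt(n) + 0.1)
  expect_lt(abs(sd(cv$egfr) - 30.91), 3 * 30.91 / sqrt(2 * n) + 0.3)
  p3 <- function(p) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(cv$mannitol) - 0.6032), p3(0.6032))
  expect_lt(abs(mean(cv$meropenem) - 0.7132), p3(0.7132))
  expect_lt(abs(mean(cv$diuretics) - 0.1595), p3(0.1595))
  expect_lt(abs(mean(cv$rrt) - 0.0272), p3(0.0272))
  expect_lt(abs(mean(cv$sex == "male") - 370 / 560), p3(370 / 560))
  # covariate invariants
  expect_true(all(cv$age >= 18 & cv$age <= 89))
  expect_true(all(cv$scr > 0))
  expect_true(all(abs(cv$bmi - cv$wt / (cv$ht / 100)^2) < 0.5))
})

test_that("mannitol frequency at the study size matches the cohort table", {
  co <- generate_cohort(cohort_config(n_subjects = 560, seed = 8))
  expect_lt(abs(mean(co$covariates$mannitol) - 0.6032), 0.05)
})

test_that("design couples dose to renal function and is trough-dominated", {
  co <- generate_cohort(cohort_config(n_subjects = 2000, seed = 31))
  d1 <- co$doses[!duplicated(co$doses$id), ]
  daily <- d1$amt * 24 / d1$interval
  egfr <- co$covariates$egfr[match(d1$id, co$covariates$id)]
  expect_gt(cor(daily, egfr, method = "spearman"), 0.3)
  # all seven regimens in use
  expect_equal(nrow(unique(co$doses[, c("amt", "interval")])), 7)
  expect_gt(mean(co$obs$trough), 0.88)
  # troughs sit immediately before a dose, after at least five of them
  tr <- co$obs[co$obs$trough, ]
  m <- tr$time / d1$interval[match(tr$id, d1$id)]
  expect_true(all(abs(m - round(m)) < 1e-9) && all(round(m) >= 5))
})

test_that("degenerate noise reproduces model predictions exactly", {
  co <- generate_cohort(cohort_config(n_subjects = 12, seed = 5))
  sim <- simulate_observations(co, theta_final(), 0, sigma_pair(0, 0),
                               seed = 1, max_resample = 0)
  truth <- attr(sim, "truth")
  expect_equal(truth$eta, rep(0, 12))
  for (i in co$covariates$id) {
    d <- sim$doses[sim$doses$id == i, ]
    o <- sim$obs[sim$obs$id == i, ]
    cl <- truth$cl[truth$id == i]
    expect_equal(o$dv, concentration(d, cl, 60.2, o$time))
  }
})

test_that("combined residual error has the correct limiting behaviour", {
  sig <- final_sigma()
  expect_equal(residual_sd(0, sig), 1.51)           # additive floor
  expect_equal(residual_sd(1e6, sig) / 1e6, 0.25,   # proportional CV limit
               tolerance = 1e-6)
  expect_equal(residual_sd(10, sig), sqrt(1.51^2 + 2.5^2))
})

test_that("simulated observations are reproducible and stay in range", {
  co <- generate_cohort(cohort_config(n_subjects = 80, seed = 13))
  s1 <- simulate_observations(co, theta_final(), 0.2145, final_sigma(),
                              seed = 99)
  s2 <- simulate_observations(co, theta_final(), 0.2145, final_sigma(),
                              seed = 99)
  expect_identical(s1$obs, s2$obs)
  ok <- !s1$obs$blq & !s1$obs$aloq
  expect_true(all(s1$obs$dv[ok] > 0.67 & s1$obs$dv[ok] < 90))
  # per-subject random effects follow the requested spread
  tr <- attr(s1, "truth")
  expect_lt(abs(sd(tr$eta) - 0.2145), 3 * 0.2145 / sqrt(2 * 80))
})
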