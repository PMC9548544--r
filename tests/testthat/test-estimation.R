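test_that("degenerate OFV reduces to the fixed-effects Gaussian deviance", {
  cov <- data.frame(id = 1L, age = 50, sex = "male", female = FALSE,
                    wt = 70, ht = 170, bmi = 70 / 1.7^2, scr = 0.9,
                    egfr = ckd_epi(50, "male", 0.9),
                    clcr = cockcroft_gault(50, "male", 70, 0.9),
                    rrt = FALSE, mannitol = FALSE, meropenem = FALSE,
                    diuretics = FALSE)
  doses <- data.frame(id = 1L, time = c(0, 12), amt = 1000, dur = 1,
                      interval = 12)
  obs <- data.frame(id = 1L, time = 11.5, dv = 9.2, blq = FALSE,
                    aloq = FALSE)
  et <- event_table(cov, doses, obs)
  th <- theta_vector(cl_tv = 8, v_fixed = 60.2)
  spec <- model_spec()
  s2 <- 1.4
  f <- concentration(doses, 8, 60.2, 11.5)
  expected <- log(s2^2) + (9.2 - f)^2 / s2^2
  expect_equal(neg2ll(spec, th, 0, sigma_pair(0, s2), et), expected)
  # omega -> 0 is continuous with the degenerate case
  expect_equal(neg2ll(spec, th, 1e-9, sigma_pair(0, s2), et), expected,
               tolerance = 1e-4)
  expect_error(neg2ll(spec, th, 0.2, sigma_pair(0, 0), et), "zero")
})

test_that("Laplace OFV matches Gauss-Hermite quadrature on the toy fixture", {
  et <- toy_event_table()
  spec <- final_model_spec()
  got <- neg2ll(spec, theta_final(), 0.2145, toy_sigma(), et)
  ref <- gh_ofv(spec, theta_final(), 0.2145, toy_sigma(), et,
                n_nodes = 10000)
  expect_lt(abs(got - ref), 0.1)
  # the Laplace error shrinks as the random-effect variance shrinks
  errs <- vapply(c(0.4, 0.2, 0.05), function(om) {
    abs(neg2ll(spec, theta_final(), om, toy_sigma(), et) -
          gh_ofv(spec, theta_final(), om, toy_sigma(), et, 2000))
  }, numeric(1))
  expect_lt(errs[1], 0.5)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.02)
})

test_that("OFV is invariant to subject ordering", {
  sim <- final_model_sim(n = 40, cohort_seed = 2, sim_seed = 3)
  perm <- c(25:40, 1:24)
  shuffled <- event_table(sim$covariates[perm, ], sim$doses, sim$obs)
  spec <- final_model_spec()
  expect_lt(abs(neg2ll(spec, theta_final(), 0.2145, final_sigma(), sim) -
                  neg2ll(spec, theta_final(), 0.2145, final_sigma(),
                         shuffled)),
            1e-6)
})

test_that("noise-free data identify the typical clearance almost exactly", {
  co <- generate_cohort(cohort_config(n_subjects = 40, seed = 17))
  sim <- simulate_observations(co, theta_base(), 0, sigma_pair(0, 0.01),
                               seed = 18, max_resample = 0)
  f <- suppressWarnings(
    fit_ppk(model_spec(), sim,
            init = list(fixed = 7, omega = 0.1, sigma = sigma_pair(0.05, 0.1)),
            control = fit_control(se = FALSE)))
  expect_lt(abs(f$theta$cl_tv - 8.08) / 8.08, 0.001)
})

test_that("fitting the generating model recovers its parameters", {
  sim <- final_model_sim(n = 250, cohort_seed = 42, sim_seed = 43)
  f <- suppressWarnings(fit_ppk(final_model_spec(), sim))
  expect_true(f$converged)
  est <- setNames(f$estimates$estimate, f$estimates$parameter)
  expect_lt(abs(est["cl_tv"] - 7.98), 0.5)
  expect_lt(abs(est["beta_egfr"] - 0.80), 0.15)
  expect_true(f$shrinkage$eta >= 0 && f$shrinkage$eta <= 1)
  expect_true(f$shrinkage$eps >= 0 && f$shrinkage$eps <= 1)
  tab <- f$estimates
  ok <- !is.na(tab$se)
  expect_equal(tab$rse_percent[ok],
               100 * tab$se[ok] / abs(tab$estimate[ok]))
  expect_equal(tab$ci_hi[ok] - tab$estimate[ok], 1.96 * tab$se[ok])
  # adding the data-generating covariate always improves the fit
  f0 <- suppressWarnings(fit_ppk(model_spec(), sim,
                                 control = fit_control(se = FALSE)))
  expect_lt(f$ofv, f0$ofv - 50)
})

test_that("CWRES reduces to scaled residuals in the degenerate case", {
  cov <- data.frame(id = 1:2, age = 50, sex = "male", female = FALSE,
                    wt = 70, ht = 170, bmi = 70 / 1.7^2, scr = 0.9,
                    egfr = ckd_epi(50, "male", 0.9),
                    clcr = cockcroft_gault(50, "male", 70, 0.9),
                    rrt = FALSE, mannitol = FALSE, meropenem = FALSE,
                    diuretics = FALSE)
  doses <- do.call(rbind, lapply(1:2, function(i)
    data.frame(id = i, time = seq(0, 48, by = 12), amt = 1000, dur = 1,
               interval = 12)))
  obs <- data.frame(id = c(1L, 2L, 2L), time = c(47.9, 24, 36),
                    dv = c(7.7, 10.1, 5.3), blq = FALSE, aloq = FALSE)
  et <- event_table(cov, doses, obs)
  spec <- model_spec()
  fit <- fake_fit(spec, theta_vector(8, 60.2), 0, sigma_pair(0, 2), et)
  res <- cwres(fit, et)
  expect_equal(res$cwres, (res$dv - res$pred) / 2)
  expect_equal(res$pred, res$ipred)
})

test_that("CWRES are calibrated under the generating model and flag misfit", {
  sim <- final_model_sim(n = 250, cohort_seed = 42, sim_seed = 43)
  f_true <- suppressWarnings(fit_ppk(final_model_spec(), sim,
                                     control = fit_control(se = FALSE)))
  r_true <- cwres(f_true, sim)
  expect_lt(abs(mean(r_true$cwres)), 0.15)
  expect_true(sd(r_true$cwres) > 0.85 && sd(r_true$cwres) < 1.15)
  # omitting the dominant covariate leaves structure in the residuals
  f_mis <- suppressWarnings(
    fit_ppk(model_spec(cont = c(wt = 70), cat = "mannitol"), sim,
            control = fit_control(se = FALSE)))
  r_mis <- cwres(f_mis, sim)
  egfr <- sim$covariates$egfr[match(r_mis$id, sim$covariates$id)]
  egfr_t <- sim$covariates$egfr[match(r_true$id, sim$covariates$id)]
  expect_gt(abs(cor(r_mis$cwres, log(egfr))),
            abs(cor(r_true$cwres, log(egfr_t))))
})
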