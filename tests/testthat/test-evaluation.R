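test_that("bootstrap resampling preserves subject count and is seeded", {
  sim <- final_model_sim(n = 40, cohort_seed = 61, sim_seed = 62)
  spec <- final_model_spec()
  ref <- suppressWarnings(fit_ppk(spec, sim,
                                  control = fit_control(se = FALSE)))
  b1 <- suppressWarnings(bootstrap_ppk(spec, sim, n_boot = 2, seed = 7,
                                       ref_fit = ref))
  b2 <- suppressWarnings(bootstrap_ppk(spec, sim, n_boot = 2, seed = 7,
                                       ref_fit = ref))
  expect_identical(b1$replicates, b2$replicates)
  expect_equal(b1$n_requested, 2)
  expect_s3_class(b1, "ppk_bootstrap")
  # a with-replacement resample keeps the subject count, renumbered
  set.seed(1)
  take <- sample(sim$covariates$id, 40, replace = TRUE)
  rs <- vancoppk:::resample_subjects(sim, take)
  expect_equal(n_subjects(rs), 40)
  expect_false(anyDuplicated(rs$covariates$id) > 0)
  expect_equal(nrow(rs$obs),
               sum(table(factor(sim$obs$id, sim$covariates$id))[
                 as.character(take)]))
})

test_that("bootstrap intervals widen when inter-individual variability doubles", {
  spec <- final_model_spec()
  widths <- sapply(c(0.15, 0.30), function(om) {
    sim <- final_model_sim(n = 60, cohort_seed = 63, sim_seed = 64,
                           omega = om)
    ref <- suppressWarnings(fit_ppk(spec, sim,
                                    control = fit_control(se = FALSE)))
    b <- suppressWarnings(bootstrap_ppk(spec, sim, n_boot = 20, seed = 5,
                                        ref_fit = ref))
    s <- b$summary
    s$ci_hi[s$parameter == "cl_tv"] - s$ci_lo[s$parameter == "cl_tv"]
  })
  expect_gt(widths[2], widths[1])
})

test_that("VPC degenerates sensibly", {
  sim <- final_model_sim(n = 30, cohort_seed = 65, sim_seed = 66)
  fit <- fake_fit(final_model_spec(), theta_final(), 0.2145, final_sigma(),
                  sim)
  v1 <- vpc_ppk(fit, sim, n_sim = 1, seed = 2)
  expect_s3_class(v1, "ppk_vpc")
  expect_true(all(v1$bins$sim_p5 <= v1$bins$sim_p50 &
                    v1$bins$sim_p50 <= v1$bins$sim_p95))
  # noiseless model + noiseless data: every simulation equals PRED and
  # every observation sits exactly on it
  sim0 <- simulate_observations(sim, theta_final(), 0, sigma_pair(0, 0),
                                seed = 3, max_resample = 0)
  fit0 <- fake_fit(final_model_spec(), theta_final(), 0, sigma_pair(0, 0),
                   sim0)
  v0 <- vpc_ppk(fit0, sim0, n_sim = 5, seed = 4)
  expect_equal(v0$coverage, 1)
  expect_equal(v0$obs$sim_lo, v0$obs$sim_hi)
  # noisy observations against a noiseless model: the interval is a point
  # the data never hit
  fitn <- fake_fit(final_model_spec(), theta_final(), 0, sigma_pair(0, 0),
                   sim)
  vn <- vpc_ppk(fitn, sim, n_sim = 5, seed = 4)
  expect_equal(vn$coverage, 0)
})

test_that("VPC coverage is near nominal under the true model", {
  sim <- final_model_sim(n = 150, cohort_seed = 67, sim_seed = 68)
  fit <- fake_fit(final_model_spec(), theta_final(), 0.2145, final_sigma(),
                  sim)
  v <- vpc_ppk(fit, sim, n_sim = 100, seed = 5)
  expect_gt(v$coverage, 0.80)
  expect_lt(v$coverage, 0.98)
  expect_equal(sum(v$bins$n_obs), nrow(v$obs))
})
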