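test_that("forward step with no candidates is a no-op", {
  sim <- final_model_sim(n = 30, cohort_seed = 51, sim_seed = 52)
  st <- suppressWarnings(
    forward_step(model_spec(), covariate_candidates()[0, ], sim))
  expect_false(st$record$accepted)
  expect_identical(st$record$delta_ofv, 0)
  expect_length(st$spec$cont, 0)
})

test_that("a lone generating covariate is selected and retained", {
  sim <- final_model_sim(
    n = 120, cohort_seed = 53, sim_seed = 54,
    theta = theta_vector(7.98, 60.2, beta_cont = c(egfr = 0.8),
                         centering = c(egfr = 115.2)))
  cand <- data.frame(name = "egfr", kind = "continuous")
  sw <- suppressWarnings(run_stepwise(model_spec(), cand, sim))
  expect_identical(names(sw$spec$cont), "egfr")
  # backward elimination kept it: removal raises OFV far beyond 10.83
  back <- sw$steps[sw$steps$action == "remove", ]
  expect_false(back$accepted)
  expect_gt(back$delta_ofv, 10.83)
})

test_that("a pure-noise covariate is eliminated backward", {
  sim <- final_model_sim(
    n = 120, cohort_seed = 55, sim_seed = 56,
    theta = theta_vector(7.98, 60.2, beta_cont = c(egfr = 0.8),
                         centering = c(egfr = 115.2)))
  spec <- model_spec(cont = c(egfr = 115.2), cat = "meropenem")
  st <- suppressWarnings(backward_step(spec, sim))
  expect_true(st$record$accepted)
  expect_identical(st$record$covariate, "meropenem")
  expect_identical(in_model_names <- c(names(st$spec$cont), st$spec$cat),
                   "egfr")
})

test_that("forward phase is greedy, monotone and renal-exclusive", {
  sim <- final_model_sim(n = 150, cohort_seed = 57, sim_seed = 58)
  sw <- suppressWarnings(
    run_stepwise(model_spec(), covariate_candidates(), sim))
  acc <- sw$steps[sw$steps$action == "add" & sw$steps$accepted, ]
  # OFV decreases along accepted forward steps
  expect_true(all(diff(c(acc$ofv_before[1], acc$ofv_after)) < 0))
  expect_identical(acc$covariate[1], "egfr")
  # once a renal proxy is in, the others never re-enter the pool
  after_first <- sw$log[sw$log$model > 13 & sw$log$phase == "forward", ]
  expect_false(any(grepl("add (scr|clcr) ", after_first$description)))
})
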