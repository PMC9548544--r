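test_that("AUC24 simulation collapses to the closed form when omega = 0", {
  sc <- dose_scenario(90, 65, TRUE, n_sim = 200, seed = 1)
  out <- simulate_auc24(sc, 1450, theta_final(), 0)
  expect_equal(out$median, 2900 / 7.2952, tolerance = 1e-4)
  expect_equal(out$lo5, out$hi95)
  expect_equal(unique(out$draws), out$median)
})

test_that("AUC24 draws scale exactly linearly in dose at matched seed", {
  sc <- dose_scenario(45, 85, TRUE, n_sim = 500, seed = 4)
  a <- simulate_auc24(sc, 900, theta_final(), 0.2145)
  b <- simulate_auc24(sc, 1800, theta_final(), 0.2145)
  expect_equal(b$draws, 2 * a$draws)
})

test_that("Monte Carlo median and interval follow the log-normal theory", {
  om <- 0.2145
  for (cfg in list(c(egfr = 90, wt = 65, dose = 1450),
                   c(egfr = 15, wt = 65, dose = 350))) {
    sc <- dose_scenario(cfg["egfr"], cfg["wt"], TRUE, n_sim = 1000,
                        seed = 6)
    cl <- typical_cl(theta_final(),
                     data.frame(egfr = cfg["egfr"], wt = cfg["wt"],
                                mannitol = TRUE))
    closed <- unname(2 * cfg["dose"] / cl)
    out <- simulate_auc24(sc, cfg["dose"], theta_final(), om)
    # median-of-lognormal standard error bound
    expect_lt(abs(out$median - closed),
              3 * 1.2533 * om / sqrt(1000) * closed)
    expect_equal(out$lo5, closed * exp(-1.6449 * om), tolerance = 0.05)
    expect_equal(out$hi95, closed * exp(1.6449 * om), tolerance = 0.05)
  }
})

test_that("dose recommendation snaps to the grid and hits the target", {
  sc <- dose_scenario(90, 65, TRUE, n_sim = 1000, seed = 3,
                      target_auc = 400)
  rec <- recommend_dose(sc, theta_final(), 0.2145)
  closed_dose <- 400 * 7.2952 * 12 / 24
  expect_lt(abs(rec$dose - closed_dose), 25)
  expect_lt(abs(rec$median_auc24 - 400) / 400, 0.01)
  expect_false(rec$intraventricular_advisory)
  # the 400 -> 600 target ratio is 1.5 up to grid rounding
  sc6 <- dose_scenario(90, 65, TRUE, n_sim = 1000, seed = 3,
                       target_auc = 600)
  rec6 <- recommend_dose(sc6, theta_final(), 0.2145)
  expect_lt(abs(rec6$dose - 1.5 * rec$dose), 2 * sc$dose_grid_step + 1e-9)
})

test_that("median ties resolve to the smaller dose", {
  # omega = 0 and cl chosen so the target falls exactly midway between
  # two grid doses: 400 * 0.5125 / 2 = 102.5
  th <- theta_vector(cl_tv = 0.5125, v_fixed = 60.2)
  sc <- dose_scenario(90, 65, FALSE, n_sim = 50, seed = 1,
                      target_auc = 400)
  rec <- recommend_dose(sc, th, 0)
  expect_equal(rec$dose, 100)
})

test_that("the dose table is monotone in renal function, weight and mannitol", {
  tab <- build_dose_table(theta_final(), 0.2145, n_sim = 400, seed = 11)
  expect_equal(nrow(tab), 24)
  expect_lt(max(abs(tab$median_auc24 - tab$target_auc) / tab$target_auc),
            0.05)
  key <- function(egfr, wt, mann, target)
    tab$dose[tab$egfr == egfr & tab$wt == wt & tab$mannitol == mann &
               tab$target_auc == target]
  for (target in c(400, 600)) for (mann in c(TRUE, FALSE)) {
    for (wt in c(65, 85))
      expect_true(all(diff(sapply(c(15, 45, 90), key, wt = wt,
                                  mann = mann, target = target)) > 0))
    for (egfr in c(15, 45, 90))
      expect_gte(key(egfr, 85, mann, target), key(egfr, 65, mann, target))
  }
  for (target in c(400, 600)) for (wt in c(65, 85))
    for (egfr in c(15, 45, 90))
      expect_gte(key(egfr, wt, TRUE, target), key(egfr, wt, FALSE, target))
  expect_identical(tab$advisory, tab$dose > 2000)
})
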