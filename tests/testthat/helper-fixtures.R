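# shared fixtures and independent oracles

final_model_spec <- function() {
  model_spec(cont = c(egfr = 115.2, wt = 70), cat = "mannitol")
}

final_sigma <- function() sigma_pair(0.25, 1.51)

# generate a cohort and simulate observations from the published final model
final_model_sim <- function(n = 200, cohort_seed = 1, sim_seed = 2,
                            theta = theta_final(), omega = 0.2145,
                            sigma = final_sigma(), ...) {
  co <- generate_cohort(cohort_config(n_subjects = n, seed = cohort_seed))
  simulate_observations(co, theta, omega, sigma, seed = sim_seed, ...)
}

# residual magnitudes used with the toy fixture: informative (low-noise)
# sampling keeps the subject-level posteriors sharp, so a quadrature
# cross-check probes the implementation rather than the size of the
# one-point Laplace approximation error
toy_sigma <- function() sigma_pair(0.1, 0.4)

# hand-built five-subject fixture with deterministic concentrations:
# observation values were generated once from the final model (random
# effects and combined noise at toy_sigma()) and frozen, so the likelihood
# oracle comparison is exactly reproducible
toy_event_table <- function() {
  age <- c(40, 55, 62, 35, 70)
  sex <- c("male", "female", "male", "male", "female")
  wt <- c(70, 62, 85, 95, 55)
  ht <- c(172, 160, 178, 183, 155)
  scr <- c(0.8, 0.7, 1.1, 0.6, 1.4)
  covariates <- data.frame(
    id = 1:5, age = age, sex = sex, female = sex == "female",
    wt = wt, ht = ht, bmi = wt / (ht / 100)^2, scr = scr,
    egfr = ckd_epi(age, sex, scr),
    clcr = cockcroft_gault(age, sex, wt, scr),
    rrt = FALSE, mannitol = c(TRUE, FALSE, TRUE, FALSE, TRUE),
    meropenem = c(TRUE, TRUE, FALSE, TRUE, FALSE), diuretics = FALSE)
  amt <- c(1000, 500, 1000, 1000, 500)
  tau <- c(12, 12, 8, 12, 24)
  doses <- do.call(rbind, lapply(1:5, function(i)
    data.frame(id = i, time = seq(0, by = tau[i], length.out = 8),
               amt = amt[i], dur = 1, interval = tau[i])))
  times <- list(c(0.5, 1, 2, 6, 12.5, 24, 47.9, 60),
                c(1, 4, 12, 24, 47.9, 72),
                c(0.5, 2, 8.5, 16, 24, 40),
                c(1, 6, 12, 24, 36, 47.9),
                c(2, 12, 24, 48, 72, 95.9))
  dv <- list(c(6.986, 15.877, 11.394, 4.425, 10.798, 1.199, 2.206, 1.998),
             c(8.244, 7.52, 3.298, 3.629, 4.511, 4.722),
             c(9.003, 15.648, 16.984, 13.501, 11.646, 16.759),
             c(15.725, 7.946, 3.285, 2.967, 3.424, 3.169),
             c(8.367, 4.905, 2.711, 3.411, 3.611, 4.604))
  obs <- do.call(rbind, lapply(1:5, function(i)
    data.frame(id = i, time = times[[i]], dv = dv[[i]],
               blq = FALSE, aloq = FALSE)))
  event_table(covariates, doses, obs)
}

# Gauss-Hermite quadrature oracle for the marginal -2 log likelihood,
# constant-free convention (drops n_obs * log(2*pi) per subject); shares
# only the closed-form concentration model with the production path --
# the integration method is entirely independent of the Laplace code
gh_ofv <- function(spec, theta, omega, sigma, data, n_nodes = 10000) {
  gh <- gauss_hermite(n_nodes)
  cov <- data$covariates
  tv <- typical_cl(theta, cov)
  total <- 0
  for (i in seq_along(cov$id)) {
    d <- data$doses[data$doses$id == cov$id[i], , drop = FALSE]
    o <- data$obs[data$obs$id == cov$id[i] & !data$obs$blq &
                    !data$obs$aloq & !is.na(data$obs$dv), , drop = FALSE]
    if (!nrow(o)) next
    if (omega > 0) {
      loglik <- vapply(gh$nodes, function(x) {
        f <- concentration(d, tv[i] * exp(sqrt(2) * omega * x),
                           theta$v_fixed, o$time)
        sum(dnorm(o$dv, f, residual_sd(f, sigma), log = TRUE))
      }, numeric(1))
      lw <- log(gh$weights) + loglik
      m <- max(lw)
      log_int <- m + log(sum(exp(lw - m))) - 0.5 * log(pi)
    } else {
      f <- concentration(d, tv[i], theta$v_fixed, o$time)
      log_int <- sum(dnorm(o$dv, f, residual_sd(f, sigma), log = TRUE))
    }
    total <- total - 2 * log_int - nrow(o) * log(2 * pi)
  }
  total
}

# numerical ODE oracle for the one-compartment infusion model: integrates
# dA/dt = R(t) - k A segment by segment with lsoda, restarting at every
# infusion start/end so the discontinuous input is handled exactly
ode_conc <- function(doses, cl, v, times) {
  k <- cl / v
  brk <- sort(unique(c(0, doses$time, doses$time + doses$dur, times)))
  rate_at <- function(t) {
    sum(doses$amt / doses$dur * (doses$time <= t & t < doses$time + doses$dur))
  }
  amt <- 0
  out <- setNames(numeric(length(times)), as.character(times))
  for (s in seq_len(length(brk) - 1)) {
    t0 <- brk[s]; t1 <- brk[s + 1]
    rate <- rate_at((t0 + t1) / 2)  # constant within a segment
    seg_t <- unique(c(t0, times[times > t0 & times <= t1], t1))
    sol <- deSolve::lsoda(
      c(A = amt), seg_t,
      function(t, y, p) list(rate - k * y[1]),
      NULL, rtol = 1e-12, atol = 1e-12)
    for (tt in seg_t[-1])
      if (tt %in% times) out[as.character(tt)] <- sol[sol[, 1] == tt, 2] / v
    amt <- sol[nrow(sol), 2]
  }
  unname(out[as.character(times)])
}

# minimal fit-like object for evaluation-stage functions that only need
# the parameter values (e.g. VPC under known true parameters)
fake_fit <- function(spec, theta, omega, sigma, data) {
  structure(list(spec = spec, theta = theta, omega_cl = omega,
                 sigma = sigma, converged = TRUE,
                 eta = data.frame(id = data$covariates$id, eta = 0)),
            class = "ppk_fit")
}
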