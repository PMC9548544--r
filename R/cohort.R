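#' Event table: doses, observations and covariates for a cohort
#'
#' The central data container. Three aligned data frames:
#' `covariates` (one row per subject: `id`, `age`, `sex`, `wt`, `ht`, `bmi`,
#' `scr` (mg/dL), `egfr`, `clcr`, and logical flags `rrt`, `mannitol`,
#' `meropenem`, `diuretics`), `doses` (`id`, `time`, `amt`, `dur`,
#' `interval`) and `obs` (`id`, `time`, `dv`, `blq`, `aloq`). Times are
#' hours from each subject's first dose; concentrations mg/L; doses mg.
#'
#' @param covariates,doses,obs see Description.
#' @return object of class `event_table`.
#' @export
event_table <- function(covariates, doses, obs) {
  stopifnot(is.data.frame(covariates), is.data.frame(doses),
            is.data.frame(obs))
  if (anyDuplicated(covariates$id))
    stop("duplicate subject ids in covariates")
  if (!all(doses$id %in% covariates$id) || !all(obs$id %in% covariates$id))
    stop("dose/observation ids not present in covariates")
  if (nrow(obs) && any(obs$time < 0))
    stop("observation times must be >= first dose time (0)")
  if (is.null(obs$blq)) obs$blq <- FALSE
  if (is.null(obs$aloq)) obs$aloq <- FALSE
  miss <- setdiff(covariates$id, unique(obs$id))
  if (length(miss))
    warning(length(miss), " subject(s) without observations")
  structure(list(covariates = covariates,
                 doses = doses[order(doses$id, doses$time), , drop = FALSE],
                 obs = obs[order(obs$id, obs$time), , drop = FALSE]),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat("<event_table> ", nrow(x$covariates), " subjects, ",
      nrow(x$obs), " observations, ", nrow(x$doses), " dose events\n",
      sep = "")
  invisible(x)
}

#' Number of subjects in an event table
#' @param x an [event_table()].
#' @export
n_subjects <- function(x) nrow(x$covariates)

# inverse-CDF truncated normal: draw count is deterministic, which keeps
# seeded streams stable when configs change elsewhere
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  if (plo >= phi) stop("infeasible truncation bounds")
  qnorm(runif(n, plo, phi), mean, sd)
}

with_preserved_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Configuration of the synthetic neurosurgical cohort
#'
#' Defaults emulate the therapeutic-drug-monitoring cohort the model was
#' built on: 560 adults, about two thirds male, age 52 +/- 15 y, body
#' weight 70 +/- 13 kg, height 168 +/- 8 cm; renal function mostly normal
#' to augmented (overall eGFR ~113 +/- 31 mL/min) with a small dialysis
#' (RRT) tail; mannitol in 60.3%, meropenem in 71.3%, diuretics in 16.0%,
#' RRT in 2.7%. Dosing uses the seven regimens in clinical use (0.5 or 1 g
#' per administration at 6-24 h intervals, 1-h infusions), assigned by eGFR
#' band so that the dose/renal-function confounding of real practice is
#' present. Sampling is trough-dominated: most observations are steady-state
#' troughs drawn immediately before a dose after at least five
#' administrations, the rest random post-infusion samples. The assay
#' calibration range is 0.67-90 mg/L.
#'
#' The creatinine marginal is induced, not sampled directly: a target eGFR
#' is drawn (normal for non-RRT subjects, calibrated so the overall mixture
#' matches the cohort mean/SD; a low tail for RRT subjects) and inverted
#' through CKD-EPI given age and sex, which yields a right-skewed
#' creatinine distribution and couples creatinine to age and sex.
#'
#' @param n_subjects cohort size.
#' @param seed integer RNG seed.
#' @param p_male probability of male sex (370/560).
#' @param age,wt,ht lists with `mean`, `sd`, `min`, `max` (truncated
#'   normals).
#' @param egfr non-RRT target eGFR distribution (`mean`, `sd`, `min`,
#'   `max`), calibrated so the RRT mixture reproduces 112.74 +/- 30.91.
#' @param rrt_egfr target eGFR distribution for RRT subjects.
#' @param p_rrt,p_mannitol,p_meropenem,p_diuretics co-medication /
#'   RRT probabilities.
#' @param trough_frac fraction of observations scheduled as steady-state
#'   troughs (the study design is trough-dominated; the exact fraction is
#'   a design knob).
#' @param obs_geom_p success probability of the geometric-like
#'   observations-per-subject law `1 + Geom(p)`; 0.625 gives the study's
#'   mean of ~1.6 observations per subject.
#' @param obs_max cap on observations per subject.
#' @param lloq,uloq assay quantification limits, mg/L.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 560, seed = 1,
                          p_male = 370 / 560,
                          age = list(mean = 52.41, sd = 15.11, min = 18, max = 89),
                          wt = list(mean = 69.74, sd = 13.05, min = 37.5, max = 130),
                          ht = list(mean = 167.88, sd = 7.98, min = 145, max = 192),
                          egfr = list(mean = 115.56, sd = 26.24, min = 25, max = 244.5),
                          rrt_egfr = list(mean = 12, sd = 5, min = 3.5, max = 30),
                          p_rrt = 0.0272, p_mannitol = 0.6032,
                          p_meropenem = 0.7132, p_diuretics = 0.1595,
                          trough_frac = 0.92, obs_geom_p = 0.625,
                          obs_max = 6, lloq = 0.67, uloq = 90) {
  stopifnot(n_subjects >= 1)
  probs <- c(p_male, p_rrt, p_mannitol, p_meropenem, p_diuretics,
             trough_frac, obs_geom_p)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  for (d in list(age, wt, ht, egfr, rrt_egfr))
    if (d$min >= d$max) stop("distribution bounds must satisfy min < max")
  structure(as.list(environment()), class = "cohort_config")
}

# the seven regimens in clinical use: amount (mg) x interval (h)
.regimens <- data.frame(
  amt = c(1000, 1000, 1000, 500, 500, 500, 500),
  interval = c(24, 12, 8, 24, 12, 8, 6)
)

# eGFR-banded regimen assignment; row indices into .regimens with mixing
# probabilities, emulating clinicians titrating daily dose to renal function
.assign_regimen <- function(egfr, u) {
  pick <- function(lo_idx, hi_idx, p_hi) ifelse(u < p_hi, hi_idx, lo_idx)
  idx <- ifelse(egfr < 20, 4L,                         # 0.5 g Qd
         ifelse(egfr < 40, 5L,                         # 0.5 g Q12h
         ifelse(egfr < 60, pick(1L, 6L, 0.7),          # 1 g Qd / 0.5 g Q8h
         ifelse(egfr < 90, pick(2L, 7L, 0.5),          # 1 g Q12h / 0.5 g Q6h
         ifelse(egfr < 130, pick(2L, 3L, 0.6),         # 1 g Q12h / 1 g Q8h
                pick(2L, 3L, 0.9))))))                 # mostly 1 g Q8h (ARC)
  idx
}

#' Generate a virtual cohort (covariates and dose schedules)
#'
#' Draws demographics, renal function, co-medications, a dosing regimen and
#' an observation-time design per subject. No concentrations are simulated;
#' see [simulate_observations()]. The returned observation table carries
#' `NA` concentrations plus the scheduled sampling times and a `trough`
#' flag.
#'
#' @param config a [cohort_config()].
#' @return an [event_table()] whose `obs$dv` is `NA`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_preserved_seed(config$seed, {
    n <- config$n_subjects
    sex <- ifelse(runif(n) < config$p_male, "male", "female")
    age <- rtruncnorm(n, config$age$mean, config$age$sd,
                      config$age$min, config$age$max)
    wt <- rtruncnorm(n, config$wt$mean, config$wt$sd,
                     config$wt$min, config$wt$max)
    ht <- rtruncnorm(n, config$ht$mean, config$ht$sd,
                     config$ht$min, config$ht$max)
    bmi <- wt / (ht / 100)^2
    rrt <- runif(n) < config$p_rrt
    egfr_target <- numeric(n)
    egfr_target[!rrt] <- rtruncnorm(sum(!rrt), config$egfr$mean,
                                    config$egfr$sd, config$egfr$min,
                                    config$egfr$max)
    if (any(rrt))
      egfr_target[rrt] <- rtruncnorm(sum(rrt), config$rrt_egfr$mean,
                                     config$rrt_egfr$sd,
                                     config$rrt_egfr$min,
                                     config$rrt_egfr$max)
    scr <- ckd_epi_inverse(egfr_target, age, sex)
    egfr <- ckd_epi(age, sex, scr)  # equals egfr_target up to round-trip
    clcr <- suppressMessages(cockcroft_gault(age, sex, wt, scr))
    mannitol <- runif(n) < config$p_mannitol
    meropenem <- runif(n) < config$p_meropenem
    diuretics <- runif(n) < config$p_diuretics
    reg_idx <- .assign_regimen(egfr, runif(n))
    amt <- .regimens$amt[reg_idx]
    tau <- .regimens$interval[reg_idx]

    n_obs <- pmin(1L + rgeom(n, config$obs_geom_p), config$obs_max)
    dose_list <- vector("list", n)
    obs_list <- vector("list", n)
    for (i in seq_len(n)) {
      k_obs <- n_obs[i]
      is_trough <- runif(k_obs) < config$trough_frac
      m_pool <- 5:(4 + max(8, k_obs))
      m <- sample(m_pool, k_obs)  # dose index before which a trough is drawn
      t_obs <- numeric(k_obs)
      t_obs[is_trough] <- m[is_trough] * tau[i]
      if (any(!is_trough)) {
        j <- sample(2:5, sum(!is_trough), replace = TRUE)
        t_obs[!is_trough] <- (j - 1) * tau[i] + 1 + runif(sum(!is_trough), 2, 10)
      }
      n_dose <- max(c(6, m[is_trough] + 1, if (any(!is_trough)) 6))
      dose_list[[i]] <- data.frame(
        id = i, time = seq(0, by = tau[i], length.out = n_dose),
        amt = amt[i], dur = 1, interval = tau[i])
      obs_list[[i]] <- data.frame(id = i, time = t_obs, dv = NA_real_,
                                  blq = FALSE, aloq = FALSE,
                                  trough = is_trough)
    }
    covariates <- data.frame(id = seq_len(n), age = age, sex = sex,
                             female = sex == "female", wt = wt,
                             ht = ht, bmi = bmi, scr = scr, egfr = egfr,
                             clcr = clcr, rrt = rrt, mannitol = mannitol,
                             meropenem = meropenem, diuretics = diuretics)
    event_table(covariates, do.call(rbind, dose_list),
                do.call(rbind, obs_list))
  })
}

#' Residual error magnitudes of the combined error model
#'
#' @param prop multiplicative component (CV, dimensionless), `sigma1`.
#' @param add additive component (SD, mg/L), `sigma2`.
#' @return object of class `sigma_pair`.
#' @export
sigma_pair <- function(prop, add) {
  stopifnot(prop >= 0, add >= 0)
  structure(list(prop = prop, add = add), class = "sigma_pair")
}

#' Residual standard deviation at a predicted concentration
#'
#' Combined error: \eqn{SD(C_{pred}) = \sqrt{\sigma_2^2 +
#' (\sigma_1 C_{pred})^2}} -- the additive SD dominates near zero, the
#' proportional CV at high concentrations.
#'
#' @param cpred predicted concentration(s), mg/L.
#' @param sigma a [sigma_pair()].
#' @export
residual_sd <- function(cpred, sigma) {
  stopifnot(inherits(sigma, "sigma_pair"))
  sqrt(sigma$add^2 + (sigma$prop * cpred)^2)
}

#' Simulate concentration observations for a cohort
#'
#' For each subject draws \eqn{\eta \sim N(0, \omega^2)}, computes the
#' individual clearance under `theta`, evaluates the one-compartment
#' infusion model at the scheduled sampling times and adds combined
#' residual error. Draws outside the assay range are redrawn up to
#' `max_resample` times, then flagged (`blq` below, `aloq` above the
#' range); flagged values keep the last draw.
#'
#' @param cohort an [event_table()] from [generate_cohort()] (or any table
#'   with scheduled observation times).
#' @param theta a [theta_vector()].
#' @param omega_cl SD of the log-normal clearance random effect.
#' @param sigma a [sigma_pair()].
#' @param seed integer seed.
#' @param lloq,uloq assay range, mg/L.
#' @param max_resample redraw budget per observation (0 disables
#'   truncation handling entirely, e.g. for predictive checks that must
#'   mirror the raw model).
#' @return the cohort with `obs$dv` filled in; the true per-subject random
#'   effects and clearances are attached as `attr(, "truth")`.
#' @export
simulate_observations <- function(cohort, theta, omega_cl, sigma, seed = 1,
                                  lloq = 0.67, uloq = 90,
                                  max_resample = 10) {
  stopifnot(inherits(cohort, "event_table"),
            inherits(theta, "theta_vector"), inherits(sigma, "sigma_pair"),
            omega_cl >= 0)
  with_preserved_seed(seed, {
    cov <- cohort$covariates
    tv <- typical_cl(theta, cov)
    eta <- rnorm(nrow(cov), 0, omega_cl)
    cl_i <- individual_cl(tv, eta)
    obs <- cohort$obs
    obs$blq <- FALSE
    obs$aloq <- FALSE
    split_doses <- split(cohort$doses, factor(cohort$doses$id, cov$id))
    split_idx <- split(seq_len(nrow(obs)), factor(obs$id, cov$id))
    for (i in seq_along(cov$id)) {
      idx <- split_idx[[i]]
      if (!length(idx)) next
      cpred <- concentration(split_doses[[i]], cl_i[i], theta$v_fixed,
                             obs$time[idx])
      sdv <- residual_sd(cpred, sigma)
      dv <- cpred + rnorm(length(idx), 0, sdv)
      if (max_resample > 0) {
        for (r in seq_len(max_resample)) {
          out <- dv <= lloq | dv >= uloq
          if (!any(out)) break
          dv[out] <- cpred[out] + rnorm(sum(out), 0, sdv[out])
        }
      }
      obs$dv[idx] <- dv
      obs$blq[idx] <- dv <= lloq
      obs$aloq[idx] <- dv >= uloq
    }
    out <- event_table(cov, cohort$doses, obs)
    attr(out, "truth") <- data.frame(id = cov$id, eta = eta, cl = cl_i,
                                     typical_cl = tv)
    out
  })
}
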