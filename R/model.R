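#' Fixed-effect parameter set for the clearance covariate model
#'
#' The structural clearance model is a product of a typical value, centered
#' power terms for continuous covariates and exponential shifts for
#' categorical covariates:
#' \deqn{CL_{typ} = \theta_{TV} \prod_c (x_c / m_c)^{\beta_c}
#'       \exp\big(\sum_k \beta_k \, z_k\big)}
#' with volume of distribution fixed (it is not estimable from
#' trough-dominated sampling).
#'
#' @param cl_tv population typical clearance, L/h.
#' @param v_fixed volume of distribution, L.
#' @param beta_cont named numeric vector of power exponents for continuous
#'   covariates (names must match covariate columns, e.g. `egfr`, `wt`).
#' @param beta_cat named numeric vector of log-scale shifts for categorical
#'   covariates (e.g. `mannitol`).
#' @param centering named numeric vector of positive centering constants,
#'   one per entry of `beta_cont`.
#' @return object of class `theta_vector`.
#' @export
theta_vector <- function(cl_tv, v_fixed = 60.2,
                         beta_cont = numeric(), beta_cat = numeric(),
                         centering = numeric()) {
  stopifnot(is.numeric(cl_tv), length(cl_tv) == 1L, cl_tv > 0,
            is.numeric(v_fixed), v_fixed > 0)
  if (length(beta_cont) && is.null(names(beta_cont)))
    stop("beta_cont must be named")
  if (length(beta_cat) && is.null(names(beta_cat)))
    stop("beta_cat must be named")
  miss <- setdiff(names(beta_cont), names(centering))
  if (length(miss))
    stop("missing centering constant for: ", paste(miss, collapse = ", "))
  if (length(centering) && any(centering <= 0))
    stop("centering constants must be positive")
  structure(list(cl_tv = cl_tv, v_fixed = v_fixed,
                 beta_cont = beta_cont, beta_cat = beta_cat,
                 centering = centering[names(beta_cont)]),
            class = "theta_vector")
}

#' Final published clearance model for vancomycin in neurosurgical patients
#'
#' CL (L/h) = 7.98 x (eGFR/115.2)^0.8 x (BW/70)^0.3 x e^A, A = 0.13 with
#' mannitol co-medication, else 0; V = 60.2 L.
#'
#' @return a [theta_vector()].
#' @export
theta_final <- function() {
  theta_vector(cl_tv = 7.98, v_fixed = 60.2,
               beta_cont = c(egfr = 0.8, wt = 0.3),
               beta_cat = c(mannitol = 0.13),
               centering = c(egfr = 115.2, wt = 70))
}

#' Covariate-free base clearance model
#'
#' Typical clearance 8.08 L/h, V fixed at 60.2 L, no covariates.
#'
#' @return a [theta_vector()].
#' @export
theta_base <- function() {
  theta_vector(cl_tv = 8.08, v_fixed = 60.2)
}

#' Population typical clearance for given covariates
#'
#' @param theta a [theta_vector()].
#' @param cov data frame (or coercible list) with one row per patient,
#'   holding every covariate named in `theta` (continuous columns numeric,
#'   categorical columns logical or 0/1).
#' @return typical clearance, L/h (vector, one per row of `cov`).
#' @export
#' @examples
#' typical_cl(theta_final(),
#'            data.frame(egfr = 115.2, wt = 70, mannitol = FALSE)) # 7.98
typical_cl <- function(theta, cov) {
  stopifnot(inherits(theta, "theta_vector"))
  cov <- as.data.frame(cov)
  need <- c(names(theta$beta_cont), names(theta$beta_cat))
  miss <- setdiff(need, names(cov))
  if (length(miss))
    stop("covariate(s) missing from data: ", paste(miss, collapse = ", "))
  cl <- rep(theta$cl_tv, nrow(cov))
  for (nm in names(theta$beta_cont)) {
    x <- cov[[nm]]
    if (any(!is.finite(x)) || any(x <= 0))
      stop("continuous covariate '", nm, "' must be positive")
    cl <- cl * (x / theta$centering[[nm]])^theta$beta_cont[[nm]]
  }
  shift <- 0
  for (nm in names(theta$beta_cat))
    shift <- shift + theta$beta_cat[[nm]] * as.numeric(cov[[nm]])
  cl * exp(shift)
}

#' Individual clearance from a typical value and a random effect
#'
#' Log-normal inter-individual variability: \eqn{CL_i = CL_{typ} e^{\eta_i}},
#' \eqn{\eta_i \sim N(0, \omega^2)}.
#'
#' @param typical typical clearance, L/h.
#' @param eta random-effect value(s).
#' @return individual clearance, L/h.
#' @export
individual_cl <- function(typical, eta) {
  if (any(typical <= 0)) stop("typical clearance must be positive")
  typical * exp(eta)
}

#' Dose event table constructor
#'
#' @param start_time infusion start times, h.
#' @param amount dose amounts, mg.
#' @param duration infusion durations, h; defaults to 1 h (the conventional
#'   infusion time when records do not state one).
#' @return data frame with columns `time`, `amt`, `dur`.
#' @export
dose_events <- function(start_time, amount, duration = 1) {
  n <- length(start_time)
  amount <- rep_len(amount, n)
  duration <- rep_len(duration, n)
  if (any(amount <= 0)) stop("dose amounts must be positive")
  if (any(duration <= 0)) stop("infusion durations must be positive")
  data.frame(time = start_time, amt = amount, dur = duration)
}

#' Steady-state dosing schedule shorthand
#'
#' Expands `n` repeated doses of `amount` mg every `interval` h.
#'
#' @param amount mg per administration.
#' @param interval dosing interval, h (must exceed the infusion duration).
#' @param n number of administrations.
#' @param duration infusion duration, h.
#' @export
regimen_doses <- function(amount, interval, n, duration = 1) {
  if (interval <= duration) stop("interval must exceed infusion duration")
  dose_events(seq(0, by = interval, length.out = n), amount, duration)
}

#' Plasma concentration under one-compartment infusion kinetics
#'
#' Closed-form superposition over doses of the zero-order-infusion /
#' first-order-elimination solution. During an infusion a dose contributes
#' \eqn{(R_0/CL)(1 - e^{-k(t - t_0)})}; afterwards the end-of-infusion value
#' decays as \eqn{e^{-k \Delta t}}. Linear in every dose amount. Times
#' before the first dose return 0.
#'
#' @param doses a data frame from [dose_events()] (columns `time`, `amt`,
#'   `dur`), sorted by `time`.
#' @param cl clearance, L/h.
#' @param v volume of distribution, L.
#' @param t time(s) at which to evaluate, h.
#' @return concentration(s), mg/L.
#' @export
#' @examples
#' d <- regimen_doses(1000, 12, 10)
#' concentration(d, cl = 7.98, v = 60.2, t = c(1, 12, 119.99))
concentration <- function(doses, cl, v, t) {
  stopifnot(length(cl) == 1L, length(v) == 1L)
  if (cl <= 0 || v <= 0) stop("cl and v must be positive (k = cl/v > 0)")
  if (any(t < 0)) stop("t must be non-negative")
  if (is.null(doses) || nrow(doses) == 0L) return(rep(0, length(t)))
  if (is.unsorted(doses$time)) stop("doses must be sorted by start time")
  k <- cl / v
  rel <- outer(t, doses$time, "-")                  # n_t x n_dose
  act <- rel > 0
  te <- pmin(rel, rep(doses$dur, each = length(t)))
  rate <- rep(doses$amt / doses$dur, each = length(t))
  contrib <- rate / cl * (1 - exp(-k * te)) * exp(-k * (rel - te))
  contrib[!act] <- 0
  rowSums(contrib)
}

#' Steady-state AUC over 24 hours
#'
#' For linear elimination the steady-state area under the concentration-time
#' curve over 24 h equals the daily dose divided by clearance.
#'
#' @param daily_dose total dose per 24 h, mg.
#' @param cl clearance, L/h.
#' @return AUC24, h.mg/L.
#' @export
#' @examples
#' auc24_steady_state(2900, 7.2952)
auc24_steady_state <- function(daily_dose, cl) {
  if (any(daily_dose <= 0) || any(cl <= 0))
    stop("daily_dose and cl must be positive")
  daily_dose / cl
}
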