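#' Model specification for the clearance NLME model
#'
#' Structural model: one-compartment, zero-order infusion, first-order
#' elimination, volume of distribution fixed (default 60.2 L, taken from a
#' comparable neurosurgical population because trough-dominated sampling
#' cannot identify V). Statistical model: a single log-normal random effect
#' on clearance and a combined (additive + proportional) residual error.
#' Covariates act on clearance only: continuous ones as centered power
#' terms, categorical ones as exponential shifts.
#'
#' @param cont named numeric vector: centering constants keyed by the
#'   continuous covariate names entering clearance (empty for the base
#'   model).
#' @param cat character vector of categorical covariate names.
#' @param v fixed volume of distribution, L (never estimated).
#' @return object of class `model_spec`.
#' @export
#' @examples
#' model_spec(cont = c(egfr = 115.2, wt = 70), cat = "mannitol")
model_spec <- function(cont = numeric(), cat = character(), v = 60.2) {
  if (length(cont)) {
    if (is.null(names(cont)) || any(!nzchar(names(cont))))
      stop("cont must be a named vector of centering constants")
    if (any(cont <= 0)) stop("centering constants must be positive")
  }
  all_names <- c(names(cont), cat)
  if (anyDuplicated(all_names)) stop("duplicate covariates in model spec")
  stopifnot(v > 0)
  structure(list(cont = cont, cat = as.character(cat), v = v),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  desc <- if (length(x$cont) + length(x$cat) == 0) "base model" else
    paste(c(names(x$cont), x$cat), collapse = " + ")
  cat("<model_spec> CL ~ ", desc, "; V fixed at ", x$v, " L\n", sep = "")
  invisible(x)
}

# number of fixed-effect parameters (cl_tv + covariate coefficients)
n_fixed <- function(spec) 1L + length(spec$cont) + length(spec$cat)

spec_par_names <- function(spec) {
  c("cl_tv",
    if (length(spec$cont)) paste0("beta_", names(spec$cont)),
    if (length(spec$cat)) paste0("beta_", spec$cat),
    "omega_cl", "sigma_prop", "sigma_add")
}

# assemble a theta_vector from a spec and a fixed-effect vector
spec_theta <- function(spec, fixed) {
  nc <- length(spec$cont)
  nk <- length(spec$cat)
  theta_vector(cl_tv = fixed[1],
               v_fixed = spec$v,
               beta_cont = if (nc) setNames(fixed[1 + seq_len(nc)],
                                            names(spec$cont)) else numeric(),
               beta_cat = if (nk) setNames(fixed[1 + nc + seq_len(nk)],
                                           spec$cat) else numeric(),
               centering = spec$cont)
}

# flatten an event table into the contiguous arrays the likelihood core
# expects; excludes flagged / missing observations and subjects left empty
stack_event_table <- function(data) {
  cov <- data$covariates
  obs <- data$obs
  keep <- !is.na(obs$dv) & !obs$blq & !obs$aloq
  obs <- obs[keep, , drop = FALSE]
  used <- cov$id %in% obs$id
  if (!all(used))
    message(sum(!used), " subject(s) without usable observations dropped")
  cov <- cov[used, , drop = FALSE]
  doses <- data$doses[data$doses$id %in% cov$id, , drop = FALSE]
  fid <- factor(obs$id, levels = cov$id)
  o <- order(fid)
  obs <- obs[o, , drop = FALSE]
  fid <- fid[o]
  fdid <- factor(doses$id, levels = cov$id)
  od <- order(fdid, doses$time)
  doses <- doses[od, , drop = FALSE]
  fdid <- fdid[od]
  obs_len <- as.integer(table(fid))
  dose_len <- as.integer(table(fdid))
  list(cov = cov,
       obs_time = obs$time, obs_y = obs$dv,
       obs_off = c(0L, cumsum(obs_len)[-length(obs_len)]),
       obs_len = obs_len,
       obs_id = obs$id,
       dose_time = doses$time, dose_dur = doses$dur,
       dose_rate = doses$amt / doses$dur,
       dose_off = c(0L, cumsum(dose_len)[-length(dose_len)]),
       dose_len = dose_len,
       n_obs = nrow(obs))
}

.stack_ofv <- function(stack, spec, fixed, omega, s1, s2,
                       eta_mult = 6, inner_tol = 1e-8, detail = FALSE) {
  theta <- spec_theta(spec, fixed)
  tvcl <- typical_cl(theta, stack$cov)
  foce_ofv_cpp(tvcl, spec$v, omega, s1, s2,
               stack$obs_time, stack$obs_y, stack$obs_off, stack$obs_len,
               stack$dose_time, stack$dose_dur, stack$dose_rate,
               stack$dose_off, stack$dose_len, eta_mult, inner_tol, detail)
}

#' FOCE objective function value (-2 log marginal likelihood)
#'
#' For each subject the 1-D conditional mode of the clearance random effect
#' is located (Brent search on `eta_mult` x omega around zero) and a
#' Laplace-type approximation with the residual variance evaluated at
#' individual predictions (FOCE with interaction) gives the marginal
#' likelihood contribution. All additive log(2*pi) terms are dropped, the
#' usual convention when only OFV differences between nested models are
#' interpreted. Observations flagged below/above the assay range or with
#' missing values are excluded.
#'
#' @param spec a [model_spec()].
#' @param theta a [theta_vector()] conforming to `spec`.
#' @param omega_cl SD of the clearance random effect (>= 0; the degenerate
#'   omega = 0 case reduces to the fixed-effects weighted -2 log
#'   likelihood).
#' @param sigma a [sigma_pair()]; the components must not both be zero.
#' @param data an [event_table()].
#' @param detail if `TRUE` also return the conditional modes and inner
#'   curvatures.
#' @return the OFV (numeric scalar), or a list when `detail = TRUE`.
#' @export
neg2ll <- function(spec, theta, omega_cl, sigma, data, detail = FALSE) {
  stopifnot(inherits(spec, "model_spec"), inherits(theta, "theta_vector"),
            inherits(sigma, "sigma_pair"), inherits(data, "event_table"))
  if (sigma$prop == 0 && sigma$add == 0)
    stop("sigma components must not both be zero")
  stack <- stack_event_table(data)
  fixed <- c(theta$cl_tv, theta$beta_cont[names(spec$cont)],
             theta$beta_cat[spec$cat])
  res <- .stack_ofv(stack, spec, fixed, omega_cl, sigma$prop, sigma$add,
                    detail = detail)
  if (detail) {
    list(ofv = res$ofv,
         eta = data.frame(id = stack$cov$id, eta = res$eta,
                          curvature = res$hess))
  } else res$ofv
}

#' Control settings for [fit_ppk()]
#'
#' @param maxit maximum iterations for each Nelder-Mead pass.
#' @param reltol outer relative convergence tolerance.
#' @param inner_tol tolerance of the per-subject conditional-mode search.
#' @param eta_mult half-width of the conditional-mode search interval in
#'   units of omega.
#' @param restarts extra Nelder-Mead restarts from the incumbent (restarting
#'   rebuilds the simplex, guarding against premature collapse).
#' @param polish finish with a quasi-Newton (BFGS) pass from the
#'   Nelder-Mead solution.
#' @param se compute standard errors from a finite-difference Hessian.
#' @export
fit_control <- function(maxit = 1500, reltol = 1e-7, inner_tol = 1e-8,
                        eta_mult = 6, restarts = 1, polish = TRUE,
                        se = TRUE) {
  list(maxit = maxit, reltol = reltol, inner_tol = inner_tol,
       eta_mult = eta_mult, restarts = restarts, polish = polish, se = se)
}

# log-linear regression of naive clearance (dose rate over mean observed
# concentration) on the model covariates; crude but a serviceable start
default_init <- function(spec, stack) {
  cov <- stack$cov
  mean_dv <- vapply(seq_len(nrow(cov)), function(i) {
    idx <- stack$obs_off[i] + seq_len(stack$obs_len[i])
    mean(stack$obs_y[idx])
  }, numeric(1))
  rate <- vapply(seq_len(nrow(cov)), function(i) {
    idx <- stack$dose_off[i] + seq_len(stack$dose_len[i])
    amt <- stack$dose_rate[idx] * stack$dose_dur[idx]
    tau <- if (stack$dose_len[i] > 1)
      diff(stack$dose_time[idx][1:2]) else 24
    amt[1] / tau
  }, numeric(1))
  cl0 <- pmax(pmin(rate / pmax(mean_dv, 0.2), 60), 0.3)
  rhs <- NULL
  if (length(spec$cont))
    rhs <- cbind(rhs, sapply(names(spec$cont), function(nm)
      log(cov[[nm]] / spec$cont[[nm]])))
  if (length(spec$cat))
    rhs <- cbind(rhs, sapply(spec$cat, function(nm) as.numeric(cov[[nm]])))
  if (is.null(rhs)) {
    fixed <- exp(mean(log(cl0)))
  } else {
    co <- coef(lm(log(cl0) ~ rhs))
    co[is.na(co)] <- 0
    fixed <- c(exp(co[1]), co[-1])
  }
  list(fixed = unname(fixed), omega = 0.3, sigma = sigma_pair(0.2, 2))
}

par_pack <- function(fixed, omega, s1, s2) {
  c(log(fixed[1]), fixed[-1], log(omega), log(s1), log(s2))
}

par_unpack <- function(par, spec) {
  p <- n_fixed(spec)
  list(fixed = c(exp(par[1]), if (p > 1) par[2:p]),
       omega = exp(par[p + 1]), s1 = exp(par[p + 2]), s2 = exp(par[p + 3]))
}

#' Fit the clearance NLME model by FOCE
#'
#' Minimises [neg2ll()] over log-transformed positivity-constrained
#' parameters (typical clearance, omega, both sigma components) and
#' unconstrained covariate coefficients, using Nelder-Mead with restarts.
#' Standard errors come from a central finite-difference Hessian of the
#' OFV (the observed information is half that Hessian), 95% confidence
#' intervals are Wald-type, and shrinkages are
#' eta-shrinkage = 1 - SD(conditional modes)/omega and
#' eps-shrinkage = 1 - SD(IWRES).
#'
#' @param spec a [model_spec()].
#' @param data an [event_table()] with observed concentrations.
#' @param init optional list with `fixed` (vector: cl_tv then covariate
#'   coefficients), `omega`, `sigma` (a [sigma_pair()]); defaults to a
#'   log-linear naive-clearance regression.
#' @param control a [fit_control()].
#' @return object of class `ppk_fit`: estimates, OFV, SE/RSE/CI table,
#'   conditional random-effect modes, shrinkages, convergence flag.
#' @export
fit_ppk <- function(spec, data, init = NULL, control = fit_control()) {
  stopifnot(inherits(spec, "model_spec"), inherits(data, "event_table"))
  stack <- stack_event_table(data)
  if (is.null(init)) init <- default_init(spec, stack)
  if (length(init$fixed) != n_fixed(spec))
    stop("init$fixed must have length ", n_fixed(spec))
  par0 <- par_pack(init$fixed, init$omega, init$sigma$prop, init$sigma$add)
  obj <- function(par) {
    u <- par_unpack(par, spec)
    .stack_ofv(stack, spec, u$fixed, u$omega, u$s1, u$s2,
               control$eta_mult, control$inner_tol)$ofv
  }
  opt <- optim(par0, obj, method = "Nelder-Mead",
               control = list(maxit = control$maxit,
                              reltol = control$reltol))
  for (r in seq_len(control$restarts)) {
    opt2 <- optim(opt$par, obj, method = "Nelder-Mead",
                  control = list(maxit = control$maxit,
                                 reltol = control$reltol))
    improved <- opt$value - opt2$value
    opt <- opt2
    if (improved < 0.01) break
  }
  if (isTRUE(control$polish)) {
    # quasi-Newton polish: Nelder-Mead can stall short of the optimum in
    # one direction once the simplex collapses
    opt3 <- try(optim(opt$par, obj, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-10,
                                     ndeps = rep(1e-4, length(opt$par)))),
                silent = TRUE)
    if (!inherits(opt3, "try-error") && opt3$value <= opt$value)
      opt <- opt3
  }
  converged <- opt$convergence == 0
  u <- par_unpack(opt$par, spec)
  theta <- spec_theta(spec, u$fixed)
  det <- .stack_ofv(stack, spec, u$fixed, u$omega, u$s1, u$s2,
                    control$eta_mult, control$inner_tol, detail = TRUE)
  # individual predictions and IWRES at the conditional modes
  tvcl <- typical_cl(theta, stack$cov)
  cl_i <- tvcl * exp(det$eta)
  ipred <- numeric(stack$n_obs)
  for (i in seq_len(nrow(stack$cov))) {
    oidx <- stack$obs_off[i] + seq_len(stack$obs_len[i])
    didx <- stack$dose_off[i] + seq_len(stack$dose_len[i])
    dd <- data.frame(time = stack$dose_time[didx],
                     amt = stack$dose_rate[didx] * stack$dose_dur[didx],
                     dur = stack$dose_dur[didx])
    ipred[oidx] <- concentration(dd, cl_i[i], spec$v, stack$obs_time[oidx])
  }
  sig <- sigma_pair(u$s1, u$s2)
  iwres <- (stack$obs_y - ipred) / residual_sd(ipred, sig)
  shrinkage <- list(
    eta = max(0, min(1, 1 - sd(det$eta) / u$omega)),
    eps = max(0, min(1, 1 - sd(iwres))))

  nm <- spec_par_names(spec)
  est <- c(u$fixed, u$omega, u$s1, u$s2)
  se <- rep(NA_real_, length(est))
  vcov_nat <- NULL
  if (isTRUE(control$se)) {
    H <- fd_hessian(obj, opt$par)
    vc <- try(2 * solve(H), silent = TRUE)
    if (inherits(vc, "try-error") || any(!is.finite(diag(vc))) ||
        any(diag(vc) < 0)) {
      # near-flat or noise-negative curvature directions (e.g. a variance
      # component collapsed to its boundary) make H singular or indefinite;
      # drop those directions via a pseudoinverse so the identified
      # parameters keep their standard errors, and report NA for the
      # parameters that load on the dropped directions
      ei <- eigen((H + t(H)) / 2, symmetric = TRUE)
      pos <- ei$values > max(abs(ei$values)) * 1e-9
      vc <- 2 * ei$vectors[, pos, drop = FALSE] %*%
        diag(1 / ei$values[pos], sum(pos)) %*%
        t(ei$vectors[, pos, drop = FALSE])
      bad_dir <- rowSums(abs(ei$vectors[, !pos, drop = FALSE])) > 0.1
      diag(vc)[bad_dir] <- NA_real_
      warning("Hessian numerically singular or indefinite; SEs from ",
              "pseudoinverse, unidentified directions reported as NA")
    }
    if (all(is.na(diag(vc)))) {
      warning("no identified directions; SEs unavailable")
    } else {
      # delta method back to the natural scale for log-transformed entries
      grad <- rep(1, length(est))
      logged <- c(1L, n_fixed(spec) + 1:3)
      grad[logged] <- est[logged]
      vcov_nat <- vc * tcrossprod(grad)  # elementwise: keeps NA local
      dimnames(vcov_nat) <- list(nm, nm)
      se <- sqrt(diag(vcov_nat))
    }
  }
  tab <- data.frame(parameter = nm, estimate = est, se = se,
                    rse_percent = 100 * se / abs(est),
                    ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se,
                    row.names = NULL)
  structure(list(spec = spec, theta = theta, omega_cl = u$omega,
                 sigma = sig, ofv = opt$value, estimates = tab,
                 vcov = vcov_nat,
                 eta = data.frame(id = stack$cov$id, eta = det$eta),
                 shrinkage = shrinkage, converged = converged,
                 n_subjects = nrow(stack$cov), n_obs = stack$n_obs,
                 par = opt$par, control = control, evals = opt$counts[1]),
            class = "ppk_fit")
}

#' @export
print.ppk_fit <- function(x, digits = 4, ...) {
  cat("FOCE fit: ", x$n_subjects, " subjects, ", x$n_obs,
      " observations\nOFV: ", format(x$ofv, digits = 9),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  tab <- x$estimates
  tab$estimate <- signif(tab$estimate, digits)
  tab$se <- signif(tab$se, digits)
  tab$rse_percent <- round(tab$rse_percent, 2)
  tab$ci_lo <- signif(tab$ci_lo, digits)
  tab$ci_hi <- signif(tab$ci_hi, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("V fixed at %.4g L; IIV CL %.4g%% CV; shrinkage eta %.2f, eps %.2f\n",
              x$spec$v, 100 * x$omega_cl, x$shrinkage$eta, x$shrinkage$eps))
  invisible(x)
}

# central finite-difference Hessian
fd_hessian <- function(fn, par, rel_h = 1e-3) {
  p <- length(par)
  h <- pmax(1e-4, rel_h * abs(par))
  H <- matrix(0, p, p)
  f0 <- fn(par)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    H[i, i] <- (fn(par + ei) - 2 * f0 + fn(par - ei)) / h[i]^2
    if (i < p) for (j in (i + 1):p) {
      ej <- replace(numeric(p), j, h[j])
      H[i, j] <- H[j, i] <-
        (fn(par + ei + ej) - fn(par + ei - ej) -
           fn(par - ei + ej) + fn(par - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H
}

#' Conditional weighted residuals and predictions
#'
#' FOCE-linearised diagnostics: the model is expanded to first order in the
#' random effect about each subject's conditional mode; the resulting
#' approximate marginal mean and covariance whiten the residuals. Under the
#' data-generating model CWRES are approximately standard normal. Also
#' returns PRED (population prediction at eta = 0), IPRED (individual
#' prediction at the mode) and IWRES.
#'
#' @param fit a converged [fit_ppk()] result.
#' @param data the [event_table()] the model was fitted to.
#' @return data frame: `id`, `time`, `dv`, `pred`, `ipred`, `iwres`,
#'   `cwres`.
#' @export
cwres <- function(fit, data) {
  stopifnot(inherits(fit, "ppk_fit"), inherits(data, "event_table"))
  stack <- stack_event_table(data)
  theta <- fit$theta
  omega <- fit$omega_cl
  sig <- fit$sigma
  tvcl <- typical_cl(theta, stack$cov)
  eta <- fit$eta$eta[match(stack$cov$id, fit$eta$id)]
  out <- vector("list", nrow(stack$cov))
  for (i in seq_len(nrow(stack$cov))) {
    oidx <- stack$obs_off[i] + seq_len(stack$obs_len[i])
    didx <- stack$dose_off[i] + seq_len(stack$dose_len[i])
    dd <- data.frame(time = stack$dose_time[didx],
                     amt = stack$dose_rate[didx] * stack$dose_dur[didx],
                     dur = stack$dose_dur[didx])
    tt <- stack$obs_time[oidx]
    y <- stack$obs_y[oidx]
    f_of <- function(e) concentration(dd, tvcl[i] * exp(e), theta$v_fixed, tt)
    e0 <- eta[i]
    h <- 1e-4
    fe <- f_of(e0)
    Fg <- (f_of(e0 + h) - f_of(e0 - h)) / (2 * h)
    pred <- f_of(0)
    mu <- fe - Fg * e0
    V <- omega^2 * tcrossprod(Fg) + diag(residual_sd(fe, sig)^2,
                                         length(fe))
    w <- backsolve(chol(V), y - mu, transpose = TRUE)
    out[[i]] <- data.frame(id = stack$cov$id[i], time = tt, dv = y,
                           pred = pred, ipred = fe,
                           iwres = (y - fe) / residual_sd(fe, sig),
                           cwres = w)
  }
  do.call(rbind, out)
}
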