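#' Candidate covariates for the clearance model
#'
#' Continuous candidates (age, height, body weight, BMI, serum creatinine,
#' Cockcroft-Gault creatinine clearance, CKD-EPI eGFR) enter as centered
#' power terms; categorical candidates (female sex, RRT, mannitol,
#' meropenem, diuretics) as exponential shifts. The three renal-function
#' measures (scr, clcr, egfr) are mutually exclusive proxies by default.
#'
#' @return data frame with columns `name` and `kind`.
#' @export
covariate_candidates <- function() {
  data.frame(
    name = c("age", "ht", "wt", "bmi", "scr", "clcr", "egfr",
             "female", "rrt", "mannitol", "meropenem", "diuretics"),
    kind = c(rep("continuous", 7), rep("categorical", 5)))
}

#' Control settings for the stepwise covariate search
#'
#' @param forward_drop OFV decrease required to accept a covariate during
#'   forward addition (6.64, chi-square p < 0.01 at 1 df).
#' @param backward_rise OFV increase on removal above which a covariate is
#'   retained during backward elimination (10.83, p < 0.001 at 1 df).
#' @param renal_exclusive treat scr / clcr / egfr as mutually exclusive
#'   renal-function proxies: once one enters, the others leave the
#'   candidate pool.
#' @param centering `"median"` centers continuous candidates at their
#'   dataset median (the convention for de-novo model building) or a named
#'   numeric vector of fixed centering constants.
#' @param fit_control a [fit_control()] used for the search fits (standard
#'   errors are skipped during the search).
#' @export
sw_control <- function(forward_drop = 6.64, backward_rise = 10.83,
                       renal_exclusive = TRUE, centering = "median",
                       fit_control = vancoppk::fit_control(
                         se = FALSE, restarts = 0, maxit = 600,
                         reltol = 1e-6)) {
  fit_control$se <- FALSE
  list(forward_drop = forward_drop, backward_rise = backward_rise,
       renal_exclusive = renal_exclusive, centering = centering,
       fit_control = fit_control)
}

.renal_proxies <- c("scr", "clcr", "egfr")

center_value <- function(name, data, control) {
  if (is.numeric(control$centering)) {
    if (!name %in% names(control$centering))
      stop("no centering constant supplied for ", name)
    return(control$centering[[name]])
  }
  stats::median(data$covariates[[name]])
}

spec_add <- function(spec, name, kind, data, control) {
  if (kind == "continuous")
    model_spec(cont = c(spec$cont,
                        setNames(center_value(name, data, control), name)),
               cat = spec$cat, v = spec$v)
  else
    model_spec(cont = spec$cont, cat = c(spec$cat, name), v = spec$v)
}

spec_drop <- function(spec, name) {
  model_spec(cont = spec$cont[setdiff(names(spec$cont), name)],
             cat = setdiff(spec$cat, name), v = spec$v)
}

# warm-started candidate fit: new coefficients start at 0, everything else
# at the incumbent estimates
warm_fit <- function(spec, data, ref_fit, control) {
  init <- NULL
  if (!is.null(ref_fit)) {
    old <- c(names(ref_fit$spec$cont), ref_fit$spec$cat)
    new <- c(names(spec$cont), spec$cat)
    betas <- setNames(rep(0, length(new)), new)
    keep <- intersect(old, new)
    old_betas <- c(ref_fit$theta$beta_cont, ref_fit$theta$beta_cat)
    betas[keep] <- old_betas[keep]
    init <- list(fixed = c(ref_fit$theta$cl_tv, unname(betas)),
                 omega = ref_fit$omega_cl, sigma = ref_fit$sigma)
  }
  fit_ppk(spec, data, init = init, control = control)
}

in_model <- function(spec) c(names(spec$cont), spec$cat)

#' One forward-addition step
#'
#' Fits the current model extended by each remaining candidate, picks the
#' candidate with the largest OFV decrease, and accepts it iff the decrease
#' exceeds the forward threshold. Ties break by candidate-list order.
#' Non-convergent candidate fits are skipped with a warning.
#'
#' @param spec current [model_spec()].
#' @param candidates data frame as from [covariate_candidates()].
#' @param data an [event_table()].
#' @param control a [sw_control()].
#' @param current_fit optional fit of `spec` (refitted when absent).
#' @return list with `record` (one-row step summary), `trace` (one row per
#'   candidate tried), `spec` and `fit` (updated when accepted).
#' @export
forward_step <- function(spec, candidates, data, control = sw_control(),
                         current_fit = NULL) {
  if (is.null(current_fit))
    current_fit <- warm_fit(spec, data, NULL, control$fit_control)
  have <- in_model(spec)
  pool <- candidates[!candidates$name %in% have, , drop = FALSE]
  if (control$renal_exclusive && any(have %in% .renal_proxies))
    pool <- pool[!pool$name %in% .renal_proxies, , drop = FALSE]
  no_op <- list(
    record = data.frame(action = "add", covariate = NA_character_,
                        ofv_before = current_fit$ofv,
                        ofv_after = current_fit$ofv, delta_ofv = 0,
                        accepted = FALSE),
    trace = NULL, spec = spec, fit = current_fit)
  if (!nrow(pool)) return(no_op)
  trace <- vector("list", nrow(pool))
  fits <- vector("list", nrow(pool))
  for (r in seq_len(nrow(pool))) {
    cand_spec <- spec_add(spec, pool$name[r], pool$kind[r], data, control)
    f <- try(warm_fit(cand_spec, data, current_fit, control$fit_control),
             silent = TRUE)
    ok <- !inherits(f, "try-error") && f$converged
    if (!ok)
      warning("candidate fit failed or did not converge: ", pool$name[r])
    trace[[r]] <- data.frame(
      covariate = pool$name[r],
      ofv = if (ok) f$ofv else NA_real_,
      delta_ofv = if (ok) f$ofv - current_fit$ofv else NA_real_,
      converged = ok)
    fits[[r]] <- if (ok) f else NULL
  }
  trace <- do.call(rbind, trace)
  if (all(is.na(trace$delta_ofv))) {
    no_op$trace <- trace
    return(no_op)
  }
  best <- which.min(replace(trace$delta_ofv, is.na(trace$delta_ofv), Inf))
  accepted <- trace$delta_ofv[best] < -control$forward_drop
  record <- data.frame(action = "add", covariate = trace$covariate[best],
                       ofv_before = current_fit$ofv,
                       ofv_after = trace$ofv[best],
                       delta_ofv = trace$delta_ofv[best],
                       accepted = accepted)
  if (accepted)
    list(record = record, trace = trace,
         spec = spec_add(spec, pool$name[best], pool$kind[best], data,
                         control),
         fit = fits[[best]])
  else
    list(record = record, trace = trace, spec = spec, fit = current_fit)
}

#' One backward-elimination step
#'
#' Refits the current model with each included covariate removed; the
#' covariate whose removal raises the OFV least is eliminated if that rise
#' does not exceed the backward threshold.
#'
#' @inheritParams forward_step
#' @return as [forward_step()], with `action = "remove"`.
#' @export
backward_step <- function(spec, data, control = sw_control(),
                          current_fit = NULL) {
  have <- in_model(spec)
  if (!length(have)) stop("backward step requires at least one covariate")
  if (is.null(current_fit))
    current_fit <- warm_fit(spec, data, NULL, control$fit_control)
  trace <- vector("list", length(have))
  fits <- vector("list", length(have))
  for (r in seq_along(have)) {
    cand_spec <- spec_drop(spec, have[r])
    f <- try(warm_fit(cand_spec, data, current_fit, control$fit_control),
             silent = TRUE)
    ok <- !inherits(f, "try-error") && f$converged
    if (!ok)
      warning("removal fit failed or did not converge: ", have[r])
    trace[[r]] <- data.frame(
      covariate = have[r],
      ofv = if (ok) f$ofv else NA_real_,
      delta_ofv = if (ok) f$ofv - current_fit$ofv else NA_real_,
      converged = ok)
    fits[[r]] <- if (ok) f else NULL
  }
  trace <- do.call(rbind, trace)
  weakest <- which.min(replace(trace$delta_ofv, is.na(trace$delta_ofv), Inf))
  removable <- is.finite(trace$delta_ofv[weakest]) &&
    trace$delta_ofv[weakest] <= control$backward_rise
  record <- data.frame(action = "remove", covariate = trace$covariate[weakest],
                       ofv_before = current_fit$ofv,
                       ofv_after = trace$ofv[weakest],
                       delta_ofv = trace$delta_ofv[weakest],
                       accepted = removable)
  if (removable)
    list(record = record, trace = trace,
         spec = spec_drop(spec, have[weakest]), fit = fits[[weakest]])
  else
    list(record = record, trace = trace, spec = spec, fit = current_fit)
}

#' Stepwise covariate search (forward addition, backward elimination)
#'
#' Iterates [forward_step()] until no candidate clears the forward
#' threshold, then [backward_step()] until every remaining covariate
#' survives the backward threshold. Emits a model-development log in the
#' familiar "Model No. / description / OFV / delta OFV" layout.
#'
#' @param base starting [model_spec()] (usually the covariate-free base
#'   model).
#' @param candidates data frame as from [covariate_candidates()].
#' @param data an [event_table()].
#' @param control a [sw_control()].
#' @return list: `spec` (final model), `fit` (its fit), `steps` (accepted /
#'   rejected step records), `log` (Table-style per-model log).
#' @export
run_stepwise <- function(base = model_spec(), candidates = covariate_candidates(),
                         data, control = sw_control()) {
  fit <- warm_fit(base, data, NULL, control$fit_control)
  spec <- base
  steps <- list()
  log <- list(data.frame(model = 1L, description = "base model",
                         ofv = fit$ofv, delta_ofv = NA_real_,
                         phase = "forward"))
  model_no <- 1L
  ref_no <- 1L
  repeat {
    st <- forward_step(spec, candidates, data, control, fit)
    if (!is.null(st$trace))
      for (r in seq_len(nrow(st$trace))) {
        model_no <- model_no + 1L
        log[[length(log) + 1L]] <- data.frame(
          model = model_no,
          description = sprintf("add %s on CL to model %d",
                                st$trace$covariate[r], ref_no),
          ofv = st$trace$ofv[r], delta_ofv = st$trace$delta_ofv[r],
          phase = "forward")
      }
    steps[[length(steps) + 1L]] <- st$record
    if (!st$record$accepted) break
    spec <- st$spec
    fit <- st$fit
    ref_no <- model_no - nrow(st$trace) + which(st$trace$covariate ==
                                                  st$record$covariate)
    if (!length(setdiff(candidates$name, in_model(spec)))) break
  }
  while (length(in_model(spec))) {
    st <- backward_step(spec, data, control, fit)
    if (!is.null(st$trace))
      for (r in seq_len(nrow(st$trace))) {
        model_no <- model_no + 1L
        log[[length(log) + 1L]] <- data.frame(
          model = model_no,
          description = sprintf("remove %s on CL from model %d",
                                st$trace$covariate[r], ref_no),
          ofv = st$trace$ofv[r], delta_ofv = st$trace$delta_ofv[r],
          phase = "backward")
      }
    steps[[length(steps) + 1L]] <- st$record
    if (!st$record$accepted) break
    spec <- st$spec
    fit <- st$fit
  }
  steps <- do.call(rbind, steps)
  steps$step <- seq_len(nrow(steps))
  list(spec = spec, fit = fit,
       steps = steps[, c("step", "action", "covariate", "ofv_before",
                         "ofv_after", "delta_ofv", "accepted")],
       log = do.call(rbind, log))
}
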