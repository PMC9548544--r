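#' Nonparametric subject-level bootstrap of the model fit
#'
#' Resamples whole subjects with replacement to the original subject count,
#' refits each replicate (warm-started from the reference fit) and
#' summarises the converged replicates: per-parameter median, 2.5-97.5
#' percentile interval and relative standard error across replicates. A
#' convergence fraction below 80% flags the result as unstable.
#'
#' @param spec a [model_spec()].
#' @param data an [event_table()].
#' @param n_boot number of bootstrap data sets (5000 in a full analysis;
#'   desk-scale runs use a few hundred, recorded in the result).
#' @param seed integer seed.
#' @param ref_fit optional reference [fit_ppk()] of `spec` on `data`
#'   (fitted if absent) used as warm start and comparison point.
#' @param control a [fit_control()] for the replicate fits (SEs skipped).
#' @return object of class `ppk_bootstrap`: `summary` (one row per
#'   parameter), `replicates` (matrix of estimates), `n_requested`,
#'   `n_converged`, `unstable`.
#' @export
bootstrap_ppk <- function(spec, data, n_boot = 200, seed = 1,
                          ref_fit = NULL,
                          control = fit_control(se = FALSE, restarts = 0,
                                                maxit = 600,
                                                reltol = 1e-6)) {
  stopifnot(inherits(spec, "model_spec"), inherits(data, "event_table"),
            n_boot >= 1)
  control$se <- FALSE
  if (is.null(ref_fit)) ref_fit <- fit_ppk(spec, data, control = control)
  ids <- data$covariates$id
  nm <- spec_par_names(spec)
  reps <- matrix(NA_real_, n_boot, length(nm), dimnames = list(NULL, nm))
  init <- list(fixed = c(ref_fit$theta$cl_tv, ref_fit$theta$beta_cont,
                         ref_fit$theta$beta_cat),
               omega = ref_fit$omega_cl, sigma = ref_fit$sigma)
  with_preserved_seed(seed, {
    for (b in seq_len(n_boot)) {
      take <- sample(ids, length(ids), replace = TRUE)
      bd <- resample_subjects(data, take)
      f <- try(fit_ppk(spec, bd, init = init, control = control),
               silent = TRUE)
      if (!inherits(f, "try-error") && f$converged)
        reps[b, ] <- f$estimates$estimate
    }
  })
  ok <- stats::complete.cases(reps)
  summ <- data.frame(
    parameter = nm,
    estimate = ref_fit$estimates$estimate,
    boot_median = apply(reps[ok, , drop = FALSE], 2, median),
    ci_lo = apply(reps[ok, , drop = FALSE], 2, quantile, 0.025),
    ci_hi = apply(reps[ok, , drop = FALSE], 2, quantile, 0.975),
    rse_percent = 100 * apply(reps[ok, , drop = FALSE], 2, sd) /
      abs(apply(reps[ok, , drop = FALSE], 2, mean)),
    row.names = NULL)
  structure(list(summary = summ, replicates = reps,
                 n_requested = n_boot, n_converged = sum(ok),
                 unstable = sum(ok) < 0.8 * n_boot, ref_fit = ref_fit),
            class = "ppk_bootstrap")
}

#' @export
print.ppk_bootstrap <- function(x, ...) {
  cat("Subject-level bootstrap: ", x$n_converged, "/", x$n_requested,
      " replicates converged", if (x$unstable) "  [UNSTABLE]", "\n",
      sep = "")
  print(transform(x$summary,
                  boot_median = signif(boot_median, 4),
                  ci_lo = signif(ci_lo, 4), ci_hi = signif(ci_hi, 4),
                  rse_percent = round(rse_percent, 2)),
        row.names = FALSE)
  invisible(x)
}

# build an event table from a with-replacement draw of subject ids,
# renumbering duplicates so ids stay unique
resample_subjects <- function(data, take) {
  cov <- data$covariates[match(take, data$covariates$id), , drop = FALSE]
  new_id <- seq_along(take)
  dsp <- split(data$doses, factor(data$doses$id, data$covariates$id))
  osp <- split(data$obs, factor(data$obs$id, data$covariates$id))
  pos <- match(take, data$covariates$id)
  dl <- dsp[pos]
  ol <- osp[pos]
  for (i in seq_along(take)) {
    if (nrow(dl[[i]])) dl[[i]]$id <- new_id[i]
    if (nrow(ol[[i]])) ol[[i]]$id <- new_id[i]
  }
  cov$id <- new_id
  suppressWarnings(event_table(cov, do.call(rbind, dl), do.call(rbind, ol)))
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicates of the data set's exact design (same
#' subjects, doses, sampling times and covariates) under the fitted model
#' with fresh random effects and residual errors, then compares observed
#' concentrations with the simulated distribution. Two views are returned:
#' a pooled per-observation check (each observation against the 5th-95th
#' percentile of its own simulated values; `coverage` is the fraction
#' falling inside that 90% prediction interval) and a binned view
#' (quantile bins of time after the last dose, default 8, with the 5th,
#' 50th and 95th percentile bands of the pooled simulated concentrations
#' per bin). Empty or duplicate bins are merged.
#'
#' @param fit a converged [fit_ppk()].
#' @param data the [event_table()] the model was fitted to.
#' @param n_sim number of simulated replicates (10000 in a full analysis;
#'   a few hundred at desk scale).
#' @param seed integer seed.
#' @param bins number of time-after-dose quantile bins.
#' @return object of class `ppk_vpc`: `coverage`, `obs` (per observation:
#'   time after dose, value, its simulation interval, inside flag),
#'   `bins` (per bin: edges, simulated band, observed percentiles,
#'   coverage), `n_sim`.
#' @export
vpc_ppk <- function(fit, data, n_sim = 500, seed = 1, bins = 8) {
  stopifnot(inherits(fit, "ppk_fit"), inherits(data, "event_table"),
            n_sim >= 1)
  stack <- stack_event_table(data)
  used <- !is.na(data$obs$dv) & !data$obs$blq & !data$obs$aloq
  obs <- data$obs[used, , drop = FALSE]
  obs <- obs[order(factor(obs$id, stack$cov$id), obs$time), , drop = FALSE]
  # time after the start of the most recent prior dose
  tad <- numeric(nrow(obs))
  dsp <- split(data$doses, factor(data$doses$id, stack$cov$id))
  osp <- split(seq_len(nrow(obs)), factor(obs$id, stack$cov$id))
  for (i in seq_along(osp)) {
    idx <- osp[[i]]
    if (!length(idx)) next
    dt <- dsp[[i]]$time
    tad[idx] <- vapply(obs$time[idx],
                       function(t) t - max(dt[dt < t], -Inf), numeric(1))
  }
  design <- event_table(stack$cov,
                        data$doses[data$doses$id %in% stack$cov$id, ],
                        obs)
  sims <- matrix(NA_real_, nrow(obs), n_sim)
  for (r in seq_len(n_sim)) {
    s <- simulate_observations(design, fit$theta, fit$omega_cl, fit$sigma,
                               seed = seed + r - 1L)
    keep <- !s$obs$blq & !s$obs$aloq
    sims[keep, r] <- s$obs$dv[keep]
  }
  qs <- t(apply(sims, 1, quantile, c(0.05, 0.5, 0.95), na.rm = TRUE))
  inside <- obs$dv >= qs[, 1] & obs$dv <= qs[, 3]
  obs_out <- data.frame(id = obs$id, time = obs$time, tad = tad,
                        dv = obs$dv, sim_lo = qs[, 1], sim_med = qs[, 2],
                        sim_hi = qs[, 3], inside = inside)
  br <- unique(quantile(tad, probs = seq(0, 1, length.out = bins + 1)))
  if (length(br) < 2) br <- range(tad) + c(-0.5, 0.5)
  bin <- cut(tad, br, include.lowest = TRUE)
  lvs <- levels(bin)[tabulate(bin, length(levels(bin))) > 0]  # merge empties
  bin_rows <- lapply(lvs, function(lv) {
    sel <- bin == lv
    pool <- as.vector(sims[sel, , drop = FALSE])
    pool <- pool[!is.na(pool)]
    data.frame(bin = lv,
               t_mid = median(tad[sel]),
               n_obs = sum(sel),
               sim_p5 = quantile(pool, 0.05),
               sim_p50 = quantile(pool, 0.5),
               sim_p95 = quantile(pool, 0.95),
               obs_p5 = quantile(obs$dv[sel], 0.05),
               obs_p50 = quantile(obs$dv[sel], 0.5),
               obs_p95 = quantile(obs$dv[sel], 0.95),
               coverage = mean(inside[sel]), row.names = NULL)
  })
  structure(list(coverage = mean(inside), obs = obs_out,
                 bins = do.call(rbind, bin_rows), n_sim = n_sim),
            class = "ppk_vpc")
}

#' @export
print.ppk_vpc <- function(x, ...) {
  cat(sprintf(
    "VPC: %d simulated replicates; %.1f%% of observations inside the 90%% PI\n",
    x$n_sim, 100 * x$coverage))
  print(transform(x$bins, sim_p5 = signif(sim_p5, 3),
                  sim_p50 = signif(sim_p50, 3), sim_p95 = signif(sim_p95, 3),
                  obs_p5 = signif(obs_p5, 3), obs_p50 = signif(obs_p50, 3),
                  obs_p95 = signif(obs_p95, 3),
                  coverage = round(coverage, 3)),
        row.names = FALSE)
  invisible(x)
}
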