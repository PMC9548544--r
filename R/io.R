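#' Write an event table as a NONMEM-style CSV dataset
#'
#' One row per event: dose rows (`EVID = 1`, `MDV = 1`) carry `AMT`, `DUR`
#' and `II`; observation rows (`EVID = 0`, `MDV = 0`) carry `DV` plus
#' `BLQ`/`ALOQ` flags. Covariates repeat on every row: `AGE`, `SEX`
#' (1 = male, 0 = female), `WT`, `HT`, `BMI`, `SCR` (mg/dL), `RRT`,
#' `MANN`, `MERO`, `DIUR`. Times are hours since each subject's first
#' dose. A leading comment line records the generation context; readers
#' must treat `#` as a comment character.
#'
#' @param x an [event_table()].
#' @param path output file.
#' @param truth_path optional path for a sidecar CSV with the simulation
#'   truth (per-subject random effect and clearance) when `x` carries it.
#' @param comment optional single comment line stored on the first row.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(x, path, truth_path = NULL, comment = NULL) {
  stopifnot(inherits(x, "event_table"))
  cov <- x$covariates
  cov_cols <- function(id) {
    i <- match(id, cov$id)
    data.frame(AGE = cov$age[i], SEX = as.integer(cov$sex[i] == "male"),
               WT = cov$wt[i], HT = cov$ht[i], BMI = cov$bmi[i],
               SCR = cov$scr[i], RRT = as.integer(cov$rrt[i]),
               MANN = as.integer(cov$mannitol[i]),
               MERO = as.integer(cov$meropenem[i]),
               DIUR = as.integer(cov$diuretics[i]))
  }
  drows <- data.frame(ID = x$doses$id, TIME = x$doses$time, EVID = 1L,
                      AMT = x$doses$amt, DUR = x$doses$dur,
                      II = if (is.null(x$doses$interval)) NA_real_ else
                        x$doses$interval,
                      DV = NA_real_, MDV = 1L, BLQ = 0L, ALOQ = 0L,
                      cov_cols(x$doses$id))
  orows <- data.frame(ID = x$obs$id, TIME = x$obs$time, EVID = 0L,
                      AMT = NA_real_, DUR = NA_real_, II = NA_real_,
                      DV = x$obs$dv, MDV = 0L,
                      BLQ = as.integer(x$obs$blq),
                      ALOQ = as.integer(x$obs$aloq),
                      cov_cols(x$obs$id))
  tab <- rbind(drows, orows)
  tab <- tab[order(tab$ID, tab$TIME, -tab$EVID), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  write.csv(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
            con, row.names = FALSE, quote = FALSE, na = ".")
  truth <- attr(x, "truth")
  if (!is.null(truth_path)) {
    if (is.null(truth)) stop("event table carries no simulation truth")
    write.csv(format(truth, digits = 15, trim = TRUE), truth_path,
              row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a NONMEM-style CSV dataset into an event table
#'
#' Accepts the layout written by [write_pk_dataset()]. `RATE` is accepted
#' in place of `DUR` (converted as `DUR = AMT/RATE`); a missing `DUR`
#' defaults to a 1-h infusion, the conventional infusion time. Serum
#' creatinine is converted to the canonical mg/dL according to
#' `scr_unit`. Observation rows with a missing `DV` are a hard error (the
#' offending row numbers are reported), as are non-monotone times within a
#' subject. Unknown columns produce a warning and are ignored.
#'
#' @param path CSV file.
#' @param scr_unit unit of the `SCR` column: `"mgdl"` or `"umol"`.
#' @return an [event_table()].
#' @export
read_pk_dataset <- function(path, scr_unit = c("mgdl", "umol")) {
  scr_unit <- match.arg(scr_unit)
  tab <- read.csv(path, na.strings = c(".", "NA", ""), comment.char = "#")
  names(tab) <- toupper(names(tab))
  required <- c("ID", "TIME", "EVID", "AMT", "DV", "MDV",
                "AGE", "SEX", "WT", "HT", "SCR")
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  known <- c(required, "DUR", "RATE", "II", "BLQ", "ALOQ", "BMI",
             "RRT", "MANN", "MERO", "DIUR")
  unknown <- setdiff(names(tab), known)
  if (length(unknown))
    warning("ignoring unknown column(s): ", paste(unknown, collapse = ", "))
  if (is.null(tab$DUR)) {
    tab$DUR <- if (!is.null(tab$RATE)) tab$AMT / tab$RATE else NA_real_
  }
  tab$DUR[is.na(tab$DUR) & tab$EVID == 1] <- 1
  bad_dv <- which(tab$EVID == 0 & tab$MDV == 0 & is.na(tab$DV))
  if (length(bad_dv))
    stop("observation row(s) with missing DV: ",
         paste(bad_dv, collapse = ", "))
  for (id in unique(tab$ID)) {
    tt <- tab$TIME[tab$ID == id]
    if (is.unsorted(tt))
      stop("non-monotone times within subject ", id)
  }
  scr <- if (scr_unit == "umol") scr_umol_to_mgdl(tab$SCR) else tab$SCR
  first <- !duplicated(tab$ID)
  sex <- ifelse(tab$SEX[first] == 1, "male", "female")
  age <- tab$AGE[first]
  wt <- tab$WT[first]
  ht <- tab$HT[first]
  scr1 <- scr[first]
  covariates <- data.frame(
    id = tab$ID[first], age = age, sex = sex, female = sex == "female",
    wt = wt, ht = ht,
    bmi = if (!is.null(tab$BMI)) tab$BMI[first] else wt / (ht / 100)^2,
    scr = scr1,
    egfr = ckd_epi(age, sex, scr1),
    clcr = suppressMessages(cockcroft_gault(age, sex, wt, scr1)),
    rrt = if (!is.null(tab$RRT)) tab$RRT[first] == 1 else FALSE,
    mannitol = if (!is.null(tab$MANN)) tab$MANN[first] == 1 else FALSE,
    meropenem = if (!is.null(tab$MERO)) tab$MERO[first] == 1 else FALSE,
    diuretics = if (!is.null(tab$DIUR)) tab$DIUR[first] == 1 else FALSE)
  dr <- tab[tab$EVID == 1, , drop = FALSE]
  orow <- tab[tab$EVID == 0, , drop = FALSE]
  doses <- data.frame(id = dr$ID, time = dr$TIME, amt = dr$AMT,
                      dur = dr$DUR,
                      interval = if (!is.null(dr$II)) dr$II else NA_real_)
  obs <- data.frame(id = orow$ID, time = orow$TIME, dv = orow$DV,
                    blq = if (!is.null(orow$BLQ)) orow$BLQ == 1 else FALSE,
                    aloq = if (!is.null(orow$ALOQ)) orow$ALOQ == 1 else
                      FALSE)
  event_table(covariates, doses, obs)
}

#' Pipeline run configuration
#'
#' @param out_dir output directory (created if absent).
#' @param stages subset of `"simulate"`, `"fit_base"`, `"stepwise"`,
#'   `"fit_final"`, `"bootstrap"`, `"vpc"`, `"dose_table"`. A stage that
#'   needs an earlier product triggers it implicitly.
#' @param dataset path of an existing dataset CSV (used when `"simulate"`
#'   is not requested).
#' @param scr_unit unit of the SCR column when loading `dataset`.
#' @param seed global seed; stage seeds derive from it.
#' @param cohort a [cohort_config()] for the simulate stage.
#' @param sim_theta,sim_omega,sim_sigma generating parameters for the
#'   simulate stage (defaults: the final published model).
#' @param final_spec [model_spec()] fitted by the `fit_final` stage (and
#'   used by bootstrap/VPC/dose-table); defaults to the published
#'   covariate model. When `stepwise` runs, its selected model is used
#'   instead.
#' @param n_boot,n_sim_vpc bootstrap / VPC replicate counts.
#' @param dose_grid named list of arguments forwarded to
#'   [build_dose_table()] (axes, interval, n_sim).
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       stages = c("simulate", "fit_base", "stepwise",
                                  "fit_final", "bootstrap", "vpc",
                                  "dose_table"),
                       dataset = NULL, scr_unit = "mgdl", seed = 1,
                       cohort = cohort_config(seed = seed),
                       sim_theta = theta_final(), sim_omega = 0.2145,
                       sim_sigma = sigma_pair(0.25, 1.51),
                       final_spec = model_spec(
                         cont = c(egfr = 115.2, wt = 70),
                         cat = "mannitol"),
                       n_boot = 200, n_sim_vpc = 500,
                       dose_grid = list()) {
  stages <- match.arg(stages, several.ok = TRUE)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order: simulate (or load) the dataset,
#' fit the base model, stepwise covariate selection, fit the final model
#' (with standard errors), subject-level bootstrap, visual predictive
#' check, and the Monte Carlo dose table. Every product is written to
#' `out_dir` as a delimited text file whose first line is a comment
#' embedding the run seed and the MD5 hash of the serialised
#' configuration; `run_log.json` records seeds, stage status and output
#' files so a rerun with the same configuration reproduces the run
#' exactly. A stage failure aborts the pipeline but earlier products and
#' the log (with a failure record) are preserved.
#'
#' @param config a [run_config()].
#' @return the output directory, invisibly; the run log as attribute
#'   `"log"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_txt <- paste(utils::capture.output(utils::str(
    config[setdiff(names(config), "out_dir")], give.attr = FALSE)),
    collapse = "\n")
  cfg_file <- file.path(config$out_dir, "config.txt")
  writeLines(cfg_txt, cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  stamp <- sprintf("seed=%d config_md5=%s", config$seed, cfg_hash)
  log <- list(seed = config$seed, config_md5 = cfg_hash,
              package_version = as.character(utils::packageVersion("vancoppk")),
              stages = list(), outputs = character())
  write_log <- function() {
    jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  emit <- function(df, name) {
    p <- file.path(config$out_dir, name)
    con <- file(p, "w")
    writeLines(paste("#", stamp), con)
    suppressWarnings(write.csv(df, con, row.names = FALSE))
    close(con)
    log$outputs <<- c(log$outputs, name)
    p
  }
  run_stage <- function(name, expr) {
    res <- try(expr, silent = TRUE)
    if (inherits(res, "try-error")) {
      log$stages[[name]] <<- list(status = "failed",
                                  error = as.character(res))
      write_log()
      stop("stage '", name, "' failed: ", as.character(res))
    }
    log$stages[[name]] <<- list(status = "ok")
    res
  }
  stages <- config$stages
  needs_data <- any(c("simulate", "fit_base", "stepwise", "fit_final",
                      "bootstrap", "vpc") %in% stages)

  data <- if (!needs_data) NULL else run_stage("data", {
    if ("simulate" %in% stages) {
      cohort <- generate_cohort(config$cohort)
      sim <- simulate_observations(cohort, config$sim_theta,
                                   config$sim_omega, config$sim_sigma,
                                   seed = config$seed + 1L)
      write_pk_dataset(sim, file.path(config$out_dir, "dataset.csv"),
                       truth_path = file.path(config$out_dir,
                                              "cohort_truth.csv"),
                       comment = stamp)
      log$outputs <- c(log$outputs, "dataset.csv", "cohort_truth.csv")
      sim
    } else {
      if (is.null(config$dataset))
        stop("no dataset path supplied and simulate stage not enabled")
      read_pk_dataset(config$dataset, config$scr_unit)
    }
  })

  base_fit <- NULL
  if (any(c("fit_base", "stepwise") %in% stages))
    base_fit <- run_stage("fit_base", {
      f <- fit_ppk(model_spec(v = config$final_spec$v), data)
      emit(f$estimates, "base_parameters.csv")
      f
    })

  final_spec <- config$final_spec
  if ("stepwise" %in% stages) {
    sw <- run_stage("stepwise", {
      sw <- run_stepwise(model_spec(v = config$final_spec$v),
                         covariate_candidates(), data)
      emit(sw$log, "step_log.csv")
      emit(sw$steps, "step_records.csv")
      sw
    })
    final_spec <- sw$spec
  }

  final_fit <- NULL
  if (any(c("fit_final", "bootstrap", "vpc") %in% stages))
    final_fit <- run_stage("fit_final", {
      f <- fit_ppk(final_spec, data)
      emit(f$estimates, "final_parameters.csv")
      emit(cwres(f, data), "diagnostics.csv")
      f
    })

  if ("bootstrap" %in% stages)
    run_stage("bootstrap", {
      b <- bootstrap_ppk(final_spec, data, n_boot = config$n_boot,
                         seed = config$seed + 2L, ref_fit = final_fit)
      emit(b$summary, "bootstrap.csv")
      b
    })

  if ("vpc" %in% stages)
    run_stage("vpc", {
      v <- vpc_ppk(final_fit, data, n_sim = config$n_sim_vpc,
                   seed = config$seed + 3L)
      emit(v$bins, "vpc_bins.csv")
      emit(v$obs, "vpc_observations.csv")
      log$stages$vpc$coverage <- v$coverage
      v
    })

  if ("dose_table" %in% stages)
    run_stage("dose_table", {
      theta <- if (!is.null(final_fit)) final_fit$theta else config$sim_theta
      omega <- if (!is.null(final_fit)) final_fit$omega_cl else
        config$sim_omega
      args <- c(list(theta = theta, omega_cl = omega,
                     seed = config$seed + 4L), config$dose_grid)
      emit(do.call(build_dose_table, args), "dose_table.csv")
    })

  write_log()
  structure(invisible(config$out_dir), log = log)
}
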