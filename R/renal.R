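#' Convert serum creatinine from umol/L to mg/dL
#'
#' Clinical laboratories in China typically report serum creatinine in
#' umol/L, while the Cockcroft-Gault and CKD-EPI equations take mg/dL.
#' The molar mass of creatinine gives the conversion factor 88.4.
#'
#' @param scr_umol serum creatinine in umol/L (positive).
#' @return serum creatinine in mg/dL.
#' @export
#' @examples
#' scr_umol_to_mgdl(88.4) # 1
scr_umol_to_mgdl <- function(scr_umol) {
  if (any(!is.finite(scr_umol)) || any(scr_umol <= 0))
    stop("serum creatinine must be positive and finite")
  scr_umol / 88.4
}

.check_renal_input <- function(age, sex, scr) {
  if (any(!is.finite(scr)) || any(scr <= 0))
    stop("serum creatinine must be positive and finite")
  if (any(!is.finite(age)) || any(age < 0))
    stop("age must be non-negative")
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  invisible(TRUE)
}

#' Cockcroft-Gault creatinine clearance
#'
#' CLcr (mL/min) = (140 - age) * BW / (Scr * 72), multiplied by 0.85 for
#' females. Reported without body-surface-area normalisation. Values above
#' 300 mL/min are physiologically extreme (augmented renal clearance is
#' common in neurocritical care) and are flagged with a message, never
#' capped.
#'
#' @param age years.
#' @param sex `"male"` or `"female"` (vectorised).
#' @param weight body weight, kg.
#' @param scr serum creatinine, mg/dL.
#' @return creatinine clearance, mL/min.
#' @export
#' @examples
#' cockcroft_gault(40, "male", 72, 1.0) # 100
cockcroft_gault <- function(age, sex, weight, scr) {
  .check_renal_input(age, sex, scr)
  if (any(!is.finite(weight)) || any(weight <= 0))
    stop("body weight must be positive")
  clcr <- (140 - age) * weight / (scr * 72)
  clcr <- ifelse(sex == "female", clcr * 0.85, clcr)
  if (any(clcr > 300))
    message(sum(clcr > 300), " CLcr value(s) > 300 mL/min (not capped)")
  clcr
}

#' CKD-EPI estimated glomerular filtration rate
#'
#' eGFR (mL/min) = 144 * (Scr/a)^b * 0.993^age with sex-specific constants:
#' female a = 0.7 (b = -0.329 for Scr <= 0.7, b = -1.209 above), male
#' a = 0.9 (b = -0.411 for Scr <= 0.9, b = -1.210 above). The two branches
#' agree exactly at Scr = a, so eGFR is continuous in Scr.
#'
#' @inheritParams cockcroft_gault
#' @return estimated GFR, mL/min.
#' @export
#' @examples
#' ckd_epi(52, "male", 0.7339)
ckd_epi <- function(age, sex, scr) {
  .check_renal_input(age, sex, scr)
  n <- max(length(age), length(sex), length(scr))
  age <- rep_len(age, n); sex <- rep_len(sex, n); scr <- rep_len(scr, n)
  a <- ifelse(sex == "female", 0.7, 0.9)
  b <- ifelse(sex == "female",
              ifelse(scr <= 0.7, -0.329, -1.209),
              ifelse(scr <= 0.9, -0.411, -1.210))
  144 * (scr / a)^b * 0.993^age
}

#' Invert the CKD-EPI equation for serum creatinine
#'
#' Given a target eGFR, age and sex, returns the serum creatinine that the
#' CKD-EPI equation maps to that eGFR. Used by the synthetic-cohort
#' generator to couple creatinine to age and sex so that the implied renal
#' function matches a prescribed distribution.
#'
#' @param egfr target eGFR, mL/min (positive).
#' @inheritParams cockcroft_gault
#' @return serum creatinine, mg/dL.
#' @export
ckd_epi_inverse <- function(egfr, age, sex) {
  if (any(!is.finite(egfr)) || any(egfr <= 0))
    stop("egfr must be positive")
  n <- max(length(egfr), length(age), length(sex))
  egfr <- rep_len(egfr, n); age <- rep_len(age, n); sex <- rep_len(sex, n)
  a <- ifelse(sex == "female", 0.7, 0.9)
  b_low <- ifelse(sex == "female", -0.329, -0.411)
  b_high <- ifelse(sex == "female", -1.209, -1.210)
  x <- egfr / (144 * 0.993^age)
  # x >= 1 corresponds to Scr <= a (the shallow branch), x < 1 to Scr > a
  ifelse(x >= 1, a * x^(1 / b_low), a * x^(1 / b_high))
}
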