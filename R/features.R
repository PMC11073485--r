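#' Heart rate of a cardiac cycle
#'
#' @param cycle A [cardiac_cycle] (or any list with a `T` element, seconds).
#' @return Heart rate in bpm, `60 / T`.
#' @export
compute_heart_rate <- function(cycle) {
  Tdur <- if (is.list(cycle)) cycle$T else cycle
  if (!is_number(Tdur) || Tdur <= 0) abort_domain("cycle duration must be > 0")
  60 / Tdur
}

#' Heart-rate-normalized systolic intrinsic frequency
#'
#' `omegai1 = omega1 [bpm] / HR [bpm]`, a unitless index that compensates
#' for the age-dependent heart rate in children.
#'
#' @param omega1_bpm Systolic intrinsic frequency in bpm.
#' @param HR Heart rate in bpm, positive.
#' @return Unitless ratio.
#' @export
normalize_omega1 <- function(omega1_bpm, HR) {
  if (any(!is.finite(HR)) || any(HR <= 0)) abort_domain("HR must be > 0")
  omega1_bpm / HR
}

#' Per-cycle feature vector from a fitted model
#'
#' @param fit An [fit_if()] result.
#' @return One-row data frame with `omega1_bpm`, `omega2_bpm`, `phi1`,
#'   `phi2`, `Rs`, `Rd`, `HR` (bpm) and `omegai1`.
#' @export
cycle_features <- function(fit) {
  stopifnot(inherits(fit, "if_fit"))
  p <- fit$params
  HR <- 60 / fit$T
  o1 <- to_bpm(p$omega1)
  data.frame(omega1_bpm = o1, omega2_bpm = to_bpm(p$omega2),
             phi1 = p$phi1, phi2 = p$phi2, Rs = p$Rs, Rd = p$Rd,
             HR = HR, omegai1 = normalize_omega1(o1, HR),
             residual = fit$residual)
}

#' Age-group bracket
#'
#' Integer-year brackets 0-6, 7-13 and 14-20; fractional ages floor to whole
#' years, and ages above 20 fall in the oldest bracket.
#'
#' @param age Age in years (vectorized).
#' @return Factor with levels `"0-6"`, `"7-13"`, `"14-20"`.
#' @export
age_group <- function(age) {
  yr <- floor(age)
  factor(ifelse(yr <= 6, "0-6", ifelse(yr <= 13, "7-13", "14-20")),
         levels = c("0-6", "7-13", "14-20"))
}

#' Aggregate cycle features into one subject record
#'
#' The protocol averages the fitted parameters of the selected cycles
#' (arithmetic mean, per feature) rather than refitting an averaged beat,
#' so each subject carries exactly one feature set. The binary screening
#' label is positive for `lvef < 50` (strictly; 50% exactly is negative).
#'
#' @param features Data frame of per-cycle features from [cycle_features()]
#'   (one row per selected cycle).
#' @param subject_id Subject identifier.
#' @param age Age in years.
#' @param lvef Left-ventricular ejection fraction in percent, or `NA` when
#'   unlabelled.
#' @param circular_phi Average phases on the circle instead of
#'   arithmetically (default off; per-subject phase spread is small).
#' @return One-row data frame: `subject_id`, `age`, `age_group`, `lvef`,
#'   `label`, averaged features, `n_cycles`, `insufficient`.
#' @export
aggregate_subject <- function(features, subject_id, age, lvef = NA_real_,
                              circular_phi = FALSE) {
  if (is.null(features) || nrow(features) == 0L)
    abort_data("no cycle features to aggregate")
  avg <- function(x) mean(x)
  cavg <- function(x) atan2(mean(sin(x)), mean(cos(x)))
  phi_fun <- if (circular_phi) cavg else avg
  data.frame(
    subject_id = as.character(subject_id),
    age = age,
    age_group = age_group(age),
    lvef = lvef,
    label = if (is.na(lvef)) NA else lvef < 50,
    omega1_bpm = avg(features$omega1_bpm),
    omega2_bpm = avg(features$omega2_bpm),
    phi1 = phi_fun(features$phi1),
    phi2 = phi_fun(features$phi2),
    Rs = avg(features$Rs),
    Rd = avg(features$Rd),
    HR = avg(features$HR),
    omegai1 = avg(features$omegai1),
    residual = if ("residual" %in% names(features)) avg(features$residual)
               else NA_real_,
    n_cycles = nrow(features),
    insufficient = nrow(features) < 3L,
    stringsAsFactors = FALSE)
}
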