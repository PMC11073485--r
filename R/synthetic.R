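#' Left-ventricular ejection fraction from ventricular volumes
#'
#' `LVEF = 100 * (EDV - ESV) / EDV` in percent.
#'
#' @param edv End-diastolic volume in mL, positive.
#' @param esv End-systolic volume in mL, `0 <= esv <= edv`.
#' @return Ejection fraction in percent (vectorized).
#' @export
compute_lvef <- function(edv, esv) {
  if (any(!is.finite(edv)) || any(edv <= 0)) abort_domain("EDV must be > 0")
  if (any(!is.finite(esv)) || any(esv < 0)) abort_domain("ESV must be >= 0")
  if (any(esv > edv)) abort_domain("ESV cannot exceed EDV")
  100 * (edv - esv) / edv
}

#' Cohort generator configuration
#'
#' Defines the synthetic study conditions: cohort size and low-LVEF
#' prevalence, the pediatric age-group mix, the age-to-heart-rate mapping,
#' the planted low-LVEF effects on the systolic intrinsic parameters, the
#' within-group spreads, and the waveform noise model. Defaults mirror a
#' pediatric screening cohort: 50 subjects with 32% prevalence (a 16/50
#' split), equal thirds in the 0-6 / 7-13 / 14-20 year brackets, group mean
#' heart rates 110 / 85 / 70 bpm, and low-LVEF subjects shifted upward in
#' omega1 (+15 bpm, three within-group SDs) and downward in phi1
#' (-0.5 rad). The heart-rate means and effect magnitudes are generator
#' conventions chosen to be physiologically plausible; only the effect
#' directions are anchored to reported group differences.
#'
#' @param n Number of subjects.
#' @param prevalence Fraction with low LVEF; the positive count is
#'   `round(prevalence * n)`.
#' @param age_group_weights Sampling weights of the three age groups.
#' @param hr_means,hr_sd Heart-rate means per age group and common SD (bpm).
#' @param omega1_ratio Baseline `omega1 / HR` ratio of normal subjects.
#' @param omega1_sd Within-group SD of omega1 (bpm).
#' @param delta_omega1 Additive omega1 shift for low-LVEF subjects (bpm).
#' @param delta_omegai1 Additional omega1 shift expressed per unit of HR
#'   (plants an omegai1 offset directly; default 0).
#' @param phi1_mean,phi1_sd Baseline phi1 distribution (rad).
#' @param delta_phi1 Additive phi1 shift for low-LVEF subjects (rad).
#' @param omega2_ratio,omega2_sd Diastolic frequency as a fraction of HR
#'   and its SD (bpm).
#' @param t0_frac,t0_jitter Systolic fraction of the cycle and its SD.
#' @param rs_meanlog,rs_sdlog Lognormal systolic envelope parameters.
#' @param baseline Constant pressure offset (arbitrary units).
#' @param noise_sd Additive white-noise SD as a fraction of pulse
#'   amplitude.
#' @param drift_amp Amplitude of a slow sinusoidal baseline drift, as a
#'   fraction of pulse amplitude (0 disables).
#' @param drift_freq Drift frequency in Hz.
#' @param cycles_per_subject Beats per recording.
#' @param sampling_rate Sampling rate in Hz.
#' @param seed Mandatory integer seed; every draw derives from it.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n = 50L, prevalence = 0.32,
                          age_group_weights = c(1, 1, 1) / 3,
                          hr_means = c(110, 85, 70), hr_sd = 10,
                          omega1_ratio = 1.15, omega1_sd = 5,
                          delta_omega1 = 15, delta_omegai1 = 0,
                          phi1_mean = 0, phi1_sd = 0.15, delta_phi1 = -0.5,
                          omega2_ratio = 0.55, omega2_sd = 3,
                          t0_frac = 0.35, t0_jitter = 0.02,
                          rs_meanlog = 0, rs_sdlog = 0.1, baseline = 2,
                          noise_sd = 0.02, drift_amp = 0, drift_freq = 0.2,
                          cycles_per_subject = 7L, sampling_rate = 250,
                          seed = NULL) {
  if (is.null(seed) || !is_number(seed)) abort_config("seed is mandatory")
  if (!is_number(n) || n < 1) abort_config("n must be >= 1")
  if (!is_number(prevalence) || prevalence < 0 || prevalence > 1)
    abort_config("prevalence must be in [0, 1]")
  if (length(age_group_weights) != 3L || any(age_group_weights < 0) ||
      sum(age_group_weights) <= 0)
    abort_config("age_group_weights must be 3 nonnegative weights")
  for (v in list(hr_sd, omega1_sd, omega2_sd, phi1_sd, t0_jitter, noise_sd,
                 drift_amp))
    if (!is_number(v) || v < 0) abort_config("SDs and amplitudes must be >= 0")
  if (!is_number(cycles_per_subject) || cycles_per_subject < 2)
    abort_config("cycles_per_subject must be >= 2")
  if (!is_number(sampling_rate) || sampling_rate <= 0)
    abort_config("sampling_rate must be > 0")
  cfg <- list(n = as.integer(n), prevalence = prevalence,
              age_group_weights = age_group_weights / sum(age_group_weights),
              hr_means = hr_means, hr_sd = hr_sd,
              omega1_ratio = omega1_ratio, omega1_sd = omega1_sd,
              delta_omega1 = delta_omega1, delta_omegai1 = delta_omegai1,
              phi1_mean = phi1_mean, phi1_sd = phi1_sd,
              delta_phi1 = delta_phi1,
              omega2_ratio = omega2_ratio, omega2_sd = omega2_sd,
              t0_frac = t0_frac, t0_jitter = t0_jitter,
              rs_meanlog = rs_meanlog, rs_sdlog = rs_sdlog,
              baseline = baseline, noise_sd = noise_sd,
              drift_amp = drift_amp, drift_freq = drift_freq,
              cycles_per_subject = as.integer(cycles_per_subject),
              sampling_rate = sampling_rate, seed = as.integer(seed))
  structure(cfg, class = "cohort_config")
}

# Draw one subject's ground truth. Runs inside the subject's seed stream.
draw_subject_truth <- function(cfg, i, positive) {
  group <- sample.int(3L, 1L, prob = cfg$age_group_weights)
  age_lo <- c(0, 7, 14)[group]; age_hi <- c(7, 14, 21)[group]
  age <- stats::runif(1, age_lo, age_hi)
  HR <- min(max(stats::rnorm(1, cfg$hr_means[group], cfg$hr_sd), 45), 190)
  # snap the period to the sampling grid so sampled cycles are exactly
  # representable by the closure-constrained model (T = n / fs)
  Tdur <- round(60 / HR * cfg$sampling_rate) / cfg$sampling_rate
  HR <- 60 / Tdur
  T0 <- min(max((cfg$t0_frac + stats::rnorm(1, 0, cfg$t0_jitter)) * Tdur,
                0.2 * Tdur), 0.5 * Tdur)
  omega1_bpm <- cfg$omega1_ratio * HR + stats::rnorm(1, 0, cfg$omega1_sd) +
    positive * (cfg$delta_omega1 + cfg$delta_omegai1 * HR)
  omega1_bpm <- min(max(omega1_bpm, 45), 295)
  phi1 <- cfg$phi1_mean + stats::rnorm(1, 0, cfg$phi1_sd) +
    positive * cfg$delta_phi1
  # diastolic frequency: keep the closure solve well conditioned,
  # |sin(omega2 (T - T0))| bounded away from 0
  omega2_bpm <- NA_real_
  for (try in 1:50) {
    cand <- cfg$omega2_ratio * HR + stats::rnorm(1, 0, cfg$omega2_sd)
    cand <- min(max(cand, 25), 195)
    if (abs(sin(from_bpm(cand) * (Tdur - T0))) >= 0.25) {
      omega2_bpm <- cand; break
    }
  }
  if (is.na(omega2_bpm)) omega2_bpm <- cfg$omega2_ratio * HR
  Rs <- stats::rlnorm(1, cfg$rs_meanlog, cfg$rs_sdlog)
  edv <- stats::rlnorm(1, log(100), 0.3)
  ef <- NA_real_
  repeat {   # rejection: EF drawn on the labelled side of 50%
    ef <- if (positive) stats::rnorm(1, 40, 8) else stats::rnorm(1, 62, 6)
    if (positive && ef < 50 && ef > 15) break
    if (!positive && ef >= 50 && ef < 80) break
  }
  esv <- edv * (1 - ef / 100)
  params <- if_params_constrained(from_bpm(omega1_bpm), from_bpm(omega2_bpm),
                                  T0, Tdur, Rs = Rs, phi1 = phi1,
                                  c = cfg$baseline)
  list(subject_id = sprintf("S%03d", i), age = age, HR = HR, T = Tdur,
       T0 = T0, params = params, EDV = edv, ESV = esv,
       lvef = compute_lvef(edv, esv),
       label = compute_lvef(edv, esv) < 50)
}

#' Generate one noisy forward-model cycle
#'
#' Samples the subject's exact piecewise two-sinusoid model on a uniform
#' grid and adds white noise scaled to the pulse amplitude. Deterministic
#' for a fixed seed. The truth parameters must satisfy the continuity and
#' closure constraints (the generator refuses unfittable cycles).
#'
#' @param truth A subject truth entry from [gen_cohort()] (list with
#'   `params`, `T0`, `T`) or an [if_params] with `T0`, `T` supplied.
#' @param noise_sd Noise SD as a fraction of pulse amplitude.
#' @param seed Integer seed.
#' @param sampling_rate Sampling rate in Hz.
#' @return A [cardiac_cycle] carrying the true `T0`.
#' @export
gen_cycle <- function(truth, noise_sd = 0.02, seed = 1L, sampling_rate = 250) {
  pars <- truth$params; T0 <- truth$T0; Tdur <- truth$T
  stopifnot(inherits(pars, "if_params"))
  # verify the constraint set before generating
  v0 <- pars$c + pars$a1
  vT0s <- pars$c + pars$a1 * cos(pars$omega1 * T0) + pars$b1 * sin(pars$omega1 * T0)
  vT0d <- pars$c + pars$a2 * cos(pars$omega2 * T0) + pars$b2 * sin(pars$omega2 * T0)
  vT <- pars$c + pars$a2 * cos(pars$omega2 * Tdur) + pars$b2 * sin(pars$omega2 * Tdur)
  scale <- max(abs(c(pars$Rs, pars$Rd, 1)))
  if (abs(vT0s - vT0d) > 1e-8 * scale || abs(vT - v0) > 1e-8 * scale)
    abort_domain("truth parameters violate the continuity/closure constraints")
  nsmp <- round(Tdur * sampling_rate)
  tt <- (seq_len(nsmp) - 1L) / sampling_rate
  mu <- reconstruct(pars, T0, Tdur, tt)
  amp <- diff(range(mu))
  p <- with_seed(seed, mu + stats::rnorm(nsmp, 0, noise_sd * amp))
  cardiac_cycle(p, sampling_rate, T0,
                subject_id = truth$subject_id %||% "synthetic")
}

#' Generate a synthetic cohort of recordings with ground truth
#'
#' Draws `n` subjects with age-stratified heart rates and a planted
#' low-LVEF effect (elevated omega1/omegai1, reduced phi1), builds each
#' subject's exact forward-model cycle, and concatenates noisy beats into a
#' continuous recording per subject. Each subject uses an independent seed
#' stream derived from the cohort seed and the subject index, so the cohort
#' is fully reproducible and insertion-order independent.
#'
#' @param cfg A [cohort_config()].
#' @return List with `waveforms` (named list of [waveform]), `truth` (data
#'   frame: `subject_id`, `age`, `HR`, `T`, `T0`, `lvef`, `label`, `EDV`,
#'   `ESV`, true parameter columns) and `config`.
#' @export
gen_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  n_pos <- round(cfg$prevalence * cfg$n)
  if (cfg$prevalence > 0 && n_pos < 1)
    warning("prevalence * n < 1: cohort has 0 positive subjects", call. = FALSE)
  pos_idx <- with_seed(mix_seed(cfg$seed, 0L),
                       sample.int(cfg$n, n_pos))
  truths <- lapply(seq_len(cfg$n), function(i) {
    with_seed(mix_seed(cfg$seed, i),
              draw_subject_truth(cfg, i, i %in% pos_idx))
  })
  waveforms <- lapply(seq_len(cfg$n), function(i) {
    tr <- truths[[i]]
    cyc <- lapply(seq_len(cfg$cycles_per_subject), function(j) {
      gen_cycle(tr, cfg$noise_sd, mix_seed(cfg$seed, i * 1000L + j),
                cfg$sampling_rate)$pressure
    })
    p <- unlist(cyc)
    tt <- (seq_along(p) - 1L) / cfg$sampling_rate
    if (cfg$drift_amp > 0) {
      amp <- diff(range(p))
      p <- p + cfg$drift_amp * amp * sin(2 * pi * cfg$drift_freq * tt)
    }
    waveform(tt, p, tr$subject_id)
  })
  names(waveforms) <- vapply(truths, function(tr) tr$subject_id, character(1))
  truth <- do.call(rbind, lapply(truths, function(tr) {
    p <- tr$params
    data.frame(subject_id = tr$subject_id, age = tr$age, HR = tr$HR,
               T = tr$T, T0 = tr$T0, EDV = tr$EDV, ESV = tr$ESV,
               lvef = tr$lvef, label = tr$label,
               true_omega1_bpm = to_bpm(p$omega1),
               true_omega2_bpm = to_bpm(p$omega2),
               true_phi1 = p$phi1, true_phi2 = p$phi2,
               true_Rs = p$Rs, true_Rd = p$Rd, true_c = p$c,
               true_omegai1 = to_bpm(p$omega1) / tr$HR,
               stringsAsFactors = FALSE)
  }))
  list(waveforms = waveforms, truth = truth, truths = truths, config = cfg)
}
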