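# Shared fixture builders: exact forward-model cycles with known truth.

# Draw one admissible truth parameter set inside the default grid range.
# Keeps the diastolic closure solve well conditioned and the period on the
# sampling grid so the cycle is exactly representable.
random_truth <- function(fs = 250) {
  repeat {
    HR <- stats::runif(1, 55, 150)
    Tdur <- round(60 / HR * fs) / fs
    T0 <- stats::runif(1, 0.28, 0.42) * Tdur
    om1 <- from_bpm(stats::runif(1, 60, 250))
    om2 <- from_bpm(stats::runif(1, 30, 180))
    if (abs(sin(om2 * (Tdur - T0))) < 0.25) next
    if (abs(sin(om1 * T0)) < 0.1) next
    n_sys <- sum(((seq_len(round(Tdur * fs)) - 1) / fs) < T0)
    if (n_sys < 16 || round(Tdur * fs) - n_sys < 16) next
    phi1 <- stats::runif(1, -0.7, 0.4)
    pars <- tryCatch(
      if_params_constrained(om1, om2, T0, Tdur,
                            Rs = stats::runif(1, 0.5, 2), phi1 = phi1,
                            c = stats::runif(1, 0, 5)),
      error = function(e) NULL)
    if (is.null(pars)) next
    return(list(params = pars, T0 = T0, T = Tdur, subject_id = "fixture"))
  }
}

# Noise-free or noisy sampled cycle from a truth list.
truth_cycle <- function(truth, noise_sd = 0, seed = 1, fs = 250) {
  gen_cycle(truth, noise_sd = noise_sd, seed = seed, sampling_rate = fs)
}

# Random truth restricted to notch-bearing morphologies: systolic pressure
# falling into the junction and diastolic pressure rising out of it (a
# dicrotic wave), with no competing sinusoid minimum inside the search
# window. Conditions are analytic (slopes of the two branches), not based
# on the estimator under test.
notched_truth <- function(fs = 250) {
  repeat {
    tr <- random_truth(fs)
    p <- tr$params
    s_slope <- p$Rs * p$omega1 * cos(p$omega1 * tr$T0 + p$phi1)
    d_slope <- p$Rd * p$omega2 * cos(p$omega2 * tr$T0 + p$phi2)
    if (s_slope > -0.15 * p$Rs * p$omega1) next
    if (d_slope < 0.15 * p$Rd * p$omega2) next
    # systolic branch: no interior minimum before T0
    if (p$omega1 * tr$T0 + p$phi1 > 3 * pi / 2) next
    # diastolic branch: no second minimum inside the search window
    if (p$omega2 * 0.6 * tr$T + p$phi2 > 3 * pi / 2) next
    return(tr)
  }
}

# A standard well-behaved truth used across tests (90 bpm beat).
canonical_truth <- function(fs = 500, HR = 75, T0_frac = 0.375,
                            phi1 = -0.1, om1_bpm = 90, om2_bpm = 48) {
  Tdur <- round(60 / HR * fs) / fs
  list(params = if_params_constrained(from_bpm(om1_bpm), from_bpm(om2_bpm),
                                      T0_frac * Tdur, Tdur,
                                      Rs = 1, phi1 = phi1, c = 2),
       T0 = T0_frac * Tdur, T = Tdur, subject_id = "canon")
}

# Recording that concatenates identical noisy beats of one truth.
truth_recording <- function(truth, n_beats, noise_sd = 0, seed = 1, fs = 250) {
  p <- unlist(lapply(seq_len(n_beats), function(j) {
    gen_cycle(truth, noise_sd, seed + j, sampling_rate = fs)$pressure
  }))
  waveform((seq_along(p) - 1) / fs, p, "rec")
}

# Exhaustive-search oracle for the single best Gini split of a data set:
# every (feature, midpoint) candidate scored by brute force. Deterministic
# tie-break mirrors the documented convention (feature order, then
# threshold).
oracle_best_split <- function(dat, predictors, label = "label") {
  gini <- function(y) { p <- mean(y); 1 - p^2 - (1 - p)^2 }
  n <- nrow(dat)
  best <- list(dec = -Inf)
  for (f in predictors) {
    xs <- sort(unique(dat[[f]]))
    if (length(xs) < 2) next
    for (thr in (utils::head(xs, -1) + utils::tail(xs, -1)) / 2) {
      l <- dat[[label]][dat[[f]] < thr]
      r <- dat[[label]][dat[[f]] >= thr]
      dec <- n * gini(dat[[label]]) - length(l) * gini(l) - length(r) * gini(r)
      if (dec > best$dec + 1e-12 * n) best <- list(dec = dec, f = f, thr = thr)
    }
  }
  best
}

# Two-threshold planted cohort: positive exactly when omega1 is above the
# (102, 112) gap AND omegai1 above the (1.32, 1.48) gap. The two decoy
# regions are placed so each feature's gap split isolates exactly one pure
# region; the gap cuts are then the strict Gini optima of their splits and
# the root tie resolves by the documented feature-order tie-break.
planted_two_threshold_cohort <- function(n_region = 14) {
  reg <- function(n, o1, oi, lab)
    data.frame(omega1_bpm = seq(o1[1], o1[2], length.out = n),
               omegai1 = seq(oi[1], oi[2], length.out = n), label = lab)
  # deterministic geometry chosen so each planted cut is the strict Gini
  # optimum of its split: the low-omega1 decoy is larger (isolating it
  # purely wins the root), and the high-omega1 negatives start above the
  # positives so the pure root threshold falls inside the planted gap
  rbind(reg(n_region + 6, c(80, 102), c(1.48, 1.9), FALSE),
        reg(n_region, c(112, 140), c(1.48, 1.9), TRUE),
        reg(n_region, c(118, 140), c(0.9, 1.32), FALSE))
}

# Check that a trained tree recovers the planted structure: at most three
# splits, training accuracy one, and each planted cut represented by a
# split threshold inside its empirical midpoint gap.
expect_planted_recovery <- function(tree, dat) {
  testthat::expect_true(audit_cart(tree))
  testthat::expect_lte(sum(!tree$leaf), 3)
  testthat::expect_identical(predict(tree, dat)$label, dat$label)
  o1_thr <- tree$threshold[!tree$leaf & tree$feature == "omega1_bpm"]
  oi_thr <- tree$threshold[!tree$leaf & tree$feature == "omegai1"]
  testthat::expect_true(any(o1_thr > 102 & o1_thr < 112))
  testthat::expect_true(any(oi_thr > 1.32 & oi_thr < 1.48))
}

# Audit the printed structural constraints of a trained tree.
audit_cart <- function(tree) {
  cons <- attr(tree, "constraints")
  splits <- sum(!tree$leaf)
  ok_budget <- splits <= cons$max_splits
  ok_size <- all(tree$n[!tree$leaf] >= cons$min_split_size)
  ok_binary <- all(!is.na(tree$left[!tree$leaf])) &&
    all(!is.na(tree$right[!tree$leaf]))
  ok_budget && ok_size && ok_binary
}
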