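test_that("reconstruction evaluates the piecewise model exactly", {
  p0 <- if_params(2 * pi, pi, 0, 0, 0, 0, 5)
  tt <- seq(0, 0.99, by = 0.01)
  expect_equal(reconstruct(p0, 0.4, 1, tt), rep(5, length(tt)))

  p1 <- if_params(2 * pi, pi, 0, 1, 0, 0, 2)
  expect_equal(reconstruct(p1, 0.4, 1, 0.25), 2 + sin(pi / 2))
  expect_error(reconstruct(p1, 1.2, 1, tt), class = "if_domain_error")
})

test_that("fit-reconstruct round trip is exact on a noiseless cycle", {
  tr <- canonical_truth(fs = 250, HR = 90, om1_bpm = 110, om2_bpm = 55)
  cy <- truth_cycle(tr, noise_sd = 0, fs = 250)
  f <- fit_if(cy)
  amp <- diff(range(cy$pressure))
  expect_lt(max(abs(predict(f) - cy$pressure)), 1e-6 * amp)
})

test_that("the linear subproblem recovers exact coefficients at the true frequencies", {
  tr <- canonical_truth(fs = 250)
  cy <- truth_cycle(tr, noise_sd = 0, fs = 250)
  p <- tr$params
  sol <- solve_linear_coeffs(cy$pressure, cy$times, tr$T0, tr$T,
                             p$omega1, p$omega2)
  truth_coef <- c(a1 = p$a1, b1 = p$b1, a2 = p$a2, b2 = p$b2, c = p$c)
  expect_equal(sol$coef, truth_coef, tolerance = 1e-8)
  expect_false(sol$degenerate)
})

test_that("unconstrained mode equals the brute-force normal-equations solution", {
  withr::local_seed(7)
  for (k in 1:10) {
    tr <- random_truth()
    cy <- truth_cycle(tr, noise_sd = 0.05, seed = k)
    om1 <- from_bpm(stats::runif(1, 60, 200))
    om2 <- from_bpm(stats::runif(1, 30, 150))
    sol <- solve_linear_coeffs(cy$pressure, cy$times, tr$T0, tr$T, om1, om2,
                               mode = "unconstrained")
    sys <- cy$times < tr$T0
    A <- cbind(cos(om1 * cy$times) * sys, sin(om1 * cy$times) * sys,
               cos(om2 * cy$times) * (!sys), sin(om2 * cy$times) * (!sys), 1)
    oracle <- solve(t(A) %*% A, t(A) %*% cy$pressure)
    expect_equal(unname(sol$coef), drop(oracle), tolerance = 1e-10)
  }
})

test_that("constraints hold exactly and can only increase the misfit", {
  withr::local_seed(21)
  for (k in 1:50) {
    tr <- random_truth()
    cy <- truth_cycle(tr, noise_sd = 0.05, seed = 100 + k)
    om1 <- from_bpm(stats::runif(1, 60, 200))
    om2 <- from_bpm(stats::runif(1, 30, 150))
    con <- solve_linear_coeffs(cy$pressure, cy$times, tr$T0, tr$T, om1, om2)
    unc <- solve_linear_coeffs(cy$pressure, cy$times, tr$T0, tr$T, om1, om2,
                               mode = "unconstrained")
    if (con$degenerate || unc$degenerate) next
    cf <- con$coef
    scale <- max(1, max(abs(cf)))
    cont <- cf["a1"] * cos(om1 * tr$T0) + cf["b1"] * sin(om1 * tr$T0) -
      cf["a2"] * cos(om2 * tr$T0) - cf["b2"] * sin(om2 * tr$T0)
    clos <- cf["a2"] * cos(om2 * tr$T) + cf["b2"] * sin(om2 * tr$T) - cf["a1"]
    expect_lt(abs(cont), 1e-10 * scale)
    expect_lt(abs(clos), 1e-10 * scale)
    expect_gte(con$objective, unc$objective - 1e-10 * (1 + unc$objective))
  }
})

test_that("fit recovers planted frequencies on a noiseless cycle", {
  fs <- 250
  Tdur <- round(60 / 60 * fs) / fs    # 60 bpm beat
  tr <- list(params = if_params_constrained(from_bpm(90), from_bpm(60),
                                            0.35 * Tdur, Tdur, Rs = 1,
                                            phi1 = -0.1, c = 2),
             T0 = 0.35 * Tdur, T = Tdur, subject_id = "x")
  f <- fit_if(truth_cycle(tr, 0, fs = fs))
  expect_lt(abs(to_bpm(f$params$omega1) - 90), 0.25)
  expect_lt(abs(to_bpm(f$params$omega2) - 60), 0.25)
  expect_lt(f$residual, 1e-6)
  expect_true(f$converged)
  expect_lte(f$objective, f$grid_objective + 1e-12)
})

test_that("frequency recovery degrades gracefully under 1% noise", {
  # the 90 / 60 bpm reference beat (T = 1 s, T0 = 0.35 s)
  tr <- canonical_truth(fs = 500, HR = 60, T0_frac = 0.35,
                        om1_bpm = 90, om2_bpm = 60)
  errs <- vapply(1:20, function(s) {
    f <- fit_if(truth_cycle(tr, noise_sd = 0.01, seed = s, fs = 500))
    to_bpm(f$params$omega1) - 90
  }, numeric(1))
  expect_lt(max(abs(errs)), 2)
})

test_that("refined objective never exceeds the coarse grid objective", {
  withr::local_seed(3)
  for (k in 1:5) {
    tr <- random_truth()
    f <- fit_if(truth_cycle(tr, noise_sd = 0.02, seed = k))
    expect_lte(f$objective, f$grid_objective + 1e-12 * (1 + f$grid_objective))
  }
})

test_that("bpm conversion matches its definition", {
  expect_equal(to_bpm(2 * pi), 60)
  expect_equal(to_bpm(0), 0)
  expect_lt(abs(to_bpm(11.27) - 107.6), 0.05)
  expect_equal(from_bpm(to_bpm(3.7)), 3.7)
})

test_that("fits are equivariant to pressure offset and positive scaling", {
  tr <- canonical_truth(fs = 250)
  cy <- truth_cycle(tr, noise_sd = 0.01, seed = 2, fs = 250)
  f0 <- fit_if(cy)
  k <- 4.2; m <- -17
  cy2 <- cy; cy2$pressure <- k * cy$pressure + m
  f1 <- fit_if(cy2)
  expect_equal(to_bpm(f1$params$omega1), to_bpm(f0$params$omega1),
               tolerance = 1e-6)
  expect_equal(to_bpm(f1$params$omega2), to_bpm(f0$params$omega2),
               tolerance = 1e-6)
  expect_equal(f1$params$phi1, f0$params$phi1, tolerance = 1e-5)
  expect_equal(f1$params$Rs, k * f0$params$Rs, tolerance = 1e-5)
  expect_equal(f1$params$c, k * f0$params$c + m, tolerance = 1e-4)
})

test_that("doubling the sampling rate barely moves the recovered frequency", {
  om1_fit <- vapply(c(250, 500), function(fs) {
    tr <- canonical_truth(fs = fs, HR = 80, om1_bpm = 100, om2_bpm = 48)
    to_bpm(fit_if(truth_cycle(tr, 0, fs = fs))$params$omega1)
  }, numeric(1))
  expect_lt(abs(om1_fit[2] - om1_fit[1]), 0.1)
})

test_that("any waveform born of the model is recovered with tiny residual", {
  withr::local_seed(11)
  for (k in 1:5) {
    tr <- random_truth()
    f <- fit_if(truth_cycle(tr, 0, seed = k))
    expect_lt(f$residual, 1e-6)
    expect_lt(abs(to_bpm(f$params$omega1) - to_bpm(tr$params$omega1)), 0.25)
  }
})

test_that("onset-shift refinement makes the fit exact on rotated cycles", {
  tr <- canonical_truth(fs = 250, HR = 80, om1_bpm = 105, om2_bpm = 52)
  w <- truth_recording(tr, 3, noise_sd = 0, fs = 250)
  nsmp <- round(tr$T * 250)
  for (d in c(1L, 3L)) {   # cut d samples before the true boundary
    pr <- w$pressure[(nsmp + 1 - d):(2 * nsmp - d)]
    est <- estimate_notch(pr, 250)
    cy <- cardiac_cycle(pr, 250, est$T0, "rot")
    f <- fit_if(cy, fit_config(refine_T0 = TRUE, refine_onset = TRUE))
    expect_lt(abs(to_bpm(f$params$omega1) - 105), 0.25)
    expect_lt(f$residual, 1e-6)
  }
})
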