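test_that("ejection fraction follows the volume formula with domain checks", {
  expect_equal(compute_lvef(100, 100), 0)
  expect_equal(compute_lvef(100, 0), 100)
  expect_equal(compute_lvef(120, 48), 60)
  expect_error(compute_lvef(100, 120), class = "if_domain_error")
  expect_error(compute_lvef(0, 0), class = "if_domain_error")
})

test_that("cycle generation is seed-deterministic with calibrated noise", {
  tr <- canonical_truth(fs = 250)
  a <- gen_cycle(tr, 0.02, seed = 7, sampling_rate = 250)
  b <- gen_cycle(tr, 0.02, seed = 7, sampling_rate = 250)
  expect_identical(a$pressure, b$pressure)
  c2 <- gen_cycle(tr, 0.02, seed = 8, sampling_rate = 250)
  expect_false(identical(a$pressure, c2$pressure))

  mu <- gen_cycle(tr, 0, seed = 1, sampling_rate = 250)$pressure
  amp <- diff(range(mu))
  many <- unlist(lapply(1:10, function(s)
    gen_cycle(tr, 0.02, seed = s, sampling_rate = 250)$pressure - mu))
  expect_lt(abs(stats::sd(many) - 0.02 * amp), 0.1 * 0.02 * amp)
})

test_that("generator refuses constraint-violating truths", {
  tr <- canonical_truth(fs = 250)
  bad <- tr
  bad$params <- if_params(tr$params$omega1, tr$params$omega2,
                          1, 1, 1, 1, 0)   # arbitrary, constraints broken
  expect_error(gen_cycle(bad, 0, seed = 1), class = "if_domain_error")
})

test_that("a 50-subject cohort at 32% prevalence plants exactly 16 positives", {
  cfg <- cohort_config(n = 50, prevalence = 0.32, seed = 123)
  coh <- gen_cohort(cfg)
  expect_equal(sum(coh$truth$label), 16)
  expect_equal(nrow(coh$truth), 50)
  expect_identical(coh$truth$label, coh$truth$lvef < 50)
  expect_identical(coh$truth$label,
                   compute_lvef(coh$truth$EDV, coh$truth$ESV) < 50)
})

test_that("cohorts are reproducible to the byte and order-independent per subject", {
  cfg <- cohort_config(n = 6, prevalence = 0.5, seed = 99,
                       cycles_per_subject = 4)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  pipeline_synth(cfg, d1)
  pipeline_synth(cfg, d2)
  for (f in list.files(d1)) {
    if (grepl("manifest", f)) next
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("generated recordings pass waveform invariants and segment fully", {
  cfg <- cohort_config(n = 5, prevalence = 0.4, seed = 7,
                       cycles_per_subject = 6)
  coh <- gen_cohort(cfg)
  for (w in coh$waveforms) {
    expect_s3_class(w, "waveform")
    cycles <- suppressWarnings(segment_cycles(w, detect_beats(w)))
    expect_gte(length(cycles), cfg$cycles_per_subject - 1)
  }
})

test_that("a null effect with zero spread gives indistinguishable classes", {
  cfg <- cohort_config(n = 24, prevalence = 0.5, seed = 5,
                       delta_omega1 = 0, delta_phi1 = 0,
                       omega1_sd = 0, phi1_sd = 0, hr_sd = 0,
                       age_group_weights = c(1, 0, 0))
  coh <- gen_cohort(cfg)
  pos <- coh$truth[coh$truth$label, ]
  neg <- coh$truth[!coh$truth$label, ]
  expect_equal(mean(pos$true_omega1_bpm), mean(neg$true_omega1_bpm),
               tolerance = 1e-10)
  dat <- data.frame(subject_id = coh$truth$subject_id,
                    omega1_bpm = coh$truth$true_omega1_bpm,
                    omegai1 = coh$truth$true_omegai1,
                    label = coh$truth$label)
  tree <- train_cart(dat, c("omega1_bpm", "omegai1"))
  expect_equal(sum(!tree$leaf), 0)
})

test_that("fitted subject parameters recover generator truth on clean data", {
  cfg <- cohort_config(n = 6, prevalence = 0.5, noise_sd = 0, seed = 31,
                       cycles_per_subject = 4)
  coh <- gen_cohort(cfg)
  for (i in seq_len(cfg$n)) {
    tr <- coh$truths[[i]]
    f <- fit_if(gen_cycle(tr, 0, seed = 1, sampling_rate = 250))
    expect_lt(abs(to_bpm(f$params$omega1) - to_bpm(tr$params$omega1)), 0.25)
    expect_lt(abs(f$params$phi1 - tr$params$phi1), 0.01)
  }
})

test_that("prevalence too small for one positive warns and yields none", {
  cfg <- cohort_config(n = 4, prevalence = 0.1, seed = 3)
  expect_warning(coh <- gen_cohort(cfg), "0 positive")
  expect_equal(sum(coh$truth$label), 0)
})
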