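# ifscreen

Intrinsic-frequency analysis of carotid pressure waveforms and
decision-tree screening for low left-ventricular ejection fraction (LVEF).

## What this package does

Non-invasive carotid tonometry yields an uncalibrated pressure waveform
`p(t)`. Treating the left ventricle plus the arterial tree as a coupled
dynamical system that decouples at aortic-valve closure (the dicrotic
notch, time `T0`), each cardiac cycle is modelled as a piecewise pair of
sinusoids and fitted by least squares:

```
minimize  || p(t) − χ(0,T0)[a1 cos ω1 t + b1 sin ω1 t]
                 − χ(T0,T)[a2 cos ω2 t + b2 sin ω2 t] − c ||²
```

subject to pressure continuity at `T0` and closure `p(T) = p(0)`. The
systolic and diastolic *intrinsic frequencies* `ω1`, `ω2` (reported in
bpm), the intrinsic phases `φi = atan2(ai, bi)` and envelopes
`Rs`, `Rd` summarize ventricular–arterial coupling; the unitless index
`ωi1 = ω1/HR` compensates for the age dependence of pediatric heart
rate. Low LVEF (`< 50%`) is screened with two published fixed decision
rules — thresholds `ω1 = 107.6` bpm, age 6 y, `φ1 = −0.65` rad, and
`ωi1 = 1.6 / 1.22` — and with constrained CART classifiers (at most
`1 + #predictors` splits, nodes split only above 10 samples) evaluated by
deterministic leave-one-out cross-validation and ROC/AUC.

The package is aimed at researchers in physiological signal processing
who need a reproducible, fully tested implementation of this analysis
chain: waveform I/O and beat segmentation, notch estimation and quality
scoring, the global two-frequency fit, feature derivation, the screening
classifiers, and a seeded synthetic-cohort generator built on the exact
forward model (the clinical cohort behind the original report is not
publicly deposited, so all quantitative validation here is against
synthetic ground truth).

## Worked example

```r
library(ifscreen)

# one synthetic beat with known truth: omega1 = 90 bpm, omega2 = 50 bpm
Tdur <- 0.8
truth <- list(params = if_params_constrained(from_bpm(90), from_bpm(50),
                                             T0 = 0.3, T = Tdur,
                                             Rs = 1, phi1 = -0.1, c = 2),
              T0 = 0.3, T = Tdur)
cycle <- gen_cycle(truth, noise_sd = 0.01, seed = 7, sampling_rate = 500)
fit <- fit_if(cycle)
summary(fit)
```

```
Intrinsic-frequency fit (continuity+closure)
  n = 400 samples, T = 0.800 s, T0 = 0.300 s
  omega1 = 89.63 bpm   omega2 = 49.64 bpm
  phi1 = -0.093 rad     phi2 = -0.871 rad
  Rs = 1.007  Rd = 0.6444  c = 1.995
  relative residual = 0.0399  (converged: TRUE)
```

The planted frequencies are recovered to a fraction of a bpm at 1%
noise, and `phi1` to about 0.01 rad. A full cohort run:

```r
dir <- tempfile("cohort")
pipeline_synth(cohort_config(n = 30, prevalence = 0.4, noise_sd = 0.01,
                             seed = 42), dir)
feats <- pipeline_extract(dir, verbose = FALSE)
res <- pipeline_screen(feats, out_dir = dir)
res$cart_loocv
```

```
<screening_report>
<confusion> TP=11 FP=1 TN=17 FN=1
  sensitivity = 0.917, specificity = 0.944, accuracy = 0.933, AUC = 0.887
```

One row per subject lands in `features.csv` (columns
`subject_id, age, age_group, lvef, label, omega1_bpm, phi1, HR, omegai1, ...`),
the screening report in `report.json`, and the pooled LOOCV ROC in
`roc_loocv.csv`. The numbers above say: on a 30-subject synthetic cohort
with the default planted effect (+15 bpm on `ω1` for low-LVEF subjects,
three within-group SDs), 28 of 30 held-out subjects are classified
correctly; the AUC is coarser than the accuracy suggests because a
constrained tree emits only a handful of distinct leaf scores to rank by.

A thin command-line wrapper over the same functions ships in
`inst/cli/ifscreen.R` (`synth`, `extract`, `screen`, `run-all`
subcommands with `--config`, `--seed`, `--out`).

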