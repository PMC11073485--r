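---
title: "Intrinsic-frequency analysis of carotid waveforms and LVEF screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intrinsic-frequency analysis of carotid waveforms and LVEF screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifscreen)
```

## The model

A carotid pressure cycle is treated as the output of the heart--aorta
system: during systole the left ventricle and the arterial tree form one
coupled oscillator, and at aortic-valve closure (the dicrotic notch, time
$T_0$) they decouple, leaving the vasculature to relax on its own. The
package models one beat $p(t)$ on $[0, T)$ as a piecewise pair of
sinusoids,

$$
p(t) \approx c +
\begin{cases}
a_1\cos\omega_1 t + b_1\sin\omega_1 t, & 0 \le t < T_0,\\
a_2\cos\omega_2 t + b_2\sin\omega_2 t, & T_0 \le t < T,
\end{cases}
$$

and estimates the seven parameters by minimizing the sum of squared sample
residuals. $\omega_1$ and $\omega_2$ are the systolic and diastolic
*intrinsic frequencies* — operating frequencies of the coupled and
decoupled system, not Fourier peaks. Derived quantities follow the usual
conventions: intrinsic phases $\varphi_i = \operatorname{atan2}(a_i, b_i)$
(the signed branch in $(-\pi, \pi]$, equal to $\tan^{-1}(a_i/b_i)$ for
$b_i > 0$; a signed convention is required because the published screening
boundary $\varphi_1 = -0.65$ rad is negative) and envelopes
$R_s = \sqrt{a_1^2+b_1^2}$, $R_d = \sqrt{a_2^2+b_2^2}$.

Two linear equality constraints are imposed by default: continuity of
pressure at $T_0$, and closure over the beat, $p(T) = p(0)$. The printed
objective alone does not pin these down, but reconstructed pulses in the
source literature are visibly continuous and a closed beat is the natural
periodic reading; both relaxations remain available
(`fit_config(mode = "continuity-only")`, `"unconstrained"`).

Pressure units are arbitrary throughout (tonometry is uncalibrated);
everything downstream is invariant to offset and positive scaling of the
signal, and the fit is equivariant (frequencies and phases unchanged,
envelopes and offset transformed accordingly).

## Fitting strategy

At fixed $(\omega_1, \omega_2)$ the problem is linear least squares in
$(a_1, b_1, a_2, b_2, c)$ and is solved exactly — by eliminating the two
constraints down to a 3-unknown system (vectorized over the whole
frequency grid via Cramer's rule), or through the KKT system in the scalar
path. The profiled objective over $(\omega_1, \omega_2)$ is multimodal
with narrow valleys, so the search is an exhaustive coarse grid (default
1 bpm over 40--300 bpm for $\omega_1$, 20--200 bpm for $\omega_2$)
followed by restarted Nelder--Mead refinement from the best few
well-separated grid basins. Restarting the simplex at the incumbent until
the improvement falls below `refine_tol` (default $10^{-8}$, relative)
protects against premature collapse when the optimum objective is close to
zero, as it is for noiseless cycles. The refined objective is never
accepted if it exceeds the best coarse node. Grid nodes where the
constraint elimination degenerates ($\sin \omega_1 T_0 \approx 0$) are
skipped; their basins are covered by neighbouring nodes, and the scalar
KKT path handles them when met during refinement.

Two optional refinements extend the frequency search:

* `refine_T0` lets the systolic duration move within a window (default
  $\pm 20\%$) around the notch estimate. The objective is very sensitive
  to a misplaced junction, while notch detection is only sample-accurate
  and sometimes falls back to a fixed fraction, so joint refinement is how
  the pipeline reconciles the two.
* `refine_onset` adds a circular shift of the cycle start (window
  $\pm 3\%$ of the period). A cycle cut a few samples away from the true
  foot is a *rotation* of the underlying periodic beat, which a closed
  two-piece model cannot represent exactly; with the shift parameter it
  can, and recovery on rotated noiseless cycles is again exact.

Both are off in `fit_config()` defaults — a cycle with a trusted $T_0$
needs neither — and both are on in the pipeline, where $T_0$ and the onset
come from detectors.

## Waveform processing

Beat onsets are found automatically (the study protocol's manual cycle
selection is replaced for reproducibility): the signal is smoothed with a
short moving average, upstrokes are peaks of the first derivative above a
robust fraction of the maximum slope, a refractory period suppresses
double-firing — widened using the dominant period from the signal's
autocorrelation, which prevents the dicrotic upstroke from registering as
a beat — and the onset is the local pressure minimum preceding each
upstroke. The dicrotic notch is the most prominent local minimum of the
lightly smoothed cycle within a physiologic window ($[0.15T, 0.6T]$ by
default); a cycle with no interior minimum falls back to $T_0 = 0.35T$ and
is flagged, costing it 0.25 of quality score. Quality is threshold-free:
one minus the RMS discrepancy from the per-subject median beat template,
normalized by the template's pulsatile RMS. The three to five
highest-quality cycles are fitted and their parameters averaged
arithmetically into one record per subject (the protocol averages fitted
parameters, not beats; a circular phase mean is available but off, since
per-subject phase spread is small). Heart rate is taken from the cycle
length, $HR = 60/T$, and the unitless index $\omega i_1 =
\omega_1[\mathrm{bpm}]/HR$ compensates for the strong age dependence of
pediatric heart rate.

In the pipeline two guards make subject aggregation robust: a fit whose
relative residual exceeds 5% is retried from canonical systolic fractions
($0.30T \ldots 0.45T$), since a badly misplaced notch estimate can strand
the $T_0$ refinement in the wrong basin; and cycles whose residual stays
far above the subject's median ($1.5\times$, with an absolute floor of
0.015) are excluded from the average, at least two always being retained.
Both events are rare on clean data and logged behaviour is deterministic.

## Screening

Two fixed, published decision rules are encoded verbatim with their
printed strict inequalities (equality at a boundary falls to the
non-strict side; this is a measure-zero choice documented for
reproducibility):

* rule A on $(\omega_1, \text{age}, \varphi_1)$: $\omega_1 < 107.6$ bpm is
  normal regardless of age; otherwise age $\ge 6$ years is low LVEF, and
  under 6 years the call is low only when $\varphi_1 < -0.65$ rad;
* rule B on $(\omega_1, \omega i_1)$: $\omega i_1 > 1.6$ is low,
  $\omega i_1 < 1.22$ normal, and the band between is decided by
  $\omega_1 > 107.6$ bpm.

The trainable classifier is a greedy Gini CART with the two structural
constraints stated for the original analysis: at most $1 + p$ splits for
$p$ predictors, and a node may be split only when it holds more than 10
samples (read literally as $\ge 11$). Growth is best-first so the split
budget is spent where impurity falls most; thresholds sit at midpoints
between consecutive distinct values; ties break to the lower predictor
index, then the smaller threshold, then the earlier node — the tree is a
deterministic function of the data. Leaves carry positive-class fractions,
which are the ranking scores for ROC analysis (the original report is
silent on how scores were derived from leaves; the resubstitution fraction
is the natural choice and any monotone transformation leaves the ROC
unchanged). Evaluation is deterministic leave-one-out cross-validation
pooled into one confusion matrix (score threshold 0.5) and one ROC; the
trapezoidal AUC is exactly the Mann--Whitney statistic with ties counted
one half. The headline clinical performance figures of the source study
are *not* reproduced here: they belong to a 50-patient cohort that is not
publicly deposited, so all quantitative claims in this package are about
synthetic cohorts with known ground truth.

## The synthetic cohort generator

`gen_cohort()` emulates the study design, not any particular patient: `n`
subjects (default 50) with low-LVEF prevalence 0.32 (a 16/50 split), ages
uniform within three equally weighted brackets (0--6, 7--13, 14--20
years), and heart rate falling with age (group means 110/85/70 bpm,
SD 10). Each subject owns one exact forward-model parameter set built by
`if_params_constrained()`, so every generated beat satisfies the fitted
model's constraints by construction; recordings concatenate beats with
independent white noise (default SD 2% of pulse amplitude; the end-to-end
recovery checks use 1%) and optional slow baseline drift. Ejection
fraction comes from lognormal end-diastolic volumes with EF drawn by
rejection on the labelled side of 50%, and the label column is always
exactly `lvef < 50`.

Planted effects follow the reported direction — low-LVEF subjects have
higher $\omega_1$/$\omega i_1$ and lower $\varphi_1$ — with magnitudes
that are generator conventions, not reported values (the source figures
are unquantified): $\Delta\omega_1 = +15$ bpm, i.e. three within-group
SDs, and $\Delta\varphi_1 = -0.5$ rad. Baseline conventions:
$\omega_1 \approx 1.15\,HR$, $\omega_2 \approx 0.55\,HR$, systolic
fraction $T_0/T \approx 0.35$, envelope near 1 in arbitrary units.

Three numerical choices deserve note. The subject period is snapped to the
sampling grid ($T = n/f_s$) so that sampled beats are exactly
representable by the closure-constrained model — without this the closure
time and the last sample disagree by up to half a sample and exact
recovery is impossible by construction. The diastolic coefficient solve
has determinant $\sin\omega_2(T - T_0)$, so $\omega_2$ draws are rejected
until $|\sin\omega_2(T-T_0)| \ge 0.25$; near the singular manifold the
"diastolic" component becomes an unphysiologically large near-resonant
pair, which no plausible pulse exhibits. And every subject draws from its
own seed stream mixed from the cohort seed and subject index, making
cohorts byte-reproducible and insertion-order independent.

What the generator does *not* emulate: reflected waves and Windkessel
tails, respiratory and motion artifacts beyond white noise and a drift
sinusoid, beat-to-beat parameter variability within a subject, and any
device transfer function. Passing tests therefore demonstrate that the
estimation and screening machinery is correct and well-conditioned on
signals that obey the model; they do not certify performance on clinical
tracings.

## Problem sizes and tolerances

The shipped checks use problem sizes chosen to exercise every code path at
desk scale: 50 noiseless cycles for exact recovery (tolerance 0.25 bpm,
residual $<10^{-6}$), 20 noisy cycles against an independently coded
dense-grid oracle (0.1 bpm spacing over a $\pm 5$ bpm window around the
generator truth; the full-range basin capture is covered by the
exact-recovery check, and the oracle shares no linear algebra with the
fitter), 50 random draws for the constrained-subproblem contracts at
$10^{-10}$, over $10^4$ grid points per fixed rule, 1000 random confusion
matrices, 200 random score sets for the AUC/rank-statistic identity at
$10^{-12}$, and one 100-subject end-to-end cohort at 1% noise (median
$\omega_1$ recovery error below 1 bpm; pooled LOOCV AUC above 0.9).

## Worked example

```{r example, eval = FALSE}
cfg <- cohort_config(n = 30, prevalence = 0.4, noise_sd = 0.01, seed = 42)
dir <- tempfile("cohort")
pipeline_synth(cfg, dir)
feats <- pipeline_extract(dir, verbose = FALSE)
res <- pipeline_screen(feats, out_dir = dir)
res$cart_loocv
```

## Known limitations

* $T_0$ handling for the original tracings is unspecified in the source;
  this package estimates the notch and refines it jointly, which is one
  defensible reading among several.
* The reported "correction of $\omega_1$ for LV ejection time" has no
  printed formula; no correction is applied, and `normalize_omega1()` is
  the only normalization.
* Phases are averaged arithmetically across cycles by default; for
  subjects with phase spread approaching $\pi$ this would be wrong, but
  such spread also indicates unusable data.
* The fixed rules' structural arrangement (which band threshold sits on
  which branch) is encoded by effective rule, which is observationally
  equivalent but not structurally identifiable from the source figures.
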