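#' Intrinsic-frequency model parameters
#'
#' The two-frequency model of one cardiac cycle: during systole `[0, T0)`
#' the pressure follows `c + a1 cos(w1 t) + b1 sin(w1 t)` (the heart and
#' aorta as one coupled oscillator at intrinsic frequency `w1`), and during
#' diastole `[T0, T)` it follows `c + a2 cos(w2 t) + b2 sin(w2 t)` (the
#' decoupled vasculature at `w2`). Derived quantities: intrinsic phases
#' `phi = atan2(a, b)` in `(-pi, pi]` (equal to `atan(a/b)` when `b > 0`)
#' and envelopes `Rs = sqrt(a1^2 + b1^2)`, `Rd = sqrt(a2^2 + b2^2)`, so that
#' the systolic branch is `c + Rs sin(w1 t + phi1)`.
#'
#' @param omega1,omega2 Intrinsic frequencies in rad/s, both positive.
#' @param a1,b1,a2,b2 Sinusoid coefficients (pressure units).
#' @param c Constant offset (pressure units).
#' @return Object of class `if_params` with the seven parameters plus
#'   derived `phi1`, `phi2`, `Rs`, `Rd`.
#' @export
if_params <- function(omega1, omega2, a1, b1, a2, b2, c) {
  if (!is_number(omega1) || omega1 <= 0) abort_domain("omega1 must be > 0")
  if (!is_number(omega2) || omega2 <= 0) abort_domain("omega2 must be > 0")
  p <- list(omega1 = unname(omega1), omega2 = unname(omega2),
            a1 = unname(a1), b1 = unname(b1), a2 = unname(a2),
            b2 = unname(b2), c = unname(c))
  p$phi1 <- atan2(p$a1, p$b1)
  p$phi2 <- atan2(p$a2, p$b2)
  p$Rs <- sqrt(p$a1^2 + p$b1^2)
  p$Rd <- sqrt(p$a2^2 + p$b2^2)
  structure(p, class = "if_params")
}

#' @export
print.if_params <- function(x, ...) {
  cat(sprintf("<if_params> omega1 = %.2f bpm, omega2 = %.2f bpm\n",
              to_bpm(x$omega1), to_bpm(x$omega2)))
  cat(sprintf("  phi1 = %.3f rad, phi2 = %.3f rad, Rs = %.3g, Rd = %.3g, c = %.3g\n",
              x$phi1, x$phi2, x$Rs, x$Rd, x$c))
  invisible(x)
}

#' Convert an angular frequency to beats per minute
#'
#' @param omega Angular frequency in rad/s.
#' @return `omega * 60 / (2 pi)` in bpm.
#' @export
to_bpm <- function(omega) omega * 60 / (2 * pi)

#' Convert beats per minute to rad/s
#' @param bpm Frequency in beats (cycles) per minute.
#' @return Angular frequency in rad/s.
#' @export
from_bpm <- function(bpm) bpm * 2 * pi / 60

#' Intrinsic phase and envelope of a sinusoid coefficient pair
#'
#' For coefficients of `a cos(w t) + b sin(w t) = R sin(w t + phi)`:
#' `R = sqrt(a^2 + b^2)` and `phi = atan2(a, b)`, the signed branch in
#' `(-pi, pi]` that restricts to `atan(a/b)` when `b > 0`. Vectorized.
#'
#' @param a,b Coefficients (pressure units).
#' @return List with components `phi` (rad) and `R`.
#' @export
phase_envelope <- function(a, b) {
  if (any(a == 0 & b == 0)) abort_domain("phase undefined for (a, b) = (0, 0)")
  list(phi = atan2(a, b), R = sqrt(a^2 + b^2))
}

#' Reconstruct a pressure cycle from model parameters
#'
#' Evaluates the piecewise two-sinusoid model: systole for `t < T0`,
#' diastole for `t >= T0`.
#'
#' @param params An [if_params] object.
#' @param T0 Systolic duration in seconds.
#' @param T Cycle duration in seconds, `T > T0 > 0`.
#' @param times Evaluation times in `[0, T)`.
#' @return Numeric vector of reconstructed pressures.
#' @export
reconstruct <- function(params, T0, T, times) {
  stopifnot(inherits(params, "if_params"))
  if (!is_number(T0) || !is_number(T) || T0 <= 0 || T0 >= T)
    abort_domain("need 0 < T0 < T")
  sys <- times < T0
  out <- numeric(length(times))
  out[sys] <- params$c + params$a1 * cos(params$omega1 * times[sys]) +
    params$b1 * sin(params$omega1 * times[sys])
  out[!sys] <- params$c + params$a2 * cos(params$omega2 * times[!sys]) +
    params$b2 * sin(params$omega2 * times[!sys])
  out
}

#' Construct parameters satisfying the continuity and closure constraints
#'
#' Given the frequencies, timing and the systolic component (envelope and
#' phase), solves the diastolic coefficients from the two linear
#' constraints used by the default fitting mode: continuity of pressure at
#' the notch, `p(T0^-) = p(T0^+)`, and closure over the beat,
#' `p(T) = p(0)`. This is the forward model used by the synthetic-data
#' generator, so generated cycles are exactly representable by the fitter.
#'
#' @param omega1,omega2 Frequencies in rad/s.
#' @param T0,T Systolic and total durations in seconds.
#' @param Rs Systolic envelope (pressure units).
#' @param phi1 Systolic intrinsic phase in rad.
#' @param c Constant offset.
#' @return An [if_params] object satisfying both constraints.
#' @export
if_params_constrained <- function(omega1, omega2, T0, T, Rs = 1, phi1 = 0, c = 0) {
  a1 <- Rs * sin(phi1); b1 <- Rs * cos(phi1)
  M <- rbind(c(cos(omega2 * T0), sin(omega2 * T0)),
             c(cos(omega2 * T),  sin(omega2 * T)))
  dt <- det(M)   # = sin(omega2 (T - T0))
  if (abs(dt) < 1e-6)
    abort_domain("degenerate diastolic timing: omega2 * (T - T0) too close to a multiple of pi")
  rhs <- c(a1 * cos(omega1 * T0) + b1 * sin(omega1 * T0), a1)
  ab2 <- solve(M, rhs)
  if_params(omega1, omega2, a1, b1, ab2[1], ab2[2], c)
}

# Constraint matrix rows for the selected mode (5 unknowns a1,b1,a2,b2,c).
constraint_rows <- function(omega1, omega2, T0, T, mode) {
  cont <- c(cos(omega1 * T0), sin(omega1 * T0),
            -cos(omega2 * T0), -sin(omega2 * T0), 0)
  clos <- c(-1, 0, cos(omega2 * T), sin(omega2 * T), 0)
  switch(mode,
         "continuity+closure" = rbind(cont, clos),
         "continuity-only" = rbind(cont),
         "unconstrained" = NULL,
         abort_config(paste0("unknown constraint mode: ", mode)))
}

#' Solve the linear subproblem at fixed frequencies
#'
#' At fixed `(omega1, omega2)` the objective is quadratic in the five linear
#' unknowns `(a1, b1, a2, b2, c)`. This solves the discrete least-squares
#' problem, optionally subject to linear equality constraints: continuity of
#' pressure at `T0` and closure `p(T) = p(0)`. Constrained modes are solved
#' through the KKT system; the unconstrained mode is an ordinary
#' least-squares fit (two independent sinusoid fits sharing the offset `c`).
#'
#' @param pressure Numeric cycle pressure samples.
#' @param times Sample times on `[0, T)` (uniform grid).
#' @param T0,T Systolic and total durations in seconds.
#' @param omega1,omega2 Frequencies in rad/s, positive.
#' @param mode One of `"continuity+closure"` (default), `"continuity-only"`,
#'   `"unconstrained"`.
#' @return List with `coef` (named a1, b1, a2, b2, c), `objective` (sum of
#'   squared residuals), `residual` (relative L2 misfit in `[0, 1]`, the
#'   ratio of the residual norm to the norm of the mean-centred signal) and
#'   `degenerate` (logical; `TRUE` with `residual = 1` and `NA` coefficients
#'   when the design is rank-deficient, e.g. `omega * T0` near a multiple of
#'   pi under constraints).
#' @export
solve_linear_coeffs <- function(pressure, times, T0, T, omega1, omega2,
                                mode = c("continuity+closure",
                                         "continuity-only", "unconstrained")) {
  mode <- match.arg(mode)
  if (!is_number(omega1) || omega1 <= 0 || !is_number(omega2) || omega2 <= 0)
    abort_domain("frequencies must be positive")
  sys <- times < T0
  A <- cbind(cos(omega1 * times) * sys, sin(omega1 * times) * sys,
             cos(omega2 * times) * (!sys), sin(omega2 * times) * (!sys),
             1)
  Cm <- constraint_rows(omega1, omega2, T0, T, mode)
  ss_tot <- sum((pressure - mean(pressure))^2)
  degen <- function() {
    list(coef = stats::setNames(rep(NA_real_, 5), c("a1", "b1", "a2", "b2", "c")),
         objective = ss_tot, residual = 1, degenerate = TRUE)
  }
  x <- tryCatch({
    if (is.null(Cm)) {
      qr.coef(qr(A), pressure)
    } else {
      G <- crossprod(A)
      m <- nrow(Cm)
      K <- rbind(cbind(G, t(Cm)), cbind(Cm, matrix(0, m, m)))
      sol <- solve(K, c(crossprod(A, pressure), rep(0, m)))
      sol[1:5]
    }
  }, error = function(e) NULL)
  if (is.null(x) || anyNA(x) || any(!is.finite(x))) return(degen())
  r <- pressure - drop(A %*% x)
  obj <- sum(r^2)
  list(coef = stats::setNames(as.numeric(x), c("a1", "b1", "a2", "b2", "c")),
       objective = obj,
       residual = if (ss_tot > 0) sqrt(min(obj / ss_tot, 1)) else 0,
       degenerate = FALSE)
}

# Vectorized objective of the continuity+closure mode over a frequency grid.
# Eliminates (a1, b1) through the constraints, leaving free u = (a2, b2, c);
# the reduced 3x3 normal equations are solved by Cramer's rule elementwise
# over the (omega1, omega2) grid. Nodes with sin(omega1 T0) ~ 0, where the
# elimination degenerates, get objective Inf (covered by neighbours).
# Returns a K1 x K2 matrix of sums of squared residuals.
grid_objective_cc <- function(pressure, times, T0, T, omega1_grid, omega2_grid) {
  sys <- times < T0
  t_s <- times[sys]; t_d <- times[!sys]
  p_s <- pressure[sys]; p_d <- pressure[!sys]
  n <- length(pressure)
  C1 <- cos(outer(t_s, omega1_grid)); S1 <- sin(outer(t_s, omega1_grid))
  cc1 <- colSums(C1 * C1); cs1 <- colSums(C1 * S1); ss1 <- colSums(S1 * S1)
  sC1 <- colSums(C1); sS1 <- colSums(S1)
  pC1 <- colSums(p_s * C1); pS1 <- colSums(p_s * S1)
  C2 <- cos(outer(t_d, omega2_grid)); S2 <- sin(outer(t_d, omega2_grid))
  cc2 <- colSums(C2 * C2); cs2 <- colSums(C2 * S2); ss2 <- colSums(S2 * S2)
  sC2 <- colSums(C2); sS2 <- colSums(S2)
  pC2 <- colSums(p_d * C2); pS2 <- colSums(p_d * S2)
  sum_p <- sum(pressure); pp <- sum(pressure^2)
  K1 <- length(omega1_grid); K2 <- length(omega2_grid)
  c1s <- cos(omega1_grid * T0); s1s <- sin(omega1_grid * T0)
  c2s <- cos(omega2_grid * T0); s2s <- sin(omega2_grid * T0)
  c2T <- cos(omega2_grid * T);  s2T <- sin(omega2_grid * T)
  O <- function(a, b) outer(a, b)
  one2 <- rep(1, K2)
  # a1 = c2T a2 + s2T b2; b1 = (al a2 + be b2) / sin(omega1 T0)
  al <- sweep(-O(c1s, c2T), 2, c2s, "+") / s1s
  be <- sweep(-O(c1s, s2T), 2, s2s, "+") / s1s
  g11 <- sweep(O(cc1, c2T^2) + 2 * al * O(cs1, c2T) + al^2 * O(ss1, one2), 2, cc2, "+")
  g22 <- sweep(O(cc1, s2T^2) + 2 * be * O(cs1, s2T) + be^2 * O(ss1, one2), 2, ss2, "+")
  g12 <- sweep(O(cc1, c2T * s2T) + al * O(cs1, s2T) + be * O(cs1, c2T) +
                 al * be * O(ss1, one2), 2, cs2, "+")
  g13 <- sweep(O(sC1, c2T) + al * O(sS1, one2), 2, sC2, "+")
  g23 <- sweep(O(sC1, s2T) + be * O(sS1, one2), 2, sS2, "+")
  g33 <- n
  r1 <- sweep(O(pC1, c2T) + al * O(pS1, one2), 2, pC2, "+")
  r2 <- sweep(O(pC1, s2T) + be * O(pS1, one2), 2, pS2, "+")
  r3 <- sum_p
  dt <- g11 * (g22 * g33 - g23 * g23) - g12 * (g12 * g33 - g23 * g13) +
    g13 * (g12 * g23 - g22 * g13)
  u1 <- (r1 * (g22 * g33 - g23 * g23) - g12 * (r2 * g33 - g23 * r3) +
           g13 * (r2 * g23 - g22 * r3)) / dt
  u2 <- (g11 * (r2 * g33 - r3 * g23) - r1 * (g12 * g33 - g23 * g13) +
           g13 * (g12 * r3 - r2 * g13)) / dt
  u3 <- (g11 * (g22 * r3 - g23 * r2) - g12 * (g12 * r3 - r2 * g13) +
           r1 * (g12 * g23 - g22 * g13)) / dt
  obj <- pp - 2 * (u1 * r1 + u2 * r2 + u3 * r3) +
    (u1 * u1 * g11 + u2 * u2 * g22 + u3 * u3 * g33 +
       2 * (u1 * u2 * g12 + u1 * u3 * g13 + u2 * u3 * g23))
  obj[!is.finite(obj)] <- Inf
  obj[abs(s1s) < 1e-8, ] <- Inf
  # the expanded quadratic cancels catastrophically near exact fits and
  # can dip a hair below zero; the true objective is a squared norm
  obj[obj < 0] <- 0
  obj
}
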