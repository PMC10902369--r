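#' Least-squares sinusoid fit at a known forcing period
#'
#' Projects one channel of a breath trace onto `{1, sin, cos}` at the known
#' forcing frequency, after discarding a warm-up window. Returns the mean,
#' amplitude, phase (principal branch) and residual RMS.
#'
#' @param trace A `breath_trace` tibble (or any data frame with `time_s`
#'   and the requested channel).
#' @param channel `"F_ET"` (default) or `"F_I"`.
#' @param period_T Forcing period in seconds.
#' @param warmup_periods Number of initial forcing periods to discard
#'   (default 1). The discarded window is floored at `min_warmup_breaths`
#'   breaths so that the washin transient has decayed even at short forcing
#'   periods. The remaining trace must span at least two periods.
#' @param min_warmup_breaths Minimum number of breaths discarded as warm-up
#'   (default 80).
#' @return A list with `mean`, `amplitude` (>= 0), `phase` (in `(-pi, pi]`),
#'   `rms` (residual root-mean-square) and `n` (points used).
#' @examples
#' lung <- build_lung(800, 150, 3400, 0, 0, n = 1)
#' tr <- simulate_breaths(lung, sine_forcing(180, VT = 300, RR = 25))
#' fit_sinusoid(tr, "F_I", 180)
#' @export
fit_sinusoid <- function(trace, channel = c("F_ET", "F_I"), period_T,
                         warmup_periods = 1, min_warmup_breaths = 80) {
  channel <- arg_match(channel)
  t <- trace$time_s
  y <- trace[[channel]]
  dt <- stats::median(diff(t))
  keep <- t > max(warmup_periods * period_T, min_warmup_breaths * dt)
  if (sum(keep) < 4 ||
      (max(t[keep]) - min(t[keep])) + dt < 2 * period_T - 1e-9) {
    abort("trace too short: need at least two forcing periods after warm-up.")
  }
  t <- t[keep]
  y <- y[keep]
  om <- 2 * pi / period_T
  X <- cbind(1, sin(om * t), cos(om * t))
  beta <- qr.solve(X, y)
  resid <- y - X %*% beta
  list(
    mean = beta[[1]],
    amplitude = sqrt(beta[[2]]^2 + beta[[3]]^2),
    phase = atan2(beta[[3]], beta[[2]]),
    rms = sqrt(mean(resid^2)),
    n = length(y)
  )
}

# Complex frequency response of the one-compartment breath recursion at the
# forcing frequency. With beta = (V + V_D)/(V + VT), gamma = (VT - V_D)/(V + VT)
# and per-breath uptake factor g, the recursion C_n = g*beta*C_{n-1} +
# g*gamma*F_n has transfer H = g*gamma / (1 - g*beta*exp(-i*theta)) at
# breath-phase increment theta = 2*pi*Tb/T.
one_compartment_gain <- function(ELV, g, VT, V_D, theta) {
  beta <- (ELV + V_D) / (ELV + VT)
  gam <- (VT - V_D) / (ELV + VT)
  g * gam / (1 - g * beta * exp(complex(imaginary = -theta)))
}

#' Invert the one-compartment frequency response for ELV and Qp
#'
#' Solves the single-compartment per-breath recursion for the two unknowns
#' (effective lung volume and soluble-tracer uptake, expressed as pulmonary
#' blood flow) from the measured complex gain between the inspired and
#' expired sinusoids: the amplitude ratio and phase lag give two real
#' equations. The gain of the recursion at the forcing frequency is
#' `H = g*gamma / (1 - g*beta*exp(-i*theta))`, so the condition that the
#' uptake factor `g` be real reduces to a single bracketed root-find in ELV;
#' `g` then follows in closed form and
#' `Qp = -(ELV + VT) * log(g) / (lambda_b * Tb)`.
#'
#' @param insp,expd Sinusoid parameter lists from [fit_sinusoid()] for the
#'   inspired and expired channels.
#' @param VT Tidal volume (mL).
#' @param V_D Deadspace volume (mL), taken as known.
#' @param RR Respiratory rate (breaths/min).
#' @param lambda_b Blood--gas partition coefficient (default 0.47).
#' @param period_T Forcing period (s).
#' @param tol Root-finding tolerance on ELV (mL); default 1e-10 relative.
#' @return A list with `ELV` (mL), `Qp` (mL/min) and diagnostics
#'   `amplitude_ratio`, `phase_lag`, `g`.
#' @export
invert_single_compartment <- function(insp, expd, VT, V_D, RR,
                                      lambda_b = 0.47, period_T,
                                      tol = 1e-10) {
  ratio <- expd$amplitude / insp$amplitude
  if (!is.finite(ratio) || ratio <= 0 || ratio >= 1 + 1e-6) {
    abort(sprintf(
      "no solution: expired/inspired amplitude ratio %.4g outside (0, 1].",
      ratio))
  }
  phase_lag <- expd$phase - insp$phase
  # principal branch
  phase_lag <- atan2(sin(phase_lag), cos(phase_lag))
  breath_s <- 60 / RR
  theta <- 2 * pi * breath_s / period_T
  H <- complex(modulus = ratio, argument = phase_lag)
  invH <- 1 / H
  e_th <- exp(complex(imaginary = -theta))
  u <- function(V) {
    ((VT - V_D) * invH + (V + V_D) * e_th) / (V + VT)
  }
  f <- function(V) Im(u(V))
  # bracket the root on a log grid
  grid <- 10^seq(-2, 7, by = 0.5)
  fg <- vapply(grid, f, numeric(1))
  sgn <- which(fg[-1] * fg[-length(fg)] <= 0)
  if (length(sgn) == 0) {
    abort("convergence error: no ELV root bracketed by the phase condition.")
  }
  lo <- grid[sgn[1]]
  hi <- grid[sgn[1] + 1]
  ELV <- uniroot(f, c(lo, hi), tol = tol * max(1, hi))$root
  g <- 1 / Re(u(ELV))
  if (!is.finite(g) || g <= 0) {
    abort("convergence error: non-physical uptake factor.")
  }
  Qp <- -(ELV + VT) * log(g) / (lambda_b * breath_s / 60)
  list(ELV = ELV, Qp = Qp, amplitude_ratio = ratio, phase_lag = phase_lag,
       g = g)
}

#' Recover IST parameters from a breath trace at one forcing period
#'
#' Fits inspired and expired sinusoids and inverts the one-compartment
#' frequency response. The deadspace is supplied, not estimated.
#'
#' @param trace A `breath_trace`.
#' @param VT,V_D,RR Ventilator settings and known deadspace (mL, mL,
#'   breaths/min).
#' @param period_T Forcing period (s); defaults to the period recorded in
#'   the trace's forcing attribute.
#' @param lambda_b Blood--gas partition coefficient.
#' @param warmup_periods Warm-up periods discarded before fitting.
#' @param min_warmup_breaths Minimum warm-up length in breaths (see
#'   [fit_sinusoid()]).
#' @return A one-row tibble of class `ist_result`: `period_T`, `ELV`, `Qp`,
#'   `V_D`, `amp_insp`, `amp_exp`, `phase_lag`, `resid_rms`.
#' @examples
#' lung <- build_lung(800, 150, 3400, 0, 0, n = 1)
#' tr <- simulate_breaths(lung, sine_forcing(180, VT = 300, RR = 25))
#' analyze_ist_trace(tr, VT = 300, V_D = 150, RR = 25)
#' @export
analyze_ist_trace <- function(trace, VT, V_D, RR, period_T = NULL,
                              lambda_b = 0.47, warmup_periods = 1,
                              min_warmup_breaths = 80) {
  if (is.null(period_T)) {
    forcing <- attr(trace, "forcing")
    if (is.null(forcing)) {
      abort("`period_T` must be given when the trace carries no forcing attribute.")
    }
    period_T <- forcing$period_T
  }
  insp <- fit_sinusoid(trace, "F_I", period_T, warmup_periods,
                       min_warmup_breaths)
  expd <- fit_sinusoid(trace, "F_ET", period_T, warmup_periods,
                       min_warmup_breaths)
  inv <- invert_single_compartment(insp, expd, VT = VT, V_D = V_D, RR = RR,
                                   lambda_b = lambda_b, period_T = period_T)
  out <- tibble(
    period_T = period_T, ELV = inv$ELV, Qp = inv$Qp, V_D = V_D,
    amp_insp = insp$amplitude, amp_exp = expd$amplitude,
    phase_lag = inv$phase_lag, resid_rms = expd$rms
  )
  class(out) <- c("ist_result", class(out))
  out
}

#' Two-period ratio heterogeneity indices
#'
#' The conventional bedside indices: recovered effective lung volume and
#' pulmonary blood flow become increasingly period-dependent as
#' heterogeneity increases, so `ELV180/ELV60` indexes ventilation
#' heterogeneity and `Qp60/Qp180` perfusion heterogeneity; both equal 1 for
#' a homogeneous lung.
#'
#' @param r180,r60 `ist_result` rows (or lists with `ELV`, `Qp`) measured at
#'   forcing periods 180 s and 60 s.
#' @return A one-row tibble with `h_ratio_v` and `h_ratio_p`.
#' @export
heterogeneity_ratios <- function(r180, r60) {
  if (r60$ELV[[1]] == 0 || r180$Qp[[1]] == 0) {
    abort("zero denominator in heterogeneity ratio.")
  }
  tibble(
    h_ratio_v = r180$ELV[[1]] / r60$ELV[[1]],
    h_ratio_p = r60$Qp[[1]] / r180$Qp[[1]]
  )
}
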