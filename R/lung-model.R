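#' Deterministic quantile-midpoint discretization of a log-normal weight
#' distribution
#'
#' Returns `n` strictly positive weights representing a log-normal
#' distribution with log-scale spread `log_sd`, taken at the quantile
#' midpoints `(k - 1/2)/n` and renormalized so that `mean(weights) == 1`.
#' There is no sampling: the same arguments always give the same weights,
#' which keeps downstream simulation-based estimation free of Monte-Carlo
#' noise.
#'
#' @param log_sd Non-negative standard deviation of the underlying normal
#'   distribution on the log scale. `0` gives the degenerate distribution
#'   (all weights equal to 1).
#' @param n Number of weights (compartments), a positive integer.
#' @return Numeric vector of length `n`, positive, with mean exactly 1.
#' @examples
#' discretize_lognormal(0, 5)
#' sd(log(discretize_lognormal(0.7, 200)))
#' @export
discretize_lognormal <- function(log_sd, n) {
  if (!is.numeric(log_sd) || length(log_sd) != 1L || is.na(log_sd) || log_sd < 0) {
    abort("`log_sd` must be a single non-negative number.")
  }
  n <- as.integer(n)
  if (is.na(n) || n < 1L) {
    abort("`n` must be a positive integer.")
  }
  if (log_sd == 0) {
    return(rep(1, n))
  }
  p <- (seq_len(n) - 0.5) / n
  w <- qlnorm(p, meanlog = -log_sd^2 / 2, sdlog = log_sd)
  w / mean(w)
}

# van der Corput (bit-reversal) sequence in base 2; used to pair the
# perfusion weights with the ventilation weights in a deterministic but
# uncorrelated order.
van_der_corput <- function(n) {
  vapply(seq_len(n) - 1L, function(i) {
    s <- 0
    f <- 0.5
    while (i > 0L) {
      s <- s + f * (i %% 2L)
      i <- i %/% 2L
      f <- f / 2
    }
    s
  }, numeric(1))
}

#' Construct a multi-compartment lung model
#'
#' Builds `n` equal-volume alveolar compartments whose specific ventilations
#' and perfusions follow deterministic log-normal weight vectors with
#' log-scale spreads `log_sd_v` and `log_sd_p`. Specific ventilation is
#' normalized so that compartment `i` receives the share `s_i * V_i` of the
#' alveolar tidal volume, with the shares summing to one; perfusions sum to
#' `qp_true`. The two weight vectors are paired in bit-reversal order so
#' that ventilation and perfusion are effectively uncorrelated across
#' compartments while remaining fully deterministic.
#'
#' @param elv_true True effective (alveolar) lung volume in mL.
#' @param vd Series deadspace volume in mL.
#' @param qp_true True total pulmonary blood flow in mL/min.
#' @param log_sd_v,log_sd_p Log-scale spreads of specific ventilation and
#'   perfusion (dimensionless; 0 = homogeneous).
#' @param n Number of compartments (default 50).
#' @param lambda_b Blood--gas partition coefficient of the tracer
#'   (dimensionless; default 0.47, nitrous oxide).
#' @param c_v Mixed-venous tracer content as a fraction (default 0, no
#'   recirculation).
#' @return An object of class `lung_model`: a list with elements `n`, `V_i`
#'   (mL), `s_i` (1/mL), `q_i` (mL/min), `V_D` (mL), `lambda_b`, `C_v`.
#' @examples
#' lung <- build_lung(900, 150, 3400, 1.0, 1.5, n = 50)
#' sum(lung$V_i)
#' sum(lung$q_i)
#' @export
build_lung <- function(elv_true, vd, qp_true, log_sd_v, log_sd_p, n = 50,
                       lambda_b = 0.47, c_v = 0) {
  if (elv_true <= 0 || vd < 0 || qp_true < 0) {
    abort("Volumes must be positive and flows non-negative.")
  }
  n <- as.integer(n)
  V_i <- rep(elv_true / n, n)
  w_v <- discretize_lognormal(log_sd_v, n)
  w_q <- discretize_lognormal(log_sd_p, n)
  # pair perfusion weights with ventilation weights in bit-reversal order
  w_q <- w_q[rank(van_der_corput(n), ties.method = "first")]
  # sum(s_i * V_i) == mean(w_v) == 1
  s_i <- w_v / elv_true
  q_i <- qp_true * w_q / sum(w_q)
  structure(
    list(n = n, V_i = V_i, s_i = s_i, q_i = q_i, V_D = vd,
         lambda_b = lambda_b, C_v = c_v),
    class = "lung_model"
  )
}

#' @export
print.lung_model <- function(x, ...) {
  cat(sprintf(
    "<lung_model> %d compartments | ELV %.0f mL | Qp %.0f mL/min | V_D %.0f mL\n",
    x$n, sum(x$V_i), sum(x$q_i), x$V_D
  ))
  cat(sprintf("  CV of specific ventilation: %.3f; CV of perfusion: %.3f\n",
              sd(x$s_i) / mean(x$s_i), sd(x$q_i) / mean(x$q_i)))
  invisible(x)
}

#' Sinusoidal inspired-tracer forcing
#'
#' Describes the inspired tracer waveform `F_I(t) = F0 + A * sin(2*pi*t/T)`
#' together with the ventilator settings needed by the per-breath
#' simulator.
#'
#' @param period_T Forcing period in seconds (the study uses 60 and 180 s).
#' @param VT Tidal volume in mL.
#' @param RR Respiratory rate in breaths/min.
#' @param F0 Mean inspired tracer fraction (default 0.04).
#' @param A Forcing amplitude as a fraction (default 0.02); requires
#'   `0 < A <= F0` and `F0 + A <= 1`.
#' @param n_breaths Number of breaths to simulate; the default covers the
#'   warm-up window (one forcing period, floored at 80 breaths so that the
#'   washin transient has decayed at short periods) plus two full periods
#'   for fitting.
#' @return An object of class `sine_forcing` (a named list).
#' @examples
#' sine_forcing(180, VT = 300, RR = 25)
#' @export
sine_forcing <- function(period_T, VT, RR, F0 = 0.04, A = 0.02,
                         n_breaths = NULL) {
  if (period_T <= 0 || VT <= 0 || RR <= 0) {
    abort("`period_T`, `VT` and `RR` must be positive.")
  }
  if (A <= 0 || A > F0 || F0 + A > 1) {
    abort("Forcing amplitude must satisfy 0 < A <= F0 and F0 + A <= 1.")
  }
  breath_s <- 60 / RR
  if (is.null(n_breaths)) {
    warmup_s <- max(period_T, 80 * breath_s)
    n_breaths <- ceiling((warmup_s + 2 * period_T) / breath_s) + 1L
  }
  structure(
    list(period_T = period_T, F0 = F0, A = A, RR = RR, VT = VT,
         n_breaths = as.integer(n_breaths)),
    class = "sine_forcing"
  )
}

#' @export
print.sine_forcing <- function(x, ...) {
  cat(sprintf(
    "<sine_forcing> T = %gs | F0 = %g | A = %g | VT = %g mL | RR = %g/min | %d breaths\n",
    x$period_T, x$F0, x$A, x$VT, x$RR, x$n_breaths
  ))
  invisible(x)
}
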