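#' Simulate per-breath tracer fractions under sinusoidal forcing
#'
#' Forward-simulates an inert, blood-soluble tracer gas through a
#' multi-compartment lung, one breath at a time. Each breath applies, in
#' order:
#'
#' 1. *Inspiration*: every compartment re-inspires its share of the series
#'    deadspace gas (which carries the previous breath's mixed
#'    end-expiratory composition) followed by fresh gas at the inspired
#'    fraction `F_I(t) = F0 + A*sin(2*pi*t/T)`; both are distributed in
#'    proportion to the compartment's fresh-gas share
#'    `dV_i = s_i * V_i * (VT - V_D)` and dilute the alveolar content.
#' 2. *Uptake*: tracer is removed to pulmonary blood over the breath at
#'    rate `lambda_b * q_i * (C_i - C_v)`, integrated exactly over the
#'    breath (exponential relaxation towards `C_v`).
#' 3. *Expiration*: the mixed end-expiratory fraction is the flow-weighted
#'    mean `F_ET = sum(dV_i * C_i) / sum(dV_i)` and the compartments return
#'    to their end-expiratory volumes.
#'
#' The scheme conserves tracer mass exactly (to floating-point precision):
#' per breath, inspired moles minus expired moles minus blood uptake equals
#' the change in the compartmental store.
#'
#' @param lung A [build_lung()] model.
#' @param forcing A [sine_forcing()] description; requires
#'   `forcing$VT > lung$V_D`.
#' @param noise_sd Standard deviation of iid Gaussian measurement noise
#'   added to the recorded `F_ET` (absolute fraction units; default 0).
#'   Noise affects only the recorded trace, not the internal state.
#' @param keep_compartments If `TRUE`, attach the matrix of per-compartment
#'   end-of-breath alveolar fractions as attribute `"C"` (breaths in rows).
#' @return A tibble of class `breath_trace` with columns `breath`, `time_s`
#'   (time at end-expiration), `F_I` (inspired fraction of the breath's
#'   fresh gas) and `F_ET`. The forcing object is attached as attribute
#'   `"forcing"`.
#' @examples
#' lung <- build_lung(800, 150, 3400, 0, 0, n = 1)
#' tr <- simulate_breaths(lung, sine_forcing(180, VT = 300, RR = 25))
#' head(tr)
#' @export
simulate_breaths <- function(lung, forcing, noise_sd = 0,
                             keep_compartments = FALSE) {
  stopifnot(inherits(lung, "lung_model"), inherits(forcing, "sine_forcing"))
  VT <- forcing$VT
  VD <- lung$V_D
  if (VT <= VD) {
    abort("no alveolar ventilation: tidal volume must exceed deadspace.")
  }
  breath_s <- 60 / forcing$RR
  breath_min <- breath_s / 60
  nb <- forcing$n_breaths

  dV <- lung$s_i * lung$V_i * (VT - VD)  # fresh-gas share per compartment
  d_i <- VD * dV / sum(dV)               # re-inspired deadspace share
  V_insp <- lung$V_i + dV + d_i          # end-inspiratory volume
  g <- exp(-lung$lambda_b * lung$q_i * breath_min / V_insp)
  w_exp <- dV / sum(dV)

  C <- rep(0, lung$n)
  fet_prev <- 0  # deadspace starts tracer-free
  omega <- 2 * pi / forcing$period_T

  t_s <- seq_len(nb) * breath_s
  F_I <- forcing$F0 + forcing$A * sin(omega * t_s)
  F_ET <- numeric(nb)
  Cmat <- if (keep_compartments) matrix(NA_real_, nb, lung$n) else NULL

  for (b in seq_len(nb)) {
    C <- (C * lung$V_i + d_i * fet_prev + dV * F_I[b]) / V_insp
    C <- lung$C_v + (C - lung$C_v) * g
    fet <- sum(w_exp * C)
    F_ET[b] <- fet
    fet_prev <- fet
    if (keep_compartments) Cmat[b, ] <- C
  }

  if (noise_sd > 0) {
    F_ET <- F_ET + rnorm(nb, 0, noise_sd)
  }

  out <- tibble(breath = seq_len(nb), time_s = t_s, F_I = F_I, F_ET = F_ET)
  class(out) <- c("breath_trace", class(out))
  attr(out, "forcing") <- forcing
  if (keep_compartments) attr(out, "C") <- Cmat
  out
}

#' Write / read a breath trace as CSV
#'
#' The on-disk format is three columns `time_s, F_I, F_ET`.
#'
#' @param trace A `breath_trace` tibble.
#' @param path File path.
#' @return `write_breath_trace()` returns `path` invisibly;
#'   `read_breath_trace()` returns a tibble with a `breath` index restored.
#' @export
write_breath_trace <- function(trace, path) {
  readr::write_csv(dplyr::select(trace, "time_s", "F_I", "F_ET"), path)
  invisible(path)
}

#' @rdname write_breath_trace
#' @export
read_breath_trace <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  out <- mutate(out, breath = seq_len(nrow(out)), .before = 1)
  class(out) <- c("breath_trace", class(out))
  out
}

#' @export
autoplot.breath_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[, c("time_s", "F_I", "F_ET")],
    cols = c("F_I", "F_ET"), names_to = "channel", values_to = "fraction"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$fraction,
                                   colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Tracer fraction", colour = NULL)
}
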