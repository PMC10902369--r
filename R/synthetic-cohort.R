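#' Protocol specification for a synthetic porcine lavage-injury cohort
#'
#' Describes the experimental protocol the generator emulates: six
#' saline-lavaged pigs ventilated at 10 mL/kg, a PEEP ladder rising
#' 5-10-15-20 cmH2O and stepping back down 15-10-5, and two paired
#' IST + CT measurements at every step.
#'
#' @param n_animals Number of animals (default 6).
#' @param weights Body weights in kg; defaults to the six study-typical
#'   weights `c(31, 32, 28, 28, 31, 32)` (recycled/truncated to
#'   `n_animals`).
#' @param peep_ladder PEEP sequence in cmH2O; must rise then fall.
#' @param repeats_per_step Paired measurements per PEEP step (default 2).
#' @param vt_per_kg Tidal volume in mL per kg (default 10).
#' @param rr_range Respiratory-rate range in breaths/min; each animal is
#'   assigned one rate from this range (default 20--25).
#' @param noise_sd Measurement noise on the expired tracer fraction,
#'   expressed as a fraction of the mean inspired fraction `F0`
#'   (default 0.005, i.e. 0.5%).
#' @param F0,A Inspired tracer sinusoid mean and amplitude.
#' @param n_compartments Simulator compartments (default 50).
#' @param lambda_b Tracer blood--gas partition coefficient (default 0.47).
#' @param ct_shape CT volume dimensions (default `c(64, 64, 16)`).
#' @param ct_spacing CT voxel spacing in mm (default `c(0.5, 0.5, 5)`).
#' @param seed Master seed; every generator output is a deterministic
#'   function of `(seed, spec)`.
#' @return A list of class `protocol_spec`.
#' @export
protocol_spec <- function(n_animals = 6,
                          weights = NULL,
                          peep_ladder = c(5, 10, 15, 20, 15, 10, 5),
                          repeats_per_step = 2,
                          vt_per_kg = 10,
                          rr_range = c(20, 25),
                          noise_sd = 0.005,
                          F0 = 0.04, A = 0.02,
                          n_compartments = 50,
                          lambda_b = 0.47,
                          ct_shape = c(64, 64, 16),
                          ct_spacing = c(0.5, 0.5, 5),
                          seed = 1) {
  if (is.null(weights)) {
    weights <- rep_len(c(31, 32, 28, 28, 31, 32), n_animals)
  }
  weights <- rep_len(weights, n_animals)
  peak <- which.max(peep_ladder)
  up <- peep_ladder[seq_len(peak)]
  down <- peep_ladder[peak:length(peep_ladder)]
  if (is.unsorted(up) || is.unsorted(rev(down)) || length(peep_ladder) < 2) {
    abort("`peep_ladder` must rise to a single peak and then fall.")
  }
  if (any(c(n_animals, weights, peep_ladder, repeats_per_step, vt_per_kg,
            rr_range, F0, A, n_compartments) <= 0) || noise_sd < 0) {
    abort("protocol quantities must be positive (noise_sd non-negative).")
  }
  structure(
    list(n_animals = as.integer(n_animals), weights = weights,
         peep_ladder = peep_ladder,
         repeats_per_step = as.integer(repeats_per_step),
         vt_per_kg = vt_per_kg, rr_range = rr_range, noise_sd = noise_sd,
         F0 = F0, A = A, n_compartments = as.integer(n_compartments),
         lambda_b = lambda_b, ct_shape = as.integer(ct_shape),
         ct_spacing = ct_spacing, seed = as.integer(seed)),
    class = "protocol_spec"
  )
}

# Deterministic sub-seed stream: one row of seeds per animal.
animal_seeds <- function(spec, n_each = 64L) {
  set.seed(spec$seed)
  matrix(sample.int(.Machine$integer.max - 1L,
                    spec$n_animals * n_each),
         nrow = spec$n_animals)
}

#' Generate per-(animal, step) physiological ground truth
#'
#' Draws deterministic per-animal trajectories of the latent quantities the
#' two modalities measure. Ventilation heterogeneity (`log_sd_v_true`)
#' falls linearly from about 1.0 at PEEP 5 to about 0.4 at PEEP 20 and
#' perfusion heterogeneity (`log_sd_p_true`) from about 1.5 to 1.2;
#' effective lung volume rises with PEEP (recruitment) while pulmonary
#' blood flow falls slightly; deadspace distends modestly. The decremental
#' limb differs from the incremental limb by a few percent (hysteresis well
#' under 10%). The CT heterogeneity parameter is a monotone map of
#' `log_sd_v_true` so that both modalities share one latent quantity.
#'
#' @param spec A [protocol_spec()].
#' @return A tibble with one row per (animal, protocol step): columns
#'   `animal`, `step`, `peep`, `limb`, `weight_kg`, `rr`, `vt_ml`,
#'   `log_sd_v_true`, `log_sd_p_true`, `elv_true`, `qp_true`, `vd_true`,
#'   `ct_heterogeneity_param`.
#' @export
generate_ground_truth <- function(spec = protocol_spec()) {
  stopifnot(inherits(spec, "protocol_spec"))
  seeds <- animal_seeds(spec)
  ladder <- spec$peep_ladder
  peak <- which.max(ladder)
  limb <- ifelse(seq_along(ladder) <= peak, "incremental", "decremental")
  purrr::map_dfr(seq_len(spec$n_animals), function(a) {
    set.seed(seeds[a, 1L])
    j_lsv <- rnorm(1, 0, 0.05)
    j_lsp <- rnorm(1, 0, 0.05)
    j_elv <- rnorm(1, 0, 0.04)
    j_qp <- rnorm(1, 0, 0.05)
    rr <- sample(seq(spec$rr_range[1], spec$rr_range[2]), 1)
    wt <- spec$weights[a]
    limb_f <- ifelse(limb == "decremental", 0.97, 1)
    lsv <- pmax((1.0 - 0.6 * (ladder - 5) / 15) * limb_f + j_lsv, 0.05)
    lsp <- pmax((1.5 - 0.3 * (ladder - 5) / 15) * limb_f + j_lsp, 0.05)
    tibble(
      animal = a,
      step = seq_along(ladder),
      peep = ladder,
      limb = limb,
      weight_kg = wt,
      rr = rr,
      vt_ml = spec$vt_per_kg * wt,
      log_sd_v_true = lsv,
      log_sd_p_true = lsp,
      elv_true = 25 * wt * (1 + 0.022 * (ladder - 5)) * (1 + j_elv),
      qp_true = 110 * wt * (1 - 0.006 * (ladder - 5)) * (1 + j_qp),
      vd_true = 5 * wt * (1 + 0.01 * (ladder - 5)),
      ct_heterogeneity_param = pmin(pmax((lsv - 0.2) / 1.1, 0), 1)
    )
  })
}

#' Generate synthetic IST breath traces for a cohort
#'
#' For every (animal, step, repeat, forcing period) the true lung is built
#' from the ground truth, simulated under sinusoidal forcing, and iid
#' Gaussian noise of standard deviation `noise_sd * F0` is added to the
#' recorded expired fractions. Sub-seeds derived from the master seed make
#' the output reproducible bit-for-bit; with `noise_sd = 0` the two
#' repeats are identical.
#'
#' @param truth Ground-truth tibble from [generate_ground_truth()].
#' @param spec The same [protocol_spec()].
#' @param periods Forcing periods in seconds (default `c(180, 60)`).
#' @return A tibble with one row per measurement: identifiers (`animal`,
#'   `step`, `peep`, `limb`, `repeat_idx`, `period_T`), the ventilator
#'   settings (`vt_ml`, `vd_ml`, `rr`), and a `trace` list-column of
#'   `breath_trace` tibbles.
#' @export
generate_ist_measurements <- function(truth, spec = protocol_spec(),
                                      periods = c(180, 60)) {
  stopifnot(inherits(spec, "protocol_spec"))
  seeds <- animal_seeds(spec)
  design <- tidyr::expand_grid(
    truth,
    repeat_idx = seq_len(spec$repeats_per_step),
    period_T = periods
  )
  design$trace <- purrr::pmap(
    list(design$animal, design$step, design$repeat_idx, design$period_T,
         design$log_sd_v_true, design$log_sd_p_true, design$elv_true,
         design$qp_true, design$vd_true, design$vt_ml, design$rr),
    function(a, s, rep_i, T, lsv, lsp, elv, qp, vd, vt, rr) {
      lung <- build_lung(elv, vd, qp, lsv, lsp, n = spec$n_compartments,
                         lambda_b = spec$lambda_b)
      forcing <- sine_forcing(T, VT = vt, RR = rr, F0 = spec$F0, A = spec$A)
      # column index encodes (step, repeat, period) so each measurement has
      # its own reproducible noise stream
      col <- 1L + (s - 1L) * 8L + (rep_i - 1L) * 2L + match(T, periods)
      set.seed(seeds[a, col %% ncol(seeds) + 1L])
      simulate_breaths(lung, forcing, noise_sd = spec$noise_sd * spec$F0)
    })
  design <- rename(design, vd_ml = "vd_true")
  select(design, "animal", "step", "peep", "limb", "repeat_idx", "period_T",
         "vt_ml", "vd_ml", "rr", "trace")
}

# Separable box smoothing along the first two axes (in-plane).
smooth_inplane <- function(a, k = 5L) {
  d <- dim(a)
  kern <- rep(1 / k, k)
  for (z in seq_len(d[3])) {
    sl <- a[, , z]
    sl <- apply(sl, 2, function(col) stats::filter(col, kern, sides = 2))
    sl <- t(apply(sl, 1, function(row) stats::filter(row, kern, sides = 2)))
    sl[is.na(sl)] <- 0
    a[, , z] <- sl
  }
  a
}

#' Generate one synthetic CT volume
#'
#' Builds an ellipsoidal lung mask and a Hounsfield-unit field emulating an
#' end-expiratory scan of a lavage-injured lung: a uniform normally-aerated
#' base (-800 HU), a gravity-axis atelectasis gradient whose dependent
#' dense layer thickens with the heterogeneity parameter, a milder
#' non-dependent over-distension component, and smoothed speckle. All three
#' deviations scale with `ct_heterogeneity_param`, so a parameter of zero
#' gives a perfectly homogeneous lung (inhomogeneity index 1 everywhere,
#' `H_CT = 0`, no atelectasis). Masked voxels are clamped to
#' `[-1000, +100]` HU.
#'
#' @param param CT heterogeneity parameter in `[0, 1]`.
#' @param spec A [protocol_spec()] (supplies shape and spacing).
#' @param seed Seed for the speckle field.
#' @return A [ct_volume()].
#' @export
generate_ct_volume <- function(param, spec = protocol_spec(), seed = 1) {
  stopifnot(param >= 0, param <= 1)
  d <- spec$ct_shape
  cx <- (d + 1) / 2
  ix <- slice.index(array(0, d), 1)
  iy <- slice.index(array(0, d), 2)
  iz <- slice.index(array(0, d), 3)
  mask <- ((ix - cx[1]) / (0.45 * d[1]))^2 +
    ((iy - cx[2]) / (0.45 * d[2]))^2 +
    ((iz - cx[3]) / (0.46 * d[3]))^2 <= 1
  u <- (iy - 1) / (d[2] - 1)  # 0 = non-dependent, 1 = dependent (gravity axis)
  ramp <- min(1, param / 0.15)
  atel <- 880 * ramp * plogis((u - (1 - 0.5 * param)) / 0.05)
  over <- -180 * param * plogis((0.25 - u) / 0.08)
  set.seed(seed)
  speckle <- smooth_inplane(array(rnorm(prod(d), 0, 1), d), k = 5L) *
    (55 * param) * sqrt(5 * 5)  # undo box-kernel variance reduction
  hu <- -800 + atel + over + speckle
  hu <- round(pmin(pmax(hu, -1000), 100))
  hu[!mask] <- -1000
  ct_volume(hu, mask, spacing = spec$ct_spacing)
}

#' Generate a complete synthetic cohort
#'
#' Ground truth, IST breath traces and CT volumes for every animal, PEEP
#' step and repeat, reproducible from `(seed, spec)`.
#'
#' @param spec A [protocol_spec()].
#' @param periods IST forcing periods (default `c(180, 60)`).
#' @param ct If `FALSE`, skip CT volume generation.
#' @return A list of class `synthetic_cohort` with elements `spec`,
#'   `truth`, `ist` (measurement tibble with `trace` list-column) and `ct`
#'   (tibble with a `volume` list-column, or `NULL`).
#' @export
simulate_cohort <- function(spec = protocol_spec(), periods = c(180, 60),
                            ct = TRUE) {
  truth <- generate_ground_truth(spec)
  ist <- generate_ist_measurements(truth, spec, periods)
  ct_tbl <- NULL
  if (ct) {
    seeds <- animal_seeds(spec)
    ct_tbl <- tidyr::expand_grid(
      truth[, c("animal", "step", "peep", "limb", "ct_heterogeneity_param")],
      repeat_idx = seq_len(spec$repeats_per_step)
    )
    ct_tbl$volume <- purrr::pmap(
      list(ct_tbl$animal, ct_tbl$step, ct_tbl$repeat_idx,
           ct_tbl$ct_heterogeneity_param),
      function(a, s, rep_i, p) {
        generate_ct_volume(p, spec,
                           seed = seeds[a, 32L + (s - 1L) * 2L + rep_i])
      })
  }
  structure(list(spec = spec, truth = truth, ist = ist, ct = ct_tbl),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d animals x %d PEEP steps x %d repeats | %d IST traces%s\n",
    x$spec$n_animals, length(x$spec$peep_ladder), x$spec$repeats_per_step,
    nrow(x$ist),
    if (is.null(x$ct)) "" else sprintf(" | %d CT volumes", nrow(x$ct))))
  invisible(x)
}
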