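test_that("log-normal discretization is exact in the degenerate case and unit-mean always", {
  expect_equal(discretize_lognormal(0, 10), rep(1, 10))
  for (ls in c(0.3, 0.7, 1.5)) {
    for (n in c(5, 50, 200)) {
      w <- discretize_lognormal(ls, n)
      expect_equal(mean(w), 1, tolerance = 1e-9)
      expect_true(all(w > 0))
    }
  }
  expect_error(discretize_lognormal(-0.1, 10), "non-negative")
  expect_error(discretize_lognormal(0.5, 0), "positive integer")
})

test_that("discretized log-weight spread matches the target within 5%", {
  # independent check of the target second log-moment by numerical
  # integration of the log-normal density
  target <- sqrt(integrate(function(x) x^2 * dnorm(x, 0, 0.7),
                           -Inf, Inf)$value)
  w <- discretize_lognormal(0.7, 200)
  expect_equal(sd(log(w)), target, tolerance = 0.05)
})

test_that("build_lung conserves totals and spreads scale with log_sd", {
  lung <- build_lung(900, 150, 3400, 0, 0, 50)
  expect_equal(unique(round(lung$V_i, 12)), 900 / 50)
  expect_equal(length(unique(round(lung$s_i, 12))), 1L)
  expect_equal(sum(lung$V_i), 900)
  expect_equal(sum(lung$q_i), 3400)
  expect_equal(sum(lung$s_i * lung$V_i), 1, tolerance = 1e-12)

  het <- build_lung(900, 150, 3400, 1.0, 1.5, 50)
  expect_equal(sum(het$V_i), 900)
  expect_equal(sum(het$q_i), 3400)

  cv <- vapply(c(0, 0.5, 1.0), function(ls) {
    l <- build_lung(900, 150, 3400, ls, 0, 50)
    sd(l$s_i) / mean(l$s_i)
  }, numeric(1))
  expect_true(all(diff(cv) > 0))
})

test_that("ventilation/perfusion pairing is close to rank-uncorrelated", {
  lung <- build_lung(900, 150, 3400, 1.0, 1.5, 64)
  expect_lt(abs(cor(rank(lung$s_i), rank(lung$q_i))), 0.2)
})

test_that("washin reaches the inspired equilibrium without perfusion", {
  lung <- build_lung(800, 150, 0, 0.8, 0, n = 20)
  forcing <- sine_forcing(180, VT = 300, RR = 25, A = 1e-9, F0 = 0.04,
                          n_breaths = 2000)
  tr <- simulate_breaths(lung, forcing)
  expect_equal(tail(tr$F_ET, 1), 0.04, tolerance = 1e-6)
})

test_that("one-compartment washin follows the geometric closed form", {
  # with deadspace re-inspired at the previous mixed-expired composition,
  # the deviation from equilibrium contracts by (ELV + V_D)/(ELV + VT)
  elv <- 800; vd <- 150; vt <- 300; f0 <- 0.04
  lung <- build_lung(elv, vd, 0, 0, 0, n = 1)
  forcing <- sine_forcing(180, VT = vt, RR = 25, F0 = f0, A = 1e-12,
                          n_breaths = 60)
  tr <- simulate_breaths(lung, forcing)
  beta <- (elv + vd) / (elv + vt)
  expect_equal(tr$F_ET, f0 * (1 - beta^seq_len(60)), tolerance = 1e-6)
})

test_that("tracer mass is conserved breath by breath", {
  lung <- build_lung(800, 150, 3400, 1.0, 1.5, n = 30)
  forcing <- sine_forcing(60, VT = 300, RR = 25, n_breaths = 120)
  tr <- simulate_breaths(lung, forcing, keep_compartments = TRUE)
  C <- attr(tr, "C")
  dV <- lung$s_i * lung$V_i * (300 - 150)
  d_i <- 150 * dV / sum(dV)
  V_insp <- lung$V_i + dV + d_i
  breath_min <- (60 / 25) / 60
  fet_prev <- 0
  C_prev <- rep(0, lung$n)
  for (b in seq_len(nrow(tr))) {
    inflow <- sum(dV * tr$F_I[b] + d_i * fet_prev)
    # uptake inferred from the exponential relaxation at constant volume
    C_mix <- (C_prev * lung$V_i + d_i * fet_prev + dV * tr$F_I[b]) / V_insp
    uptake <- sum(V_insp * (C_mix - C[b, ]))
    outflow <- sum((dV + d_i) * C[b, ])
    store_change <- sum(lung$V_i * C[b, ]) - sum(lung$V_i * C_prev)
    expect_equal(inflow - outflow - uptake, store_change,
                 tolerance = 1e-9)
    fet_prev <- tr$F_ET[b]
    C_prev <- C[b, ]
  }
})

test_that("steady-state output amplitude is linear in forcing amplitude", {
  # long trace + long discard so the washin transient cannot contaminate
  # the steady-state amplitude estimate
  lung <- build_lung(800, 150, 3400, 0.8, 1.2, n = 20)
  amp <- vapply(c(0.01, 0.02), function(a) {
    tr <- simulate_breaths(lung, sine_forcing(60, VT = 300, RR = 25, A = a,
                                              n_breaths = 1000))
    fit_sinusoid(tr, "F_ET", 60, min_warmup_breaths = 800)$amplitude
  }, numeric(1))
  expect_equal(amp[2] / amp[1], 2, tolerance = 1e-6)
})

test_that("homogeneous n-compartment simulation collapses to one compartment", {
  f <- sine_forcing(60, VT = 300, RR = 25)
  tr1 <- simulate_breaths(build_lung(800, 150, 3400, 0, 0, n = 1), f)
  tr50 <- simulate_breaths(build_lung(800, 150, 3400, 0, 0, n = 50), f)
  expect_equal(tr50$F_ET, tr1$F_ET, tolerance = 1e-9)
})

test_that("recovered ELV at 180 s exceeds that at 60 s in heterogeneous lungs", {
  for (ls in c(0.5, 1.0, 1.5)) {
    elv180 <- hetero_recovery(ls, period_T = 180)$ELV
    elv60 <- hetero_recovery(ls, period_T = 60)$ELV
    expect_gte(elv180, elv60)
  }
})

test_that("simulation rejects impossible ventilation settings", {
  lung <- build_lung(800, 400, 3400, 0, 0, n = 1)
  expect_error(
    simulate_breaths(lung, sine_forcing(60, VT = 300, RR = 25)),
    "no alveolar ventilation")
})

test_that("breath traces round-trip through CSV", {
  tr <- one_comp_trace(period_T = 60)
  path <- withr::local_tempfile(fileext = ".csv")
  write_breath_trace(tr, path)
  back <- read_breath_trace(path)
  expect_equal(back$F_ET, tr$F_ET, tolerance = 1e-12)
  expect_equal(back$time_s, tr$time_s, tolerance = 1e-12)
})
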