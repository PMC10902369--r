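# Shared fixtures: small lungs, forcings and traces built in code.

default_vent <- list(VT = 300, V_D = 150, RR = 25)

one_comp_trace <- function(elv = 800, qp = 3400, period_T = 180,
                           vd = default_vent$V_D, vt = default_vent$VT,
                           rr = default_vent$RR, ...) {
  lung <- build_lung(elv, vd, qp, 0, 0, n = 1)
  simulate_breaths(lung, sine_forcing(period_T, VT = vt, RR = rr), ...)
}

hetero_recovery <- function(log_sd_v, log_sd_p = 1.2, period_T = 180,
                            elv = 800, qp = 3400, n = 50) {
  lung <- build_lung(elv, default_vent$V_D, qp, log_sd_v, log_sd_p, n = n)
  tr <- simulate_breaths(lung, sine_forcing(period_T, VT = default_vent$VT,
                                            RR = default_vent$RR))
  analyze_ist_trace(tr, VT = default_vent$VT, V_D = default_vent$V_D,
                    RR = default_vent$RR, period_T = period_T)
}

# Brute-force voxel-ring inhomogeneity oracle: plain loops, independent of
# the vectorized implementation (shares only the definition).
cressoni_oracle <- function(ct, r1 = 2.41, r2 = 3.675, gas_floor = 0.01,
                            min_coverage = 0.5) {
  d <- dim(ct$hu)
  gas <- pmin(pmax(-ct$hu / 1000, 0), 1)
  reach <- floor(r2 / ct$spacing)
  offs <- list()
  for (i in -reach[1]:reach[1]) for (j in -reach[2]:reach[2])
    for (k in -reach[3]:reach[3]) {
      dist <- sqrt((i * ct$spacing[1])^2 + (j * ct$spacing[2])^2 +
                     (k * ct$spacing[3])^2)
      if (dist >= r1 && dist <= r2) offs[[length(offs) + 1L]] <- c(i, j, k)
    }
  n_off <- length(offs)
  index <- array(NA_real_, d)
  valid <- array(FALSE, d)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (!ct$mask[x, y, z]) next
    s <- 0
    cnt <- 0L
    for (o in offs) {
      xx <- x + o[1]; yy <- y + o[2]; zz <- z + o[3]
      if (xx < 1 || yy < 1 || zz < 1 || xx > d[1] || yy > d[2] || zz > d[3])
        next
      if (!ct$mask[xx, yy, zz]) next
      s <- s + gas[xx, yy, zz]
      cnt <- cnt + 1L
    }
    if (cnt >= min_coverage * n_off) {
      valid[x, y, z] <- TRUE
      index[x, y, z] <- (s / cnt) / max(gas[x, y, z], gas_floor)
    }
  }
  list(index = index, valid = valid)
}

random_masked_ct <- function(seed, shape = c(32, 32, 8)) {
  set.seed(seed)
  hu <- array(sample(-1000:100, prod(shape), replace = TRUE), shape)
  centre <- (shape + 1) / 2
  ix <- slice.index(hu, 1); iy <- slice.index(hu, 2); iz <- slice.index(hu, 3)
  mask <- ((ix - centre[1]) / (0.46 * shape[1]))^2 +
    ((iy - centre[2]) / (0.46 * shape[2]))^2 +
    ((iz - centre[3]) / (0.48 * shape[3]))^2 <= 1
  ct_volume(hu, mask)
}
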