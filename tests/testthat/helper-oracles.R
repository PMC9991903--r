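# Independent brute-force oracles used to cross-check the implementation.

# Exhaustive local-minima scan implementing the bound definition directly:
# strict interior minima; topographic prominence by full walks; candidates
# accepted in order of increasing value subject to the separation rule.
oracle_volume_minima <- function(v, fs, min_separation, min_prominence) {
  n <- length(v)
  cand <- integer(0)
  for (i in 2:(n - 1)) {
    if (v[i] < v[i - 1] && v[i] < v[i + 1]) cand <- c(cand, i)
  }
  prom <- function(i) {
    lo <- v[i]
    left <- if (i > 1) v[1:(i - 1)] else numeric(0)
    below <- which(left < lo)
    maxl <- if (length(below)) {
      j <- max(below)
      if (j + 1 <= i - 1) max(left[(j + 1):(i - 1)]) else -Inf
    } else max(left, -Inf)
    right <- if (i < n) v[(i + 1):n] else numeric(0)
    below <- which(right < lo)
    maxr <- if (length(below)) {
      j <- min(below)
      if (j - 1 >= 1) max(right[1:(j - 1)]) else -Inf
    } else max(right, -Inf)
    min(maxl, maxr) - lo
  }
  cand <- cand[vapply(cand, prom, numeric(1)) >= min_prominence]
  kept <- integer(0)
  for (i in cand[order(v[cand], cand)]) {
    if (!length(kept) || all(abs(kept - i) >= min_separation * fs))
      kept <- c(kept, i)
  }
  sort(kept)
}

# Sample-by-sample replay of the trigger state machine.
oracle_triggers <- function(flow, fs, threshold, hysteresis, refractory) {
  armed <- TRUE
  last <- -Inf
  out <- numeric(0)
  for (i in seq_along(flow)) {
    t <- (i - 1) / fs
    if (armed && flow[i] >= threshold) {
      out <- c(out, t); armed <- FALSE; last <- t
    } else if (!armed && flow[i] < threshold * (1 - hysteresis) &&
               (t - last) >= refractory) {
      armed <- TRUE
    }
  }
  out
}

# Shoelace signed area of a closed polygon given vertex coordinates.
oracle_shoelace <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Fine-step RK4 integration of the single-compartment equation of motion
# under a prescribed driving pressure function p_fun(t) (cmH2O). Returns
# volume (ml) sampled at the coarse grid times.
oracle_integrate_eom <- function(p_fun, duration, fs_coarse, refine,
                                 R_aw, C_rs) {
  dt <- 1 / (fs_coarse * refine)
  n_f <- as.integer(round(duration * fs_coarse * refine))
  v <- numeric(n_f + 1)
  deriv <- function(t, V) 1000 * (p_fun(t) - V / C_rs) / R_aw
  for (i in seq_len(n_f)) {
    t <- (i - 1) * dt
    k1 <- deriv(t, v[i])
    k2 <- deriv(t + dt / 2, v[i] + dt / 2 * k1)
    k3 <- deriv(t + dt / 2, v[i] + dt / 2 * k2)
    k4 <- deriv(t + dt, v[i] + dt * k3)
    v[i + 1] <- v[i] + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  v[seq(1, n_f + 1, by = refine)]
}

# Fine-step Euler integration of the CO2 balance.
oracle_gas <- function(paco2_0, va, vco2, v_store, duration, dt = 0.001) {
  paco2 <- paco2_0
  k_prod <- 0.863 * vco2
  for (i in seq_len(round(duration / dt))) {
    paco2 <- paco2 + (k_prod - paco2 * va) / v_store * dt / 60
  }
  paco2
}

# Virtual-work force for an idealized cylindrical braid: F = P * dV/dL by
# central difference on the braid-kinematics volume.
oracle_virtual_work_force <- function(pressure_psi, eps, geom, h = 1e-7) {
  b <- geom$L0 / cos(geom$theta0)            # fibre length
  npi <- b * sin(geom$theta0) / geom$D0      # n * pi
  vol <- function(L) {
    s <- sqrt(pmax(b^2 - L^2, 0))
    (pi / 4) * (s / npi)^2 * L
  }
  L <- geom$L0 * (1 - eps)
  dvdl <- (vol(L + h) - vol(L - h)) / (2 * h)
  # contractile (tensile) force is positive as the enclosed volume grows
  # with shortening: F = -P dV/dL
  -pressure_psi * 6894.757 * dvdl
}
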