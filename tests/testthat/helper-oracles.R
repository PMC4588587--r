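# Independent oracles used across the suite. These deliberately avoid
# the package's matrix assembly and propagation code paths: the ODE
# right-hand side is written out pool by pool from the physical
# equations, and integration uses deSolve's adaptive solver instead of
# matrix exponentiation.

GAMMA <- 2.675221e8

hz_per_ppm <- function(b0_T = 9.4) (GAMMA * b0_T / (2 * pi)) * 1e-6

# Independent assembly of the coupled-equation coefficients, written
# pool by pool from the physical equations (not via the package's
# generator). Returns list(A, b, y0).
oracle_bm_coeffs <- function(system, b1_uT, offset_ppm, b0_T = 9.4) {
  w1 <- GAMMA * b1_uT * 1e-6
  pools <- c(list(system$water), system$solutes)
  np <- length(pools)
  ss <- system$semisolid
  nv <- 3 * np + !is.null(ss)
  A <- matrix(0, nv, nv)
  b <- numeric(nv)
  y0 <- numeric(nv)

  for (p in seq_len(np)) {
    pp <- pools[[p]]
    xi <- 3 * p - 2; yi <- xi + 1; zi <- xi + 2
    dwp <- 2 * pi * hz_per_ppm(b0_T) * (pp$shift_ppm - offset_ppm)
    # dMx/dt = -Mx/T2 + dw My
    A[xi, xi] <- A[xi, xi] - 1 / pp$T2
    A[xi, yi] <- A[xi, yi] + dwp
    # dMy/dt = -dw Mx - My/T2 + w1 Mz
    A[yi, xi] <- A[yi, xi] - dwp
    A[yi, yi] <- A[yi, yi] - 1 / pp$T2
    A[yi, zi] <- A[yi, zi] + w1
    # dMz/dt = -w1 My + (M0 - Mz)/T1
    A[zi, yi] <- A[zi, yi] - w1
    A[zi, zi] <- A[zi, zi] - 1 / pp$T1
    b[zi] <- pp$fraction / pp$T1
    y0[zi] <- pp$fraction
    if (p > 1) {
      for (cc in 0:2) {
        # solute loses magnetization to water at k, gains at f*k
        A[xi + cc, xi + cc] <- A[xi + cc, xi + cc] - pp$k_exch
        A[xi + cc, 1 + cc] <- A[xi + cc, 1 + cc] +
          pp$fraction * pp$k_exch
        A[1 + cc, 1 + cc] <- A[1 + cc, 1 + cc] -
          pp$fraction * pp$k_exch
        A[1 + cc, xi + cc] <- A[1 + cc, xi + cc] + pp$k_exch
      }
    }
  }
  if (!is.null(ss)) {
    si <- nv
    W <- pi * w1^2 *
      super_lorentzian(offset_ppm * hz_per_ppm(b0_T), ss$T2)
    A[si, si] <- -1 / ss$T1 - W - ss$k_exch
    A[si, 3] <- ss$fraction * ss$k_exch
    A[3, 3] <- A[3, 3] - ss$fraction * ss$k_exch
    A[3, si] <- A[3, si] + ss$k_exch
    b[si] <- ss$fraction / ss$T1
    y0[si] <- ss$fraction
  }
  list(A = A, b = b, y0 = y0)
}

# Fine-step time integration of the Bloch-McConnell equations for a
# spin_system at one offset, via deSolve. Returns water Mz at t_sat.
oracle_bm_signal <- function(system, b1_uT, t_sat, offset_ppm,
                             b0_T = 9.4) {
  co <- oracle_bm_coeffs(system, b1_uT, offset_ppm, b0_T)
  rhs <- function(t, y, parms) list(parms$A %*% y + parms$b)
  sol <- deSolve::ode(co$y0, c(0, t_sat), rhs,
                      parms = list(A = co$A, b = co$b),
                      method = "lsoda", rtol = 1e-8, atol = 1e-10,
                      maxsteps = 5e6)
  sol[nrow(sol), 1 + 3]
}

# Eigendecomposition solution of the same (independently assembled)
# constant-coefficient system: M(t) = V exp(Lt) V^-1 (y0 - y_ss) + y_ss.
oracle_bm_eigen <- function(system, b1_uT, t_sat, offset_ppm,
                            b0_T = 9.4) {
  co <- oracle_bm_coeffs(system, b1_uT, offset_ppm, b0_T)
  yss <- solve(co$A, -co$b)
  e <- eigen(co$A)
  c0 <- solve(e$vectors, co$y0 - yss)
  y <- Re(e$vectors %*% (exp(e$values * t_sat) * c0)) + yss
  y[3]
}

# Random valid 2- or 3-pool system (water + 1-2 Lorentzian solutes)
random_system <- function() {
  nsol <- sample(1:2, 1)
  solutes <- lapply(seq_len(nsol), function(i) {
    cest_pool(paste0("s", i),
              fraction = runif(1, 1e-5, 5e-4),
              shift_ppm = runif(1, 5, 100),
              k_exch = runif(1, 500, 15000),
              T1 = runif(1, 0.5, 2), T2 = runif(1, 0.005, 0.05))
  })
  water <- cest_pool("water", 1, 0, 0, runif(1, 1.5, 3.5),
                     runif(1, 0.04, 1.5))
  spin_system(water, solutes)
}

# Trapezoid quadrature of the super-Lorentzian defining integral on a
# fine theta grid (independent of stats::integrate).
oracle_super_lorentzian <- function(delta_hz, T2b, n = 2e6) {
  th <- seq(1e-9, pi / 2, length.out = n)
  u <- 3 * cos(th)^2 - 1
  v <- sqrt(2 / pi) * sin(th) * (T2b / abs(u)) *
    exp(-2 * (2 * pi * delta_hz * T2b / u)^2)
  sum((v[-1] + v[-n]) / 2 * diff(th))
}

# Simulate one WASSR acquisition of a voxel whose water center sits at
# delta0: the protocol offsets are shifted by the local offset.
simulate_wassr_voxel <- function(system, delta0, offs = wassr_offsets(),
                                 noise_sd = 0, pulse = pulse_preset("wassr")) {
  z <- simulate_zspectrum(system, pulse,
                          acquisition_protocol(offs - delta0))
  sig <- z$signal[match(offs - delta0, z$offsets_ppm)]
  wassr_spectrum(offs, sig + stats::rnorm(length(offs), sd = noise_sd))
}

# Exhaustive fixed-grid symmetry search (no windowing, no parabolic
# refinement) used as the brute-force oracle for the center finder.
oracle_symmetry_center <- function(w, grid = 5e-4, search = NULL) {
  rng <- range(w$offsets_ppm)
  if (is.null(search)) search <- min(abs(rng))
  curve <- spline_smooth(w, smoothing = 0)
  dense <- seq(rng[1], rng[2], by = 0.001)
  c0 <- dense[which.min(curve(dense))]
  cand <- seq(max(-search, c0 - 0.08), min(search, c0 + 0.08),
              by = grid)
  dgrid <- seq(0.002, diff(rng) / 2, by = 0.002)
  cost <- vapply(cand, function(d0) {
    dmax <- min(rng[2] - d0, d0 - rng[1])
    dd <- dgrid[dgrid <= dmax]
    if (length(dd) < 3) return(NA_real_)
    mean((curve(d0 + dd) - curve(d0 - dd))^2)
  }, numeric(1))
  cand[which.min(cost)]
}
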