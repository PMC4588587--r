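# Bloch-McConnell forward simulation under continuous rectangular
# saturation. Lorentzian pools carry full (x, y, z) magnetization; the
# semisolid pool is longitudinal-only and is saturated at the
# lineshape-derived rate W = pi * omega1^2 * g(delta).

# Build the constant-coefficient generator d/dt M = A M + b for one
# saturation offset. State ordering: (x, y, z) for water then each
# solute, followed by a single z component for the semisolid pool.
bm_generator <- function(system, omega1_rad_s, offset_ppm, b0_T = 9.4,
                         gamma = GAMMA_H) {
  lorentz <- c(list(system$water), system$solutes)
  nl <- length(lorentz)
  has_ss <- !is.null(system$semisolid)
  n <- 3 * nl + has_ss
  A <- matrix(0, n, n)
  b <- numeric(n)
  M0 <- numeric(n)

  fracs <- vapply(lorentz, `[[`, numeric(1), "fraction")
  ks <- vapply(lorentz, `[[`, numeric(1), "k_exch")

  # exchange loss on water: to each solute, plus (z only) to semisolid
  k_w_out <- sum(fracs[-1] * ks[-1])

  for (i in seq_len(nl)) {
    p <- lorentz[[i]]
    ix <- 3 * i - 2; iy <- ix + 1; iz <- ix + 2
    dw <- 2 * pi * ppm_to_hz(p$shift_ppm - offset_ppm, b0_T, gamma)
    kout <- if (i == 1) k_w_out else p$k_exch
    A[ix, ix] <- -1 / p$T2 - kout
    A[iy, iy] <- -1 / p$T2 - kout
    A[iz, iz] <- -1 / p$T1 - kout
    A[ix, iy] <- dw
    A[iy, ix] <- -dw
    A[iy, iz] <- omega1_rad_s
    A[iz, iy] <- -omega1_rad_s
    M0[iz] <- p$fraction
    b[iz] <- p$fraction / p$T1
    if (i > 1) {
      # coupling with water, all three components
      for (c in 0:2) {
        A[3 * 1 - 2 + c, ix + c] <- A[3 * 1 - 2 + c, ix + c] + p$k_exch
        A[ix + c, 3 * 1 - 2 + c] <- A[ix + c, 3 * 1 - 2 + c] +
          p$fraction * p$k_exch
      }
    }
  }

  if (has_ss) {
    ss <- system$semisolid
    is <- n
    wz <- 3
    W <- pi * omega1_rad_s^2 *
      super_lorentzian(ppm_to_hz(offset_ppm, b0_T, gamma), ss$T2)
    A[is, is] <- -1 / ss$T1 - ss$k_exch - W
    A[is, wz] <- A[is, wz] + ss$fraction * ss$k_exch
    A[wz, is] <- A[wz, is] + ss$k_exch
    A[wz, wz] <- A[wz, wz] - ss$fraction * ss$k_exch
    M0[is] <- ss$fraction
    b[is] <- ss$fraction / ss$T1
  }

  list(A = A, b = b, M0 = M0, iz_water = 3)
}

# Propagate from thermal equilibrium over a rectangular pulse by
# exponentiating the augmented (homogeneous) generator; exact for
# constant RF.
bm_propagate <- function(gen, t_sat) {
  n <- length(gen$M0)
  Aug <- rbind(cbind(gen$A, gen$b), 0)
  E <- as.matrix(Matrix::expm(Aug * t_sat))
  M <- E %*% c(gen$M0, 1)
  M[seq_len(n)]
}

#' Simulate a z-spectrum for a multi-pool spin system
#'
#' Solves the coupled Bloch-McConnell equations from thermal equilibrium
#' over the saturation duration at every offset of the protocol, and
#' records water longitudinal magnetization normalized by the
#' unsaturated reference (the same readout with zero RF amplitude).
#' The propagation uses a single matrix-exponential step per offset,
#' which is exact for a continuous rectangular pulse. The semisolid
#' pool, when present, has no transverse components; saturation enters
#' its longitudinal equation as the rate
#' \eqn{W = \pi\,\omega_1^2\, g(\Delta)} with \eqn{g} the
#' super-Lorentzian lineshape.
#'
#' @param system a [spin_system()].
#' @param pulse a [saturation_pulse()].
#' @param protocol an [acquisition_protocol()].
#' @return a [zspectrum()] (normalized S/S0 per offset).
#' @export
#' @examples
#' sys <- build_system(agent_preset("Eu-HPDO3A", 4), "solution")
#' prot <- acquisition_protocol(seq(-30, 30, by = 5))
#' z <- simulate_zspectrum(sys, pulse_preset("eu_solution"), prot)
simulate_zspectrum <- function(system, pulse, protocol) {
  stopifnot(inherits(system, "spin_system"),
            inherits(pulse, "saturation_pulse"),
            inherits(protocol, "acq_protocol"))
  if (!all(is.finite(protocol$offsets_ppm))) stop("offsets must be finite")
  omega1 <- uT_to_rad_s(pulse$b1_uT, protocol$gamma)

  s0 <- tryCatch({
    gen0 <- bm_generator(system, 0, protocol$offsets_ppm[1],
                         protocol$b0_T, protocol$gamma)
    bm_propagate(gen0, pulse$duration_s)[gen0$iz_water]
  }, error = function(e) stop("reference simulation failed: ",
                              conditionMessage(e)))

  sig <- vapply(protocol$offsets_ppm, function(off) {
    tryCatch({
      gen <- bm_generator(system, omega1, off, protocol$b0_T,
                          protocol$gamma)
      bm_propagate(gen, pulse$duration_s)[gen$iz_water]
    }, error = function(e) {
      stop(sprintf("Bloch-McConnell solve failed at offset %g ppm: %s",
                   off, conditionMessage(e)))
    })
  }, numeric(1))

  zspectrum(protocol$offsets_ppm, sig / s0, s0 = 1, normalized = TRUE)
}

#' Analytic two-pool steady-state saturation level
#'
#' Closed-form steady state of the two-pool (water + one Lorentzian
#' solute) Bloch-McConnell system under constant RF, obtained by solving
#' the linear stationarity condition directly. Used as an independent
#' long-pulse limit check for the time-domain propagator.
#'
#' @param system a two-pool [spin_system()] (water + one Lorentzian
#'   solute, no semisolid pool).
#' @param pulse a [saturation_pulse()] (only the amplitude is used).
#' @param offset_ppm a single saturation offset, ppm.
#' @param b0_T static field, tesla.
#' @param gamma gyromagnetic ratio, rad s^-1 T^-1.
#' @return steady-state S/S0 of the water pool.
#' @export
analytic_two_pool_steady_state <- function(system, pulse, offset_ppm,
                                           b0_T = 9.4, gamma = GAMMA_H) {
  stopifnot(inherits(system, "spin_system"))
  if (length(system$solutes) > 1 || !is.null(system$semisolid)) {
    stop("analytic steady state is defined for at most two pools ",
         "(water + one Lorentzian solute)")
  }
  omega1 <- uT_to_rad_s(pulse$b1_uT, gamma)
  gen <- bm_generator(system, omega1, offset_ppm, b0_T, gamma)
  Mss <- solve(gen$A, -gen$b)
  Mss[gen$iz_water]
}
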