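#' Define one exchanging proton pool
#'
#' A pool is characterised by its proton fraction relative to free water,
#' its chemical shift from water, its exchange rate towards water, its
#' relaxation times and its lineshape. The super-Lorentzian lineshape is
#' reserved for the on-resonance semisolid (magnetization transfer) pool.
#'
#' @param name pool label.
#' @param fraction proton fraction relative to free water (dimensionless).
#' @param shift_ppm chemical shift offset from water, ppm.
#' @param k_exch exchange rate pool -> water, s^-1.
#' @param T1,T2 relaxation times, seconds.
#' @param lineshape \code{"lorentzian"} or \code{"super_lorentzian"}.
#' @return an object of class \code{cest_pool}.
#' @export
#' @examples
#' cest_pool("Eu18", fraction = 4 / 111000, shift_ppm = 18,
#'           k_exch = 5000, T1 = 1, T2 = 0.01)
cest_pool <- function(name, fraction, shift_ppm, k_exch, T1, T2,
                      lineshape = c("lorentzian", "super_lorentzian")) {
  lineshape <- match.arg(lineshape)
  stopifnot(is.character(name), length(name) == 1)
  if (!is.finite(fraction) || fraction < 0) stop("fraction must be >= 0")
  if (!is.finite(k_exch) || k_exch < 0) stop("k_exch must be >= 0")
  if (!is.finite(T1) || T1 <= 0) stop("T1 must be > 0")
  if (!is.finite(T2) || T2 <= 0) stop("T2 must be > 0")
  if (lineshape == "super_lorentzian" && shift_ppm != 0) {
    stop("super_lorentzian lineshape is only valid for the on-resonance ",
         "semisolid pool (shift_ppm = 0)")
  }
  structure(list(name = name, fraction = fraction, shift_ppm = shift_ppm,
                 k_exch = k_exch, T1 = T1, T2 = T2, lineshape = lineshape),
            class = "cest_pool")
}

#' @method print cest_pool
#' @export
print.cest_pool <- function(x, ...) {
  cat(sprintf("<pool %s> f = %.3g, shift = %g ppm, k = %g /s, T1 = %g s, T2 = %g s (%s)\n",
              x$name, x$fraction, x$shift_ppm, x$k_exch, x$T1, x$T2,
              x$lineshape))
  invisible(x)
}

#' Continuous rectangular saturation pulse
#'
#' @param b1_uT RF amplitude, microtesla.
#' @param duration_s saturation duration, seconds.
#' @return an object of class \code{saturation_pulse}; the shape is fixed
#'   to a continuous rectangular wave.
#' @seealso [pulse_preset()] for the protocols used in the tube and
#'   in vivo experiments.
#' @export
saturation_pulse <- function(b1_uT, duration_s) {
  if (!is.finite(b1_uT) || b1_uT < 0) stop("b1_uT must be >= 0")
  if (!is.finite(duration_s) || duration_s <= 0) stop("duration_s must be > 0")
  structure(list(b1_uT = b1_uT, duration_s = duration_s,
                 shape = "continuous rectangular"),
            class = "saturation_pulse")
}

#' Named saturation-pulse presets
#'
#' The presaturation protocols used across the experiments:
#' \describe{
#'   \item{eu_solution}{1.5 s, 15 uT (Eu-HPDO3A solution phantoms)}
#'   \item{eu_invivo}{800 ms, 23 uT (Eu-HPDO3A in vivo)}
#'   \item{eu_invivo_alt}{800 ms, 28 uT (alternative Eu in vivo setting)}
#'   \item{yb_solution}{1.5 s, 20 uT (Yb-HPDO3A solution phantoms)}
#'   \item{yb_invivo}{600 ms, 56 uT (Yb-HPDO3A in vivo)}
#'   \item{wassr}{1 s, 0.1 uT (low-power water-shift-referencing scan)}
#'   \item{wassr_short}{1 ms, 0.1 uT (as-printed WASSR duration; too
#'     short to produce an appreciable dip, kept for reference)}
#' }
#'
#' @param name preset name.
#' @return a [saturation_pulse()].
#' @export
#' @examples
#' pulse_preset("eu_solution")
pulse_preset <- function(name = c("eu_solution", "eu_invivo",
                                  "eu_invivo_alt", "yb_solution",
                                  "yb_invivo", "wassr", "wassr_short")) {
  name <- match.arg(name)
  switch(name,
    eu_solution   = saturation_pulse(15, 1.5),
    eu_invivo     = saturation_pulse(23, 0.8),
    eu_invivo_alt = saturation_pulse(28, 0.8),
    yb_solution   = saturation_pulse(20, 1.5),
    yb_invivo     = saturation_pulse(56, 0.6),
    wassr         = saturation_pulse(0.1, 1),
    wassr_short   = saturation_pulse(0.1, 0.001)
  )
}

#' Acquisition protocol: field, offset schedule and reference offsets
#'
#' @param offsets_ppm ordered list of saturation offsets (ppm).
#' @param b0_T static field, tesla (default 9.4).
#' @param reference_offsets_ppm offsets acquired as unsaturated-equivalent
#'   references for normalization (default 0, -300, +300 ppm).
#' @param gamma gyromagnetic ratio, rad s^-1 T^-1.
#' @return object of class \code{acq_protocol}.
#' @export
acquisition_protocol <- function(offsets_ppm, b0_T = 9.4,
                                 reference_offsets_ppm = c(0, -300, 300),
                                 gamma = GAMMA_H) {
  if (length(offsets_ppm) == 0) stop("offsets_ppm must be non-empty")
  if (!all(is.finite(offsets_ppm))) stop("offsets must be finite")
  structure(list(offsets_ppm = offsets_ppm, b0_T = b0_T,
                 reference_offsets_ppm = reference_offsets_ppm,
                 gamma = gamma),
            class = "acq_protocol")
}

#' Assemble a multi-pool spin system
#'
#' @param water the free-water [cest_pool()] (fraction 1, shift 0).
#' @param solutes list of solute (agent) pools, each with fraction < 0.01.
#' @param semisolid optional semisolid MT pool (super-Lorentzian).
#' @return object of class \code{spin_system}.
#' @export
spin_system <- function(water, solutes = list(), semisolid = NULL) {
  stopifnot(inherits(water, "cest_pool"))
  if (water$fraction != 1 || water$shift_ppm != 0) {
    stop("water pool must have fraction 1 and shift 0")
  }
  if (inherits(solutes, "cest_pool")) solutes <- list(solutes)
  for (p in solutes) {
    stopifnot(inherits(p, "cest_pool"))
    if (p$fraction >= 0.01) stop("solute fraction must be < 0.01")
    if (p$lineshape != "lorentzian") stop("solute pools must be Lorentzian")
  }
  if (!is.null(semisolid)) {
    stopifnot(inherits(semisolid, "cest_pool"))
    if (semisolid$lineshape != "super_lorentzian") {
      stop("semisolid pool must use the super_lorentzian lineshape")
    }
  }
  structure(list(water = water, solutes = solutes, semisolid = semisolid),
            class = "spin_system")
}

#' @method print spin_system
#' @export
print.spin_system <- function(x, ...) {
  n <- 1 + length(x$solutes) + !is.null(x$semisolid)
  cat(sprintf("<spin_system> %d pool(s)\n", n))
  print(x$water)
  for (p in x$solutes) print(p)
  if (!is.null(x$semisolid)) print(x$semisolid)
  invisible(x)
}

#' paraCEST agent presets
#'
#' Exchange-site presets for the two lanthanide agents: Eu-HPDO3A has a
#' single exchange site at +18 ppm with k = 5000 /s; Yb-HPDO3A has two
#' sites, +69 ppm (k = 10000 /s) and +97 ppm (k = 15000 /s). Each complex
#' carries one exchangeable proton; for Yb the proton population is split
#' equally between the two sites. Proton fractions follow
#' f_b = n_H * c / 111000 with c in mM.
#'
#' @param agent \code{"Eu-HPDO3A"} or \code{"Yb-HPDO3A"}.
#' @param conc_mM agent concentration, mM.
#' @return object of class \code{agent_preset} with per-site shifts,
#'   exchange rates and proton fractions.
#' @export
#' @examples
#' agent_preset("Eu-HPDO3A", 4)$sites
agent_preset <- function(agent = c("Eu-HPDO3A", "Yb-HPDO3A"), conc_mM) {
  agent <- match.arg(agent)
  if (!is.finite(conc_mM) || conc_mM < 0) {
    stop("conc_mM must be non-negative")
  }
  sites <- switch(agent,
    "Eu-HPDO3A" = data.frame(shift_ppm = 18, k_exch = 5000,
                             proton_share = 1),
    "Yb-HPDO3A" = data.frame(shift_ppm = c(69, 97),
                             k_exch = c(10000, 15000),
                             proton_share = c(0.5, 0.5))
  )
  sites$fraction <- sites$proton_share * conc_mM / WATER_PROTONS_MM
  structure(list(agent = agent, sites = sites, protons_per_site = 1,
                 conc_mM = conc_mM),
            class = "agent_preset")
}

# default environment parameters; all overridable via build_system()
default_env_params <- function(environment) {
  common <- list(solute_T1 = 1, solute_T2 = 0.01,
                 semisolid_T2 = 9.2e-6, semisolid_fraction = 0.10,
                 semisolid_k = 40, semisolid_T1 = 1)
  env <- switch(environment,
    solution = list(water_T1 = 3.0, water_T2 = 1.5),
    tissue   = list(water_T1 = 1.8, water_T2 = 0.04)
  )
  c(env, common)
}

#' Build a spin system from an agent preset
#'
#' Solution systems contain water plus the agent's exchange sites
#' (2 pools for Eu-HPDO3A, 3 for Yb-HPDO3A). Tissue systems add a
#' semisolid magnetization-transfer pool with a super-Lorentzian
#' lineshape (bound-water T2 default 9.2 us) and use tissue free-water
#' relaxation (T2 default 40 ms). All defaults can be overridden.
#'
#' @param preset an [agent_preset()], or \code{NULL} for an agent-free
#'   system (water only, plus the semisolid pool in tissue).
#' @param environment \code{"solution"} or \code{"tissue"}.
#' @param overrides named list overriding any of \code{water_T1},
#'   \code{water_T2}, \code{solute_T1}, \code{solute_T2},
#'   \code{semisolid_T1}, \code{semisolid_T2}, \code{semisolid_fraction},
#'   \code{semisolid_k}.
#' @return a [spin_system()].
#' @export
#' @examples
#' build_system(agent_preset("Eu-HPDO3A", 4), "solution")
#' build_system(agent_preset("Yb-HPDO3A", 9.5), "tissue")
build_system <- function(preset = NULL,
                         environment = c("solution", "tissue"),
                         overrides = list()) {
  environment <- match.arg(environment)
  if (!is.null(preset) && !inherits(preset, "agent_preset")) {
    stop("preset must be an agent_preset or NULL")
  }
  par <- default_env_params(environment)
  unknown <- setdiff(names(overrides), names(par))
  if (length(unknown)) {
    stop("unknown override(s): ", paste(unknown, collapse = ", "))
  }
  par[names(overrides)] <- overrides

  water <- cest_pool("water", 1, 0, 0, par$water_T1, par$water_T2)
  solutes <- list()
  if (!is.null(preset)) {
    s <- preset$sites
    solutes <- lapply(seq_len(nrow(s)), function(i) {
      cest_pool(sprintf("%s@%gppm", preset$agent, s$shift_ppm[i]),
                fraction = s$fraction[i], shift_ppm = s$shift_ppm[i],
                k_exch = s$k_exch[i], T1 = par$solute_T1,
                T2 = par$solute_T2)
    })
  }
  semisolid <- NULL
  if (environment == "tissue") {
    semisolid <- cest_pool("semisolid", par$semisolid_fraction, 0,
                           par$semisolid_k, par$semisolid_T1,
                           par$semisolid_T2,
                           lineshape = "super_lorentzian")
  }
  spin_system(water, solutes, semisolid)
}
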