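#' Physical constants and unit conversions
#'
#' Proton gyromagnetic ratio in rad s^-1 T^-1.
#' @keywords internal
GAMMA_H <- 2.675221e8

#' Water proton concentration used for proton-fraction bookkeeping (mM).
#' @keywords internal
WATER_PROTONS_MM <- 111000

#' Convert a chemical-shift offset in ppm to Hz
#'
#' Offsets are expressed in ppm downfield of the water resonance; the
#' conversion uses the proton Larmor frequency at the given static field.
#'
#' @param ppm numeric vector of offsets (ppm).
#' @param b0_T static field strength in tesla (default 9.4).
#' @param gamma gyromagnetic ratio in rad s^-1 T^-1.
#' @return offsets in Hz.
#' @export
#' @examples
#' ppm_to_hz(18)            # Eu-HPDO3A site at 9.4 T
ppm_to_hz <- function(ppm, b0_T = 9.4, gamma = GAMMA_H) {
  ppm * (gamma * b0_T / (2 * pi)) * 1e-6
}

#' Convert an RF amplitude in microtesla to a nutation rate in rad/s
#'
#' @param b1_uT RF amplitude in microtesla.
#' @param gamma gyromagnetic ratio in rad s^-1 T^-1.
#' @return omega1 in rad/s.
#' @export
uT_to_rad_s <- function(b1_uT, gamma = GAMMA_H) {
  gamma * b1_uT * 1e-6
}
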