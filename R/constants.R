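# Physical constants used throughout the spin-dynamics simulator.
# SI units; gyromagnetic ratios in rad s^-1 T^-1.

.GAMMA_H <- 2.6752218744e8
.GAMMA_N <- -2.7126180e7
.HBAR <- 1.054571817e-34
.MU0_4PI <- 1e-7
.R_HN <- 1.02e-10 # amide H-N bond length (m)
.CSA_N <- -164e-6 # 15N chemical shift anisotropy

# Imaginary-part threshold (s^-1) below which a Liouvillian eigenvalue is
# treated as real by the dephasing propagator.
.REAL_EIG_TOL <- 1e-3

#' Proton Larmor frequency for a given static field
#'
#' @param b0 Static magnetic field (T).
#' @return The 1H Larmor frequency in MHz (e.g. about 800 MHz at 18.8 T).
#' @export
larmor_mhz <- function(b0) {
  .GAMMA_H / (2 * pi) * b0 * 1e-6
}

#' Convert between ppm and Hz on the 1H axis
#'
#' @param x Value(s) to convert.
#' @param b0 Static magnetic field (T).
#' @return Converted value(s).
#' @export
ppm_to_hz <- function(x, b0) x * larmor_mhz(b0)

#' @rdname ppm_to_hz
#' @export
hz_to_ppm <- function(x, b0) x / larmor_mhz(b0)
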