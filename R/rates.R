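#' Kinetic rate matrix of an exchange scenario
#'
#' Builds the 3 x 3 first-order rate matrix `K` over the states (G, E1, E2)
#' such that populations evolve as `dp/dt = K p`. Within each branch of the
#' forked model E1 <-> G <-> E2 the total branch exchange rate is
#' `kex = k_forward + k_backward` and detailed balance
#' `k_G->Ei * p_G = k_Ei->G * p_Ei` holds, so that the stationary
#' distribution of `K` equals the input populations.
#'
#' @param scenario An [exchange_scenario()].
#' @return A 3 x 3 matrix (s^-1) whose columns sum to zero.
#' @examples
#' sc <- exchange_scenario(c(0.95, 0.05, 0), kex = c(100, 0),
#'                         shifts = c(8, 9, 0))
#' build_rate_matrix(sc) # k_G->E = 5, k_E->G = 95
#' @export
build_rate_matrix <- function(scenario) {
  stopifnot(inherits(scenario, "exchange_scenario"))
  p <- scenario$populations
  kex <- scenario$kex
  K <- matrix(0, 3, 3, dimnames = list(c("G", "E1", "E2"), c("G", "E1", "E2")))
  for (i in 1:2) {
    pe <- p[i + 1]
    if (pe > 0 && kex[i] > 0) {
      tot <- p[1] + pe
      k_ge <- kex[i] * pe / tot
      k_eg <- kex[i] * p[1] / tot
      K[i + 1, 1] <- k_ge # G -> Ei
      K[1, i + 1] <- k_eg # Ei -> G
    }
  }
  diag(K) <- -colSums(K)
  K
}

#' Ground-state relaxation rates from the rotational correlation time
#'
#' Computes the amide-proton and nitrogen relaxation rates of a rigid,
#' isotropically tumbling, perdeuterated amide group: 1H-15N dipolar
#' relaxation (r_HN = 1.02 A) for the proton, and dipolar plus 15N CSA
#' (-164 ppm) relaxation for the nitrogen, using the rigid spectral density
#' J(w) = (2/5) tau / (1 + (w tau)^2). Remote protons are neglected
#' (perdeuterated samples).
#'
#' @param tau_m Rotational correlation time (ns).
#' @param b0 Static field (T).
#' @return A list with elements `r1_h`, `r2_h`, `r1_n` (s^-1).
#' @examples
#' relaxation_rates(10, 18.8)
#' @export
relaxation_rates <- function(tau_m, b0) {
  if (tau_m <= 0) stop("tau_m must be positive", call. = FALSE)
  tau <- tau_m * 1e-9
  wh <- .GAMMA_H * b0
  wn <- abs(.GAMMA_N) * b0
  jw <- function(w) 0.4 * tau / (1 + (w * tau)^2)
  d <- .MU0_4PI * .HBAR * .GAMMA_H * abs(.GAMMA_N) / .R_HN^3
  d2 <- d^2
  c2 <- (wn * .CSA_N)^2 / 3 # 15N CSA interaction strength

  r1_h <- (d2 / 4) * (jw(wh - wn) + 3 * jw(wh) + 6 * jw(wh + wn))
  r2_h <- (d2 / 8) * (4 * jw(0) + jw(wh - wn) + 3 * jw(wh) +
                        6 * jw(wn) + 6 * jw(wh + wn))
  r1_n <- (d2 / 4) * (jw(wh - wn) + 3 * jw(wn) + 6 * jw(wh + wn)) +
    c2 * jw(wn)
  list(r1_h = r1_h, r2_h = r2_h, r1_n = r1_n)
}
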