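#' Define a conformational exchange scenario
#'
#' An exchange scenario describes a ground state G exchanging with up to two
#' sparsely populated excited states in the forked topology E1 <-> G <-> E2,
#' together with the spin parameters needed to simulate amide-proton CEST
#' profiles.
#'
#' @param populations Numeric vector of state populations `(p_G, p_E1, p_E2)`
#'   summing to 1. For a two-state system set `p_E2 = 0`; for a single state
#'   set both excited populations to 0.
#' @param kex Branch exchange rates `(kex_GE1, kex_GE2)` in s^-1, each the sum
#'   of the forward and backward rate constants of that branch.
#' @param shifts Chemical shifts `(w_G, w_E1, w_E2)` in ppm.
#' @param tau_m Rotational correlation time (ns); all ground-state relaxation
#'   rates are computed from it (see [relaxation_rates()]).
#' @param j_hn One-bond 1H-15N scalar coupling (Hz, negative; about -93 Hz).
#' @param r_ex Microsecond-exchange contribution added to R2 of every state
#'   (s^-1).
#' @param dr2 Excited-state amide-proton R2 offsets
#'   `(R2(E1) - R2(G), R2(E2) - R2(G))` in s^-1.
#' @return An object of class `exchange_scenario`.
#' @examples
#' sc <- exchange_scenario(
#'   populations = c(0.95, 0.05, 0), kex = c(100, 0),
#'   shifts = c(8.2, 8.9, 0), tau_m = 10, j_hn = -93
#' )
#' @export
exchange_scenario <- function(populations, kex = c(0, 0), shifts,
                              tau_m = 10, j_hn = -93, r_ex = 0,
                              dr2 = c(0, 0)) {
  populations <- as.numeric(populations)
  if (length(populations) == 2) populations <- c(populations, 0)
  stopifnot(length(populations) == 3)
  if (any(populations < 0)) {
    stop("populations must be non-negative", call. = FALSE)
  }
  if (abs(sum(populations) - 1) > 1e-8) {
    stop("populations must sum to 1", call. = FALSE)
  }
  kex <- as.numeric(kex)
  if (length(kex) == 1) kex <- c(kex, 0)
  stopifnot(length(kex) == 2)
  if (any(kex < 0)) stop("exchange rates must be non-negative", call. = FALSE)
  shifts <- as.numeric(shifts)
  if (length(shifts) < 3) shifts <- c(shifts, rep(0, 3 - length(shifts)))
  if (tau_m <= 0) stop("tau_m must be positive", call. = FALSE)
  dr2 <- as.numeric(dr2)
  if (length(dr2) == 1) dr2 <- c(dr2, 0)

  n_states <- if (populations[3] > 0) 3L else if (populations[2] > 0) 2L else 1L
  # an unpopulated state cannot exchange
  if (populations[2] == 0) kex[1] <- 0
  if (populations[3] == 0) kex[2] <- 0

  structure(
    list(
      n_states = n_states, populations = populations, kex = kex,
      shifts = shifts, tau_m = tau_m, j_hn = j_hn, r_ex = r_ex, dr2 = dr2
    ),
    class = "exchange_scenario"
  )
}

#' @export
print.exchange_scenario <- function(x, ...) {
  cat(sprintf(
    "<exchange_scenario> %d state(s)\n  p = (%s)\n  kex = (%s) s^-1\n  shifts = (%s) ppm\n  tau_m = %g ns, J_HN = %g Hz, R_ex = %g s^-1, dR2 = (%s) s^-1\n",
    x$n_states, paste(signif(x$populations, 4), collapse = ", "),
    paste(signif(x$kex, 4), collapse = ", "),
    paste(signif(x$shifts, 4), collapse = ", "),
    x$tau_m, x$j_hn, x$r_ex, paste(signif(x$dr2, 4), collapse = ", ")
  ))
  invisible(x)
}

#' Define the acquisition settings of a CEST experiment
#'
#' @param b0 Static field (T). `b0 = 18.8` corresponds to a 1H Larmor
#'   frequency of roughly 800 MHz.
#' @param b1 Saturation field strength (Hz).
#' @param offsets Regular grid of B1 carrier positions (ppm). Alternatively
#'   supply `offset_min`, `offset_span` and `n_offsets`.
#' @param tex CEST relaxation delay (s).
#' @param d1 Inter-scan delay (s); retained as metadata.
#' @param offset_min,offset_span,n_offsets Convenience constructor for a
#'   regular offset grid covering `[offset_min, offset_min + offset_span]`.
#' @return An object of class `acquisition_config`.
#' @examples
#' cfg <- acquisition_config(b0 = 18.8, b1 = 30, offset_min = 6.6,
#'                           offset_span = 3.4, n_offsets = 90)
#' @export
acquisition_config <- function(b0 = 18.8, b1 = 30, offsets = NULL,
                               tex = 0.4, d1 = 0.5,
                               offset_min = 6.6, offset_span = 3.4,
                               n_offsets = 90) {
  if (is.null(offsets)) {
    offsets <- seq(offset_min, offset_min + offset_span,
                   length.out = n_offsets)
  }
  offsets <- as.numeric(offsets)
  if (length(offsets) < 2) stop("need at least two offsets", call. = FALSE)
  step <- diff(offsets)
  if (max(abs(step - step[1])) > 1e-6 * abs(step[1])) {
    stop("offsets must form a regular grid", call. = FALSE)
  }
  if (b1 < 0) stop("b1 must be non-negative", call. = FALSE)
  if (tex <= 0) stop("tex must be positive", call. = FALSE)
  structure(
    list(b0 = b0, b1 = b1, offsets = offsets, tex = tex, d1 = d1),
    class = "acquisition_config"
  )
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf(
    "<acquisition_config> B0 = %g T (%.0f MHz), B1 = %g Hz, T_ex = %g s\n  %d offsets from %.3f to %.3f ppm\n",
    x$b0, larmor_mhz(x$b0), x$b1, x$tex, length(x$offsets),
    min(x$offsets), max(x$offsets)
  ))
  invisible(x)
}
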