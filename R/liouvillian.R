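#' Build the Liouvillian of an exchanging amide-proton spin system
#'
#' Constructs the real evolution matrix `L` (s^-1) such that the
#' magnetization vector evolves as `M(t) = exp(-L t) M(0)` during the CEST
#' element, at a given B1 carrier offset.
#'
#' For `phase = "ap"` (anti-phase) the basis per exchange state is
#' `{Hx, Hy, Hz}` in each of the two 15N longitudinal manifolds (alpha,
#' beta), i.e. six operators per state. The alpha manifold precesses at
#' `Omega + pi * J_HN`, the beta manifold at `Omega - pi * J_HN` (with
#' `Omega` the offset from the carrier in rad/s), manifold interchange
#' proceeds at the 15N longitudinal relaxation rate, and chemical exchange
#' couples corresponding operators across states with rates from
#' [build_rate_matrix()]. Transverse relaxation of every state includes the
#' microsecond-exchange contribution `r_ex`; excited states additionally
#' carry their `dr2` offsets.
#'
#' For `phase = "ip"` (in-phase) the scalar coupling and the manifold
#' structure are absent: three operators per state.
#'
#' @param scenario An [exchange_scenario()].
#' @param config An [acquisition_config()]; its `b1` may be overridden.
#' @param offset B1 carrier position (ppm).
#' @param phase `"ap"` or `"ip"`.
#' @param b1 Optional B1 override (Hz).
#' @return A list of class `liouvillian` with elements `matrix` (square,
#'   real), `basis` (labels) and `phase`.
#' @export
build_liouvillian <- function(scenario, config, offset, phase = c("ap", "ip"),
                              b1 = NULL) {
  stopifnot(inherits(scenario, "exchange_scenario"),
            inherits(config, "acquisition_config"))
  phase <- match.arg(phase)
  if (is.null(b1)) b1 <- config$b1
  ns <- scenario$n_states
  rates <- relaxation_rates(scenario$tau_m, config$b0)
  r2 <- rates$r2_h + scenario$r_ex + c(0, scenario$dr2)[seq_len(ns)]
  r1 <- rates$r1_h
  r1n <- rates$r1_n
  w1 <- 2 * pi * b1
  lar <- larmor_mhz(config$b0)
  omega <- 2 * pi * (scenario$shifts[seq_len(ns)] - offset) * lar
  K <- build_rate_matrix(scenario)[seq_len(ns), seq_len(ns), drop = FALSE]

  bloch_block <- function(om, r2s) {
    matrix(c(r2s, om, 0,
             -om, r2s, w1,
             0, -w1, r1), 3, 3)
  }

  if (phase == "ip") {
    nb <- 3L
    L <- matrix(0, nb * ns, nb * ns)
    basis <- character(nb * ns)
    for (s in seq_len(ns)) {
      i0 <- (s - 1L) * nb
      L[i0 + 1:3, i0 + 1:3] <- bloch_block(omega[s], r2[s])
      basis[i0 + 1:3] <- paste0(c("Hx", "Hy", "Hz"), "_", s)
    }
    L <- L - K %x% diag(nb)
  } else {
    nb <- 6L
    pj <- pi * scenario$j_hn
    L <- matrix(0, nb * ns, nb * ns)
    basis <- character(nb * ns)
    for (s in seq_len(ns)) {
      i0 <- (s - 1L) * nb
      L[i0 + 1:3, i0 + 1:3] <- bloch_block(omega[s] + pj, r2[s])
      L[i0 + 4:6, i0 + 4:6] <- bloch_block(omega[s] - pj, r2[s])
      # 15N longitudinal relaxation interchanges the two manifolds
      for (k in 1:6) L[i0 + k, i0 + k] <- L[i0 + k, i0 + k] + r1n / 2
      for (k in 1:3) {
        L[i0 + k, i0 + k + 3] <- L[i0 + k, i0 + k + 3] - r1n / 2
        L[i0 + k + 3, i0 + k] <- L[i0 + k + 3, i0 + k] - r1n / 2
      }
      basis[i0 + 1:6] <- paste0(c("Hxa", "Hya", "Hza", "Hxb", "Hyb", "Hzb"),
                                "_", s)
    }
    L <- L - K %x% diag(nb)
  }
  structure(list(matrix = L, basis = basis, phase = phase),
            class = "liouvillian")
}

#' Real-eigenvalue dephasing propagator
#'
#' Computes the propagator retaining only the eigenvectors of the
#' Liouvillian whose eigenvalues are real: after the eigendecomposition
#' `L V = V D`, the propagator is `V_re exp(-t D_re) V_re^-1`, where the
#' subscript selects eigenvalues with `|Im(lambda)| <= 1e-3` s^-1 and
#' `V_re^-1` denotes the matching rows of `V^-1`. Discarding the
#' oscillatory (complex-eigenvalue) part of the spectrum mimics the
#' dephasing produced by an inhomogeneous B1 field and yields smooth CEST
#' profiles without explicit averaging over a B1 distribution.
#'
#' @param L A `liouvillian` or a square numeric matrix.
#' @param duration Propagation time (s).
#' @return A real square matrix of the same dimension as `L`.
#' @export
real_eig_propagator <- function(L, duration) {
  if (inherits(L, "liouvillian")) L <- L$matrix
  stopifnot(is.matrix(L), nrow(L) == ncol(L), duration >= 0)
  eg <- eigen(L)
  idx <- which(abs(Im(eg$values)) <= .REAL_EIG_TOL)
  vinv <- tryCatch(solve(eg$vectors), error = function(e) {
    stop("eigendecomposition of the Liouvillian is singular; ",
         "perturb degenerate shifts (see simulate_* offset jitter): ",
         conditionMessage(e), call. = FALSE)
  })
  if (length(idx) == 0L) {
    return(matrix(0, nrow(L), ncol(L)))
  }
  P <- eg$vectors[, idx, drop = FALSE] %*%
    diag(exp(-duration * eg$values[idx]), length(idx)) %*%
    vinv[idx, , drop = FALSE]
  P <- zapsmall_complex(P)
  P
}

# Full matrix exponential exp(-L t) through the eigendecomposition.
# Used for the explicit INEPT element, where coherent J evolution must be
# retained.
expm_liouvillian <- function(L, duration) {
  if (inherits(L, "liouvillian")) L <- L$matrix
  eg <- eigen(L)
  P <- eg$vectors %*% diag(exp(-duration * eg$values), nrow(L)) %*%
    solve(eg$vectors)
  zapsmall_complex(P)
}

zapsmall_complex <- function(P) {
  im <- max(abs(Im(P)))
  re <- max(abs(Re(P)))
  if (im > 1e-8 * max(re, 1)) {
    warning(sprintf("propagator has unexpected imaginary part (%.3g)", im))
  }
  Re(P)
}
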