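# On-the-fly sampler of training scenarios and examples for the two
# networks. Parameter ranges are the study conditions for the synthetic
# training data: five static fields, B1 of 15-50 Hz, a 3.4 ppm offset
# window sampled at 50-128 points, T_ex = 0.4 s, tau_m of 3-20 ns,
# 1J_HN of -95 to -91 Hz, R_ex = |N(1, 2)| s^-1, excited-state dR2 from
# N(0, 2) s^-1, shifts uniform over the sweep width, kex of 10-300 s^-1,
# excited-state populations of 0.01-0.15, and forked three-site exchange
# with probability 25%.

.B0_SET <- c(14.1, 16.4, 18.8, 21.1, 23.5)
.OFFSET_SPAN <- 3.4

#' Sample a random training scenario and acquisition configuration
#'
#' Draws one (scenario, configuration) pair from the training distribution
#' described above, using the current R random number generator state (set a
#' seed for reproducibility). With probability 25% the scenario is a forked
#' three-site exchange E1 <-> G <-> E2; otherwise the E2 population is zero.
#' Excited-state slots are ordered by population, descending.
#'
#' @param offset_min Lower edge of the offset window (ppm); the window spans
#'   3.4 ppm.
#' @return A list with elements `scenario` ([exchange_scenario()]) and
#'   `config` ([acquisition_config()]).
#' @examples
#' set.seed(1)
#' draw <- sample_scenario()
#' draw$scenario
#' @export
sample_scenario <- function(offset_min = 6.6) {
  three_site <- runif(1) < 0.25
  p_e <- runif(2, 0.01, 0.15)
  kex <- runif(2, 10, 300)
  shifts_e <- runif(2, offset_min, offset_min + .OFFSET_SPAN)
  if (!three_site) {
    p_e[2] <- 0
    kex[2] <- 0
  } else if (p_e[2] > p_e[1]) {
    # fixed slot semantics: excited states ordered by population
    p_e <- p_e[2:1]
    kex <- kex[2:1]
    shifts_e <- shifts_e[2:1]
  }
  scenario <- exchange_scenario(
    populations = c(1 - sum(p_e), p_e),
    kex = kex,
    shifts = c(runif(1, offset_min, offset_min + .OFFSET_SPAN), shifts_e),
    tau_m = runif(1, 3, 20),
    j_hn = runif(1, -95, -91),
    r_ex = abs(rnorm(1, 1, 2)),
    dr2 = rnorm(2, 0, 2)
  )
  n_pts <- sample(50:128, 1)
  config <- acquisition_config(
    b0 = sample(.B0_SET, 1),
    b1 = runif(1, 15, 50),
    offset_min = offset_min, offset_span = .OFFSET_SPAN,
    n_offsets = n_pts,
    tex = 0.4, d1 = 0.5
  )
  list(scenario = scenario, config = config)
}

#' Add Gaussian noise to a CEST profile
#'
#' Adds i.i.d. Gaussian noise with standard deviation
#' `sigma_frac * max(intensity)`.
#'
#' @param profile A [cest_profile()].
#' @param sigma_frac Noise standard deviation as a fraction of the profile
#'   maximum.
#' @return The noisy profile (noise level recorded in the metadata).
#' @export
add_noise <- function(profile, sigma_frac) {
  stopifnot(sigma_frac >= 0)
  if (sigma_frac == 0) return(profile)
  sigma <- sigma_frac * max(profile$intensity)
  profile$intensity <- profile$intensity + rnorm(nrow(profile), 0, sigma)
  attr(profile, "noise") <- sigma_frac
  profile
}

#' Build one training example for the transformation network
#'
#' Simulates the anti-phase profile of a scenario, adds noise, and packs it
#' (dip transform, real FT, zero-fill) into the two length-130 input
#' vectors; the target is the clean in-phase profile of the same scenario
#' resampled at 128 offsets and dip-transformed. Noise is applied only to
#' the input, never to the target.
#'
#' @param scenario,config A draw from [sample_scenario()].
#' @param noise_frac Input noise level (fraction of the profile maximum).
#' @param inept INEPT mode passed to [simulate_ap_profile()].
#' @return A list with `input` (list of `coef` and `time`, both length
#'   130), `target` (128 values), `f_true`, `indicator`, `n_original`, and
#'   the generating `scenario`/`config`.
#' @export
make_tr_example <- function(scenario, config, noise_frac = 0.01,
                            inept = "explicit") {
  ap <- simulate_ap_profile(scenario, config, inept = inept)
  ap <- add_noise(ap, noise_frac)
  input <- pack_profile(ap)
  cfg128 <- acquisition_config(
    b0 = config$b0, b1 = config$b1,
    offsets = seq(min(config$offsets), max(config$offsets),
                  length.out = .UPSAMPLED_SIZE),
    tex = config$tex, d1 = config$d1
  )
  ip <- simulate_ip_profile(scenario, cfg128)
  truth <- shift_targets(scenario, config)
  list(input = input, target = dip_transform(ip),
       f_true = truth$f_true, indicator = truth$indicator,
       n_original = length(config$offsets),
       scenario = scenario, config = config)
}

#' Build one training example for the chemical-shift network
#'
#' The network input is the 128-point in-phase profile produced by the
#' transformation network (pass `tr_output`); the targets are the true
#' normalized shifts and the state-indicator vector. For unit testing, the
#' clean simulated in-phase profile may be passed instead of a network
#' output (bypass mode; training proper always goes through the
#' transformation network).
#'
#' @param tr_output Numeric vector of 128 values (dip-form in-phase
#'   profile).
#' @param scenario The generating [exchange_scenario()].
#' @param config The generating [acquisition_config()] (defines the offset
#'   window for the shift normalization).
#' @return A list with `input`, `f_true` (3 values in (0,1)) and
#'   `indicator` (1 for each present state).
#' @export
make_cs_example <- function(tr_output, scenario, config) {
  stopifnot(length(tr_output) == .UPSAMPLED_SIZE)
  truth <- shift_targets(scenario, config)
  list(input = as.numeric(tr_output), f_true = truth$f_true,
       indicator = truth$indicator)
}

# Normalized shift targets and state indicator of a scenario within the
# offset window of a configuration. The slot of an absent state has no
# meaningful shift; its target is parked at 0.5 (its loss weight vanishes as
# the trained uncertainty grows, so the value is immaterial).
shift_targets <- function(scenario, config) {
  lo <- min(config$offsets)
  span <- max(config$offsets) - lo
  f <- (scenario$shifts - lo) / span
  present <- seq_len(3) <= scenario$n_states
  if (any(f[present] < 0 | f[present] > 1)) {
    stop("state shift outside the offset window", call. = FALSE)
  }
  f[!present] <- 0.5
  list(f_true = f, indicator = as.numeric(present))
}

#' Generate a batch of training examples
#'
#' Draws `n` scenarios and builds the full set of arrays needed to train
#' either network: packed anti-phase inputs, clean in-phase targets, true
#' shifts and state indicators.
#'
#' @param n Number of examples.
#' @param seed Optional seed for full reproducibility.
#' @param noise Either a single noise fraction (transformation-network
#'   regime, 0.01) or a range `c(lo, hi)` from which each profile's noise
#'   level is drawn uniformly (shift-network regime, `c(0.001, 0.04)`).
#' @param offset_min Lower edge of the offset window (ppm).
#' @param states Restrict sampling to scenarios with this number of states
#'   (`NULL` for the native 75/25 two-/three-site mixture).
#' @param inept INEPT mode for the anti-phase simulation.
#' @return A list with matrices `coef`, `time` (`n` x 130), `target`
#'   (`n` x 128), `f_true`, `indicator` (`n` x 3), integer vector
#'   `n_original`, and `draws` (the scenario/config pairs).
#' @export
generate_tr_examples <- function(n, seed = NULL, noise = 0.01,
                                 offset_min = 6.6, states = NULL,
                                 inept = "explicit") {
  if (!is.null(seed)) set.seed(seed)
  coef <- matrix(0, n, 2L * .PACKED_SIZE)
  tim <- matrix(0, n, 2L * .PACKED_SIZE)
  target <- matrix(0, n, .UPSAMPLED_SIZE)
  f_true <- matrix(0, n, 3L)
  indicator <- matrix(0, n, 3L)
  n_original <- integer(n)
  draws <- vector("list", n)
  for (i in seq_len(n)) {
    draw <- sample_scenario(offset_min = offset_min)
    if (!is.null(states)) {
      while (draw$scenario$n_states != states) {
        draw <- sample_scenario(offset_min = offset_min)
      }
    }
    nf <- if (length(noise) == 2) runif(1, noise[1], noise[2]) else noise
    ex <- make_tr_example(draw$scenario, draw$config, noise_frac = nf,
                          inept = inept)
    coef[i, ] <- ex$input$coef
    tim[i, ] <- ex$input$time
    target[i, ] <- ex$target
    f_true[i, ] <- ex$f_true
    indicator[i, ] <- ex$indicator
    n_original[i] <- ex$n_original
    draws[[i]] <- draw
  }
  list(coef = coef, time = tim, target = target, f_true = f_true,
       indicator = indicator, n_original = n_original, draws = draws)
}
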