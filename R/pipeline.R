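# End-to-end one-shot analysis: anti-phase profile -> transformation
# network -> in-phase profile -> shift network -> shifts + uncertainties;
# plus the least-squares fitting back-end and the calibration and
# consistency evaluators used to validate the stacked analysis.

#' One-shot analysis of an anti-phase CEST profile
#'
#' Applies the two trained networks sequentially: the profile is packed
#' (dip transform, real FT, zero-fill), decoupled and upsampled by the
#' transformation network, and the 128-point in-phase profile is passed to
#' the shift network, which reports three chemical shifts with confidences
#' and calibrated uncertainties.
#'
#' Predictions with `c_pred < 0.4` are flagged (`pass_c04 = FALSE`) but
#' never dropped: below that confidence the mapped uncertainty is no longer
#' a reliable error estimate.
#'
#' @param profile An anti-phase [cest_profile()].
#' @param tr_model A trained transformation network ([train_dnn_tr()]).
#' @param cs_model A trained shift network ([train_dnn_cs()]).
#' @return A tibble of class `cest_analysis` with one row per state slot
#'   (`state_slot`, `f_pred`, `c_pred`, `delta_ppm`, `sigma_ppm`,
#'   `pass_c04`); the transformed in-phase profile is attached as attribute
#'   `"ip_profile"`.
#' @export
analyze_profile <- function(profile, tr_model, cs_model) {
  stopifnot(inherits(profile, "cest_profile"))
  span <- max(profile$offset) - min(profile$offset)
  if (abs(span - 3.4) > 0.34) {
    warning(sprintf(
      "offset span %.2f ppm is far from the 3.4 ppm training span; ",
      span), "predictions are outside the training distribution")
  }
  ip <- transform_profile(tr_model, profile)
  res <- predict_shifts(cs_model, attr(ip, "dip"),
                        offset_min = min(profile$offset), span = span)
  res$profile <- NULL
  class(res) <- c("cest_analysis", class(res))
  attr(res, "ip_profile") <- ip
  attr(res, "meta") <- profile_meta(profile)
  res
}

#' Analyze a batch of profiles
#'
#' @param profiles A (named) list of anti-phase [cest_profile()]s.
#' @inheritParams analyze_profile
#' @return A tibble with an `id` column and one row per profile and state
#'   slot.
#' @export
analyze_profiles <- function(profiles, tr_model, cs_model) {
  ids <- names(profiles)
  if (is.null(ids)) ids <- as.character(seq_along(profiles))
  purrr::map2_dfr(profiles, ids, function(p, id) {
    res <- analyze_profile(p, tr_model, cs_model)
    dplyr::bind_cols(tibble::tibble(id = id), tibble::as_tibble(res))
  })
}

#' Keep every k-th point of a profile
#'
#' Used for the full-versus-reduced-sampling consistency analysis.
#'
#' @param profile A [cest_profile()].
#' @param by Keep every `by`-th offset.
#' @return The thinned profile.
#' @export
thin_profile <- function(profile, by = 2) {
  out <- profile[seq(1, nrow(profile), by = by), ]
  for (a in c("phase", "b0", "b1", "tex", "noise", "provenance")) {
    attr(out, a) <- attr(profile, a)
  }
  class(out) <- class(profile)
  out
}

## ---- least-squares fitting -------------------------------------------------

# pack/unpack the floated parameters of a scenario
lsq_pack <- function(scenario, float) {
  ns <- scenario$n_states
  par <- c()
  if ("shifts" %in% float) {
    par <- c(par, setNames(scenario$shifts[seq_len(ns)],
                           paste0("shift_", c("G", "E1", "E2")[seq_len(ns)])))
  }
  if (ns >= 2 && "kex" %in% float) {
    par <- c(par, setNames(scenario$kex[seq_len(ns - 1)],
                           paste0("kex_GE", seq_len(ns - 1))))
  }
  if (ns >= 2 && "populations" %in% float) {
    par <- c(par, setNames(scenario$populations[2:ns],
                           paste0("p_E", seq_len(ns - 1))))
  }
  if (ns >= 2 && "dr2" %in% float) {
    par <- c(par, setNames(scenario$dr2[seq_len(ns - 1)],
                           paste0("dr2_E", seq_len(ns - 1))))
  }
  par
}

lsq_unpack <- function(par, scenario, float) {
  ns <- scenario$n_states
  sc <- scenario
  if ("shifts" %in% float) {
    sc$shifts[seq_len(ns)] <-
      par[paste0("shift_", c("G", "E1", "E2")[seq_len(ns)])]
  }
  if (ns >= 2 && "kex" %in% float) {
    sc$kex[seq_len(ns - 1)] <- pmax(par[paste0("kex_GE", seq_len(ns - 1))], 0)
  }
  if (ns >= 2 && "populations" %in% float) {
    pe <- pmin(pmax(par[paste0("p_E", seq_len(ns - 1))], 1e-4), 0.4)
    sc$populations[2:ns] <- pe
    sc$populations[1] <- 1 - sum(sc$populations[-1])
  }
  if (ns >= 2 && "dr2" %in% float) {
    sc$dr2[seq_len(ns - 1)] <- par[paste0("dr2_E", seq_len(ns - 1))]
  }
  sc
}

#' Least-squares analysis of CEST profiles
#'
#' Fits the spin-dynamics forward model ([simulate_ap_profile()] /
#' [simulate_ip_profile()]) to one or more profiles by Levenberg-Marquardt
#' least squares. Multiple profiles (for example two B1 fields) are fitted
#' jointly and share all floated parameters. By default the chemical
#' shifts, branch exchange rates, excited-state populations and
#' excited-state R2 offsets float, while the relaxation baseline (from
#' `tau_m`), the scalar coupling and `r_ex` stay fixed at the values of the
#' starting scenario. Parameter uncertainties are taken from the covariance
#' matrix at the optimum.
#'
#' @param profiles A [cest_profile()] or list of them; each must carry
#'   `b0`, `b1`, `tex` metadata.
#' @param scenario_start An [exchange_scenario()] with the starting values;
#'   its `n_states` fixes the model.
#' @param float Character vector among `"shifts"`, `"kex"`,
#'   `"populations"`, `"dr2"`.
#' @param inept INEPT mode of the forward model (for anti-phase profiles).
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @return An object of class `cest_lsq_fit`; see [tidy()] and [glance()]
#'   methods.
#' @export
least_squares_fit <- function(profiles, scenario_start,
                              float = c("shifts", "kex", "populations",
                                        "dr2"),
                              inept = "explicit", max_iter = 100) {
  if (inherits(profiles, "cest_profile")) profiles <- list(profiles)
  stopifnot(inherits(scenario_start, "exchange_scenario"))
  configs <- lapply(profiles, function(p) {
    m <- profile_meta(p)
    if (is.na(m$b0) || is.na(m$b1) || is.na(m$tex)) {
      stop("profiles must carry b0/b1/tex metadata", call. = FALSE)
    }
    acquisition_config(b0 = m$b0, b1 = m$b1, offsets = p$offset, tex = m$tex)
  })
  phases <- vapply(profiles, function(p) attr(p, "phase"), character(1))
  obs <- unlist(lapply(profiles, function(p) p$intensity))

  par0 <- lsq_pack(scenario_start, float)
  resid_fn <- function(par) {
    names(par) <- names(par0)
    sc <- lsq_unpack(par, scenario_start, float)
    sim <- unlist(purrr::map2(configs, phases, function(cfg, ph) {
      if (ph == "ap") {
        simulate_ap_profile(sc, cfg, inept = inept)$intensity
      } else {
        simulate_ip_profile(sc, cfg)$intensity
      }
    }))
    sim - obs
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter))
  converged <- fit$info %in% 1:4
  if (!converged) {
    warning("least-squares fit did not converge (info = ", fit$info, "): ",
            fit$message)
  }
  n_obs <- length(obs)
  n_par <- length(par0)
  s2 <- fit$deviance / max(n_obs - n_par, 1)
  cov <- tryCatch(2 * s2 * solve(fit$hessian), error = function(e) {
    matrix(NA_real_, n_par, n_par)
  })
  se <- sqrt(pmax(diag(cov), 0))
  structure(
    list(
      parameters = tibble::tibble(
        term = names(par0),
        estimate = as.numeric(fit$par),
        std_error = as.numeric(se)
      ),
      scenario = lsq_unpack(setNames(as.numeric(fit$par), names(par0)),
                            scenario_start, float),
      fit = fit, converged = converged, n_obs = n_obs,
      n_iter = fit$niter, rss = fit$deviance, sigma = sqrt(s2)
    ),
    class = "cest_lsq_fit"
  )
}

#' @export
print.cest_lsq_fit <- function(x, ...) {
  cat(sprintf("<cest_lsq_fit> %s, %d iterations, RSS %.4g\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, x$rss))
  print(x$parameters)
  invisible(x)
}

#' Tidy a least-squares CEST fit
#' @param x A `cest_lsq_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std_error`.
#' @export
tidy.cest_lsq_fit <- function(x, ...) x$parameters

#' @rdname tidy.cest_lsq_fit
#' @return For `glance()`: a one-row tibble with fit summaries.
#' @export
glance.cest_lsq_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, sigma = x$sigma, n_obs = x$n_obs,
                 n_iter = x$n_iter, converged = x$converged)
}

## ---- calibration evaluation ------------------------------------------------

#' Evaluate the calibration of the stacked analysis
#'
#' Simulates `n_profiles` random scenarios, runs the end-to-end analysis,
#' and compares predicted shifts with the known truth: a 2-D histogram of
#' the shift error versus confidence (bins of 0.05 in `c_pred` and
#' 0.005 ppm in the error), per-confidence-bin 68.3/95.4/99.7% error
#' envelopes, and the fraction of predictions with `c_pred >= 0.4` whose
#' error lies within the predicted uncertainty `sigma_pred`.
#'
#' @param n_profiles Number of simulated profiles.
#' @param tr_model,cs_model Trained networks.
#' @param seed Seed for the scenario draws.
#' @param states 2 (default) or 3: restrict to two- or three-site
#'   scenarios; `NULL` for the native mixture.
#' @param noise Input noise level(s) (fraction of the profile maximum); if
#'   several, profiles are split evenly across them and per-level summaries
#'   are included.
#' @param offset_min Offset window lower edge (ppm).
#' @return An object of class `cest_calibration` with elements
#'   `predictions`, `histogram`, `envelopes`, `coverage_c04`, `by_noise`,
#'   `k`, `n`.
#' @export
evaluate_calibration <- function(n_profiles, tr_model, cs_model, seed = NULL,
                                 states = 2, noise = 0.01,
                                 offset_min = 6.6) {
  if (!is.null(seed)) set.seed(seed)
  per <- ceiling(n_profiles / length(noise))
  span <- 3.4
  preds <- purrr::map_dfr(noise, function(nf) {
    data <- generate_tr_examples(per, noise = nf, offset_min = offset_min,
                                 states = states)
    dips <- tr_forward(tr_model, data$coef, data$time, data$n_original)
    out <- predict_shifts(cs_model, dips, offset_min = offset_min,
                          span = span)
    out$f_true <- as.numeric(t(data$f_true))
    out$present <- as.logical(t(data$indicator == 1))
    out$err_ppm <- (out$f_pred - out$f_true) * span
    out$noise <- nf
    out
  })
  build_calibration_report(preds, k = cs_model$k)
}

#' Build a calibration report from prediction records
#'
#' The binning/enveloping back-end of [evaluate_calibration()], exposed so
#' that prediction tables from any source (including synthetic
#' perfect-prediction records for harness self-tests) can be summarized the
#' same way.
#'
#' @param preds A tibble with columns `c_pred`, `sigma_ppm`, `err_ppm`,
#'   `present`, and optionally `noise`.
#' @param k Calibration constant (ppm) used for the overlay curve.
#' @return A `cest_calibration` object.
#' @export
build_calibration_report <- function(preds, k) {
  if (!("noise" %in% names(preds))) preds$noise <- NA_real_
  present <- dplyr::filter(preds, .data$present)
  hist2d <- present |>
    dplyr::mutate(
      c_bin = floor(.data$c_pred / 0.05) * 0.05 + 0.025,
      err_bin = floor(.data$err_ppm / 0.005) * 0.005 + 0.0025
    ) |>
    dplyr::count(.data$c_bin, .data$err_bin)
  envelopes <- present |>
    dplyr::mutate(c_bin = floor(.data$c_pred / 0.05) * 0.05 + 0.025) |>
    dplyr::group_by(.data$c_bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      q683 = quantile(abs(.data$err_ppm), 0.683),
      q954 = quantile(abs(.data$err_ppm), 0.954),
      q997 = quantile(abs(.data$err_ppm), 0.997),
      .groups = "drop"
    )
  conf <- dplyr::filter(present, .data$c_pred >= 0.4)
  coverage <- mean(abs(conf$err_ppm) <= conf$sigma_ppm)
  by_noise <- present |>
    dplyr::group_by(.data$noise) |>
    dplyr::summarise(
      n = dplyr::n(),
      rmse_ppm = sqrt(mean(.data$err_ppm^2)),
      coverage_c04 = mean(abs(.data$err_ppm[.data$c_pred >= 0.4]) <=
                            .data$sigma_ppm[.data$c_pred >= 0.4]),
      .groups = "drop"
    )
  structure(
    list(predictions = preds, histogram = hist2d, envelopes = envelopes,
         coverage_c04 = coverage, by_noise = by_noise, k = k,
         n = nrow(preds) / 3L),
    class = "cest_calibration"
  )
}

#' @export
print.cest_calibration <- function(x, ...) {
  cat(sprintf(
    "<cest_calibration> %d profiles, k = %.4g ppm\n  coverage within sigma_pred (c_pred >= 0.4): %.1f%%\n",
    x$n, x$k, 100 * x$coverage_c04))
  print(x$by_noise)
  invisible(x)
}

## ---- consistency analysis --------------------------------------------------

#' Consistency of shift predictions between paired datasets
#'
#' Analyzes two paired sets of profiles of the same sites (for example the
#' full sampling versus every second point, or two B1 field strengths) and
#' compares the predicted shifts site by site and slot by slot. The
#' consistency table is restricted to predictions with
#' `min(c_pred) > 0.4` across the pair; the RMSD over that table is
#' reported.
#'
#' @param profiles_a,profiles_b Named lists of anti-phase profiles; names
#'   pair the sites (unpaired sites are skipped with a warning).
#' @param tr_model,cs_model Trained networks.
#' @return A tibble of class `cest_consistency` with per-site shift pairs
#'   and attributes `rmsd_ppm` (over the confident pairs) and `n_confident`.
#' @export
consistency_analysis <- function(profiles_a, profiles_b, tr_model,
                                 cs_model) {
  ids_a <- names(profiles_a)
  ids_b <- names(profiles_b)
  if (is.null(ids_a)) ids_a <- as.character(seq_along(profiles_a))
  if (is.null(ids_b)) ids_b <- as.character(seq_along(profiles_b))
  common <- intersect(ids_a, ids_b)
  if (length(common) < length(ids_a) || length(common) < length(ids_b)) {
    warning("unpaired sites skipped: ",
            paste(setdiff(union(ids_a, ids_b), common), collapse = ", "))
  }
  res_a <- analyze_profiles(profiles_a[common], tr_model, cs_model)
  res_b <- analyze_profiles(profiles_b[common], tr_model, cs_model)
  tab <- dplyr::inner_join(
    dplyr::select(res_a, "id", "state_slot", delta_a = "delta_ppm",
                  c_a = "c_pred", sigma_a = "sigma_ppm"),
    dplyr::select(res_b, "id", "state_slot", delta_b = "delta_ppm",
                  c_b = "c_pred", sigma_b = "sigma_ppm"),
    by = c("id", "state_slot")
  ) |>
    dplyr::mutate(min_c = pmin(.data$c_a, .data$c_b),
                  confident = .data$min_c > 0.4)
  conf <- dplyr::filter(tab, .data$confident)
  rmsd <- if (nrow(conf) > 0) {
    sqrt(mean((conf$delta_a - conf$delta_b)^2))
  } else {
    NA_real_
  }
  class(tab) <- c("cest_consistency", class(tab))
  attr(tab, "rmsd_ppm") <- rmsd
  attr(tab, "n_confident") <- nrow(conf)
  tab
}
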