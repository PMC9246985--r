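# ggplot2 visualization of profiles, calibration reports and consistency
# tables.

#' Plot a CEST profile
#'
#' @param object A [cest_profile()].
#' @param ... Unused.
#' @return A ggplot: intensity versus offset, with the offset axis reversed
#'   (NMR convention).
#' @export
autoplot.cest_profile <- function(object, ...) {
  m <- profile_meta(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset,
                                       y = .data$intensity)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(
      x = "offset (ppm)", y = expression(I / I[0]),
      title = sprintf("%s CEST profile",
                      if (identical(m$phase, "ap")) "anti-phase"
                      else "in-phase"),
      subtitle = if (!is.na(m$b0)) {
        sprintf("B0 = %.1f T, B1 = %.3g Hz, T_ex = %.3g s",
                m$b0, m$b1, m$tex)
      }
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.cest_profile <- function(x, ...) print(autoplot.cest_profile(x, ...))

#' Plot a calibration report
#'
#' 2-D histogram of shift error versus confidence, with the empirical
#' 68.3% envelope and the predicted-uncertainty curve
#' `sigma_pred = k (1/c - 1)` overlaid.
#'
#' @param object A `cest_calibration` from [evaluate_calibration()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cest_calibration <- function(object, ...) {
  cgrid <- seq(0.05, 0.975, by = 0.005)
  sig <- tibble::tibble(c_pred = cgrid,
                        sigma = conf_to_sigma(cgrid, object$k))
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$c_bin, y = .data$err_bin)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$n)) +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::geom_line(data = object$envelopes,
                       ggplot2::aes(x = .data$c_bin, y = .data$q683),
                       inherit.aes = FALSE, linetype = "dashed") +
    ggplot2::geom_line(data = object$envelopes,
                       ggplot2::aes(x = .data$c_bin, y = -.data$q683),
                       inherit.aes = FALSE, linetype = "dashed") +
    ggplot2::geom_line(data = sig,
                       ggplot2::aes(x = .data$c_pred, y = .data$sigma),
                       inherit.aes = FALSE, color = "blue",
                       linetype = "dotted") +
    ggplot2::geom_line(data = sig,
                       ggplot2::aes(x = .data$c_pred, y = -.data$sigma),
                       inherit.aes = FALSE, color = "blue",
                       linetype = "dotted") +
    ggplot2::coord_cartesian(ylim = c(-0.25, 0.25)) +
    ggplot2::labs(x = expression(c[pred]),
                  y = expression(delta[pred] - delta[true] ~ "(ppm)"),
                  fill = "count") +
    ggplot2::theme_minimal()
}

#' @export
plot.cest_calibration <- function(x, ...) {
  print(autoplot.cest_calibration(x, ...))
}

#' Plot a consistency table
#'
#' @param object A `cest_consistency` from [consistency_analysis()].
#' @param ... Unused.
#' @return A ggplot of paired shift predictions (confident pairs only).
#' @export
autoplot.cest_consistency <- function(object, ...) {
  conf <- dplyr::filter(tibble::as_tibble(object), .data$confident)
  ggplot2::ggplot(conf, ggplot2::aes(x = .data$delta_a, y = .data$delta_b,
                                     color = .data$min_c)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(delta[pred] ~ "dataset A (ppm)"),
      y = expression(delta[pred] ~ "dataset B (ppm)"),
      color = expression(min(c[pred])),
      subtitle = sprintf("RMSD = %.4g ppm over %d confident pairs",
                         attr(object, "rmsd_ppm"),
                         attr(object, "n_confident"))
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
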