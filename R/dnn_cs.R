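# The chemical-shift network: maps a 128-point in-phase CEST profile to
# three normalized shift positions and three confidences, trained with a
# two-part heteroscedastic loss; includes the confidence-to-uncertainty
# mapping and its calibration.

.CS_EPS <- 1e-6

#' Configuration of the chemical-shift network
#'
#' A densely connected 1-D convolutional network over the 128-point
#' in-phase profile: an initial convolution, then `n_blocks` dense blocks
#' (each convolution sees the concatenation of all previous feature maps)
#' at full resolution, then a locator head ([nn_locator()]): per-slot
#' score maps read out as soft-argmax positions, and a sigmoidal dense
#' path for the three confidences. The output is the 3 x 2 tensor of
#' normalized shifts and confidences, all in (0, 1).
#'
#' @param init_filters Channels after the initial convolution.
#' @param growth,depth Growth rate and depth of each dense block.
#' @param n_blocks Number of dense blocks.
#' @param kernel Convolution kernel width.
#' @param dilations Dilations of the convolutions within each dense block
#'   (recycled to `depth`); widening the receptive field beyond a single
#'   dip is what lets the block compare neighbouring dips.
#' @param hidden Width of the confidence path of the locator head.
#' @return A `cs_model_config` list.
#' @export
cs_model_config <- function(init_filters = 12, growth = 8, depth = 3,
                            n_blocks = 1, kernel = 3, dilations = c(1, 2, 4),
                            hidden = 32) {
  structure(list(init_filters = init_filters, growth = growth, depth = depth,
                 n_blocks = n_blocks, kernel = kernel, dilations = dilations,
                 hidden = hidden),
            class = "cs_model_config")
}

#' Build the chemical-shift network
#'
#' @param cfg A [cs_model_config()].
#' @return An object of class `dnn_cs` (untrained; the calibration constant
#'   `k` is set by [train_dnn_cs()]).
#' @export
build_dnn_cs <- function(cfg = cs_model_config()) {
  stopifnot(inherits(cfg, "cs_model_config"))
  # full resolution throughout: pooling costs localization precision
  layers <- list(nn_conv1d(1L, cfg$init_filters, kernel = cfg$kernel,
                           act = "relu"))
  ch <- cfg$init_filters
  for (b in seq_len(cfg$n_blocks)) {
    layers <- c(layers, list(nn_dense_block(ch, cfg$growth, cfg$depth,
                                            kernel = cfg$kernel,
                                            dilations = cfg$dilations)))
    ch <- ch + cfg$depth * cfg$growth
  }
  layers <- c(layers, list(nn_locator(ch, n_slots = 3L,
                                      hidden = cfg$hidden)))
  net <- do.call(nn_network, layers)
  structure(list(net = net, cfg = cfg, k = NA_real_, trained = FALSE,
                 history = NULL),
            class = "dnn_cs")
}

#' @export
print.dnn_cs <- function(x, ...) {
  cat(sprintf(
    "<dnn_cs> %d dense blocks (growth %d, depth %d), %d parameters%s%s\n",
    x$cfg$n_blocks, x$cfg$growth, x$cfg$depth, nn_n_params(x$net),
    if (x$trained) ", trained" else ", untrained",
    if (is.finite(x$k)) sprintf(", k = %.4g ppm", x$k) else ""
  ))
  invisible(x)
}

#' Confidence / uncertainty mapping
#'
#' The predicted uncertainty is `sigma = k * (1/c - 1)`: a bijection from
#' confidence `c` in (0, 1) to `sigma` in (0, Inf), with `sigma -> Inf` as
#' `c -> 0` and `sigma = 0` at `c = 1`.
#'
#' @param c_pred Confidence value(s) in (0, 1).
#' @param sigma Uncertainty value(s) (same units as `k`).
#' @param k Calibration constant (ppm for calibrated models; 1 during
#'   training).
#' @return The mapped value(s).
#' @export
conf_to_sigma <- function(c_pred, k = 1) k * (1 / c_pred - 1)

#' @rdname conf_to_sigma
#' @export
sigma_to_conf <- function(sigma, k = 1) k / (sigma + k)

#' Shift-accuracy part of the training loss
#'
#' `L_freq = sum_i (f_pred_i - f_true_i)^2 / sigma_pred_i^2`, summed over
#' the three state slots. For matrix inputs (one row per example) the mean
#' of the row sums is returned.
#'
#' @param f_pred,f_true Predicted and true normalized shifts (length-3
#'   vectors or n x 3 matrices).
#' @param sigma_pred Predicted uncertainties (same shape, `> 0`).
#' @return A scalar.
#' @export
loss_freq <- function(f_pred, f_true, sigma_pred) {
  stopifnot(all(sigma_pred > 0))
  term <- (f_pred - f_true)^2 / sigma_pred^2
  if (is.matrix(term)) mean(rowSums(term)) else sum(term)
}

#' Uncertainty-penalty part of the training loss
#'
#' `L_uncer = 1e-4 * sum_i 1_i * sqrt(sigma_pred_i)` where the indicator
#' `1` is `{1,1,1}` for three-state input and `{1,1,0}` for two-state input,
#' so the uncertainty of an absent state is unconstrained.
#'
#' @param sigma_pred Predicted uncertainties (length-3 vector or n x 3
#'   matrix, `>= 0`).
#' @param indicator State indicator (same shape).
#' @param lambda Penalty weight.
#' @return A scalar (mean of row sums for matrix input).
#' @export
loss_uncer <- function(sigma_pred, indicator, lambda = 1e-4) {
  stopifnot(all(sigma_pred >= 0))
  term <- lambda * indicator * sqrt(sigma_pred)
  if (is.matrix(term)) mean(rowSums(term)) else sum(term)
}

#' Calibration constant of the uncertainty mapping
#'
#' After training (with `k = 1`), `k` is set to
#' `(max(offsets) - min(offsets)) * sqrt(L_freq)` so that the rescaled
#' `L_freq` has expectation 1 and `sigma_pred = k (1/c_pred - 1)` reports
#' the expected shift uncertainty in ppm.
#'
#' @param offset_span Offset range of the profiles (ppm).
#' @param l_freq_final Final mean per-profile `L_freq` of the trained
#'   network.
#' @return `k` in ppm.
#' @examples
#' calibrate_k(3.4, 7.3e-5) # 0.029 ppm
#' @export
calibrate_k <- function(offset_span, l_freq_final) {
  if (offset_span <= 0 || l_freq_final <= 0) {
    stop("offset_span and l_freq_final must be positive", call. = FALSE)
  }
  offset_span * sqrt(l_freq_final)
}

#' Map a normalized shift into ppm
#'
#' `delta = offset_min + span * f`: the affine (invertible) map from the
#' network's (0, 1) output to the profile's offset window.
#'
#' @param f_pred Normalized shift(s) in `[0, 1]`.
#' @param offset_min Lower edge of the offset window (ppm).
#' @param span Offset span (ppm).
#' @return Shift(s) in ppm.
#' @export
map_shift <- function(f_pred, offset_min, span) {
  stopifnot(all(f_pred >= 0 & f_pred <= 1))
  offset_min + span * f_pred
}

# Post-hoc bias calibration of the uncertainty head (the bias analogue of
# temperature scaling): shift each slot's confidence bias so that its
# median sigma equals the root-mean-square of that slot's current
# residuals (over examples where the slot is present). The per-profile
# modulation of the confidences (concentration and slot-distance features)
# is untouched. Applied when the readout window changes, because the error
# scale changes abruptly there; the loss then refines the head from a sane
# starting point.
recenter_uncertainties <- function(net, x, target) {
  pred <- net_forward(net, x)$out
  nl <- length(net$layers)
  stopifnot(net$layers[[nl]]$kind == "locator")
  e2 <- (pred[, 1:3, drop = FALSE] - target$f_true)^2
  z <- stats::qlogis(pmin(pmax(pred[, 4:6, drop = FALSE], 1e-6), 1 - 1e-6))
  for (i in 1:3) {
    present <- target$indicator[, i] == 1
    if (!any(present)) next
    sigma_star <- sqrt(mean(e2[present, i]))
    z_target <- stats::qlogis(1 / (1 + sigma_star))
    shift <- z_target - median(z[present, i])
    net$layers[[nl]]$params$b2[i] <- net$layers[[nl]]$params$b2[i] + shift
  }
  net
}

# Combined training loss (k = 1): L_freq + L_uncer with gradients for the
# sigmoidal (f, c) output. target = list(f_true, indicator). With
# freeze_sigma = TRUE the uncertainties are pinned at 1 (no gradient flows
# to the confidences and L_uncer is dropped), turning L_freq into a plain
# squared error on the shifts; used as a warm-up phase.
cs_loss <- function(lambda = 1e-4, eps = .CS_EPS, freeze_sigma = FALSE) {
  function(pred, target) {
    b <- nrow(pred)
    f <- pred[, 1:3, drop = FALSE]
    e <- f - target$f_true
    if (freeze_sigma) {
      lf <- mean(rowSums(e^2))
      return(list(value = lf,
                  grad = cbind(2 * e / b, matrix(0, b, 3)),
                  parts = c(l_freq = lf, l_uncer = 0)))
    }
    c_raw <- pred[, 4:6, drop = FALSE]
    cc <- pmin(pmax(c_raw, eps), 1 - eps)
    sigma <- 1 / cc - 1
    lf <- mean(rowSums(e^2 / sigma^2))
    lu <- mean(rowSums(lambda * target$indicator * sqrt(sigma)))
    df <- 2 * e / sigma^2 / b
    dsigma <- (-2 * e^2 / sigma^3 +
                 lambda * target$indicator / (2 * sqrt(sigma))) / b
    dc <- dsigma * (-1 / cc^2)
    dc[c_raw < eps | c_raw > 1 - eps] <- 0
    list(value = lf + lu, grad = cbind(df, dc),
         parts = c(l_freq = lf, l_uncer = lu))
  }
}

#' Train the chemical-shift network
#'
#' Trains on in-phase profiles produced by the transformation network (the
#' end-to-end regime) with the two-part loss `L_freq + L_uncer` at `k = 1`,
#' then freezes the calibration constant
#' `k = span * sqrt(L_freq)` computed from the final mean `L_freq`.
#'
#' @param model A [build_dnn_cs()] model.
#' @param data Examples from [generate_tr_examples()] (for the shift-network
#'   regime use `noise = c(0.001, 0.04)`).
#' @param tr_model A trained [build_dnn_tr()] model used to transform the
#'   anti-phase inputs. If `NULL`, the clean simulated in-phase targets are
#'   used directly (bypass mode, intended for unit tests only — training
#'   proper always goes through the transformation network).
#'#' @param epochs,batch_size,lr Training schedule (Adam); `lr` may be a
#'   per-epoch vector (recycled).
#' @param warmup_epochs Number of initial epochs during which the
#'   uncertainties are frozen at sigma = 1, so the shift slots train under
#'   a plain squared error before the confidence head is released. At the
#'   reduced training scales this package targets, the `1/sigma^2`
#'   weighting otherwise slows shift localization considerably; the final
#'   loss is unchanged.
#' @param refine_epochs Number of final epochs trained with the locator
#'   head's narrow readout window; earlier epochs read positions out with a
#'   global window (plain soft argmax) so the score maps develop contrast
#'   before the window tightens. At the switch the confidence biases are
#'   recentered at the loss's per-slot stationary sigma (see the package
#'   vignette).
#' @param span Offset span of the profiles (ppm) for the calibration of
#'   `k`.
#' @param checkpoint_dir If non-`NULL`, the model is serialized there after
#'   every epoch.
#' @param verbose Print per-epoch losses.
#' @return The trained model with calibrated `$k` and `$history` (epoch,
#'   l_freq, l_uncer).
#' @export
train_dnn_cs <- function(model, data, tr_model = NULL, epochs = 20,
                         batch_size = 128, lr = 3.3e-4, warmup_epochs = 0,
                         refine_epochs = 0, span = 3.4,
                         checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "dnn_cs"))
  inputs <- if (is.null(tr_model)) {
    data$target
  } else {
    tr_forward(tr_model, data$coef, data$time, data$n_original)
  }
  x <- array(inputs, c(nrow(inputs), .UPSAMPLED_SIZE, 1L))
  target <- list(f_true = data$f_true, indicator = data$indicator)
  lr_ep <- rep_len(lr, epochs)
  nl <- length(model$net$layers)
  window_final <- model$net$layers[[nl]]$window
  # positions are read out with a global window while the score maps
  # develop contrast; the window is narrowed for the refinement epochs
  switch_ep <- epochs - refine_epochs + 1L
  if (refine_epochs > 0) model$net$layers[[nl]]$window <- .UPSAMPLED_SIZE
  history <- list()
  for (ep in seq_len(epochs)) {
    if (refine_epochs > 0 && ep == switch_ep) {
      model$net$layers[[nl]]$window <- window_final
      model$net <- recenter_uncertainties(model$net, x, target)
    }
    loss <- cs_loss(freeze_sigma = ep <= warmup_epochs)
    tr <- nn_train(model$net, x, target, loss, epochs = 1,
                   batch_size = batch_size, lr = lr_ep[ep])
    model$net <- tr$net
    tr$history$epoch <- ep
    history[[ep]] <- tr$history
    if (!is.null(checkpoint_dir)) {
      saveRDS(model, file.path(checkpoint_dir,
                               sprintf("dnn_cs_epoch%03d.rds", ep)))
    }
    if (verbose) {
      message(sprintf("dnn_cs epoch %3d  L_freq %.3e  L_uncer %.3e", ep,
                      tr$history$l_freq[1], tr$history$l_uncer[1]))
    }
  }
  model$trained <- TRUE
  model$history <- dplyr::bind_rows(history)
  # recalibrate k once from the final mean L_freq over the training inputs
  pred <- nn_predict(model$net, x)
  cc <- pmin(pmax(pred[, 4:6, drop = FALSE], .CS_EPS), 1 - .CS_EPS)
  lf <- loss_freq(pred[, 1:3, drop = FALSE], data$f_true, 1 / cc - 1)
  model$l_freq_final <- lf
  model$k <- calibrate_k(span, lf)
  model
}

#' Predict chemical shifts from in-phase profiles
#'
#' @param model A trained `dnn_cs` model.
#' @param ip_dip A dip-form in-phase profile (128 values) or a matrix of
#'   them (one per row).
#' @param offset_min,span Offset window (ppm) for the linear shift mapping.
#' @return A tibble with one row per profile and state slot: `state_slot`
#'   (1 = ground state), `f_pred`, `c_pred`, `delta_ppm`, `sigma_ppm`
#'   (`= k (1/c - 1)`), and `pass_c04` (confidence at least 0.4, the domain
#'   where `sigma_pred` is a reliable uncertainty).
#' @export
predict_shifts <- function(model, ip_dip, offset_min, span) {
  stopifnot(inherits(model, "dnn_cs"))
  if (is.null(dim(ip_dip))) ip_dip <- matrix(ip_dip, 1)
  stopifnot(ncol(ip_dip) == .UPSAMPLED_SIZE)
  x <- array(ip_dip, c(nrow(ip_dip), .UPSAMPLED_SIZE, 1L))
  pred <- nn_predict(model$net, x)
  k <- if (is.finite(model$k)) model$k else 1
  f <- pred[, 1:3, drop = FALSE]
  cc <- pmin(pmax(pred[, 4:6, drop = FALSE], .CS_EPS), 1 - .CS_EPS)
  tibble::tibble(
    profile = rep(seq_len(nrow(pred)), each = 3L),
    state_slot = rep(1:3, nrow(pred)),
    f_pred = as.numeric(t(f)),
    c_pred = as.numeric(t(cc)),
    delta_ppm = map_shift(as.numeric(t(f)), offset_min, span),
    sigma_ppm = conf_to_sigma(as.numeric(t(cc)), k),
    pass_c04 = as.numeric(t(cc)) >= 0.4
  )
}
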