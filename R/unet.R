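# The three shallow U-Net variants and the training losses. All variants
# share the encoder layout (4, 8, 10 channels, bottleneck 12) and differ in
# decoder width; every variant stays under 10,000 trainable parameters with
# counts ordered A < B < C (about 5200, 6200 and 7400). Variant A is the
# designated final-prediction architecture. Dropout rates are 0.1 at the
# first two encoder depths and 0.2 at the deepest.

UNET_ENC <- c(4L, 8L, 10L)
UNET_BOTT <- 12L
UNET_DEC <- list(A = c(8L, 6L, 6L), B = c(10L, 8L, 6L), C = c(12L, 10L, 8L))
UNET_DROPOUT <- c(0.1, 0.1, 0.2)
LOSS_EPS <- 1e-7

#' Architecture of a U-Net variant
#'
#' @param variant One of `"A"`, `"B"`, `"C"`.
#' @return List with `variant`, `encoder_channels`, `bottleneck_channels`,
#'   `decoder_channels` (deepest level first), `dropout_rates` and `n_params`.
#' @export
unet_spec <- function(variant = c("A", "B", "C")) {
  variant <- match.arg(variant)
  dec <- UNET_DEC[[variant]]
  list(variant = variant, encoder_channels = UNET_ENC,
       bottleneck_channels = UNET_BOTT, decoder_channels = dec,
       dropout_rates = UNET_DROPOUT,
       n_params = cpp_unet_nparam(UNET_ENC, UNET_BOTT, dec))
}

#' Trainable parameter count of a variant
#' @inheritParams unet_spec
#' @return Integer count.
#' @export
n_unet_params <- function(variant) unet_spec(variant)$n_params

#' Build an initialized shallow U-Net
#'
#' Maps one `H x W` SNR frame (height and width padded internally to
#' multiples of 8 for the three downsamplings) to an `H x W` probability map
#' in `[0, 1]`. Weights use He-normal initialization drawn from R's RNG, so
#' `set.seed()` makes construction reproducible.
#'
#' @inheritParams unet_spec
#' @param seed Optional integer seed for initialization.
#' @return A `sand_unet` model object.
#' @export
build_unet <- function(variant = c("A", "B", "C"), seed = NULL) {
  variant <- match.arg(variant)
  spec <- unet_spec(variant)
  if (!is.null(seed)) set.seed(seed)
  layers <- cpp_unet_layers(UNET_ENC, UNET_BOTT, spec$decoder_channels)
  params <- numeric(spec$n_params)
  pos <- 0L
  for (l in seq_len(nrow(layers))) {
    nw <- layers[l, 1]; nb <- layers[l, 2]; fan_in <- layers[l, 3]
    params[pos + seq_len(nw)] <- rnorm(nw, sd = sqrt(2 / fan_in))
    pos <- pos + nw + nb  # biases start at zero
  }
  structure(list(variant = variant, spec = spec, params = params),
            class = "sand_unet")
}

#' @export
print.sand_unet <- function(x, ...) {
  cat(sprintf("<sand_unet variant %s: %d parameters, decoder (%s)>\n",
              x$variant, x$spec$n_params,
              paste(x$spec$decoder_channels, collapse = ", ")))
  invisible(x)
}

#' Predict probability maps for frames
#'
#' @param object A `sand_unet`.
#' @param frames `H x W` matrix, `H x W x B` array, or `snr_video`.
#' @param batch_size Frames per forward pass.
#' @param ... Unused.
#' @return Probability maps with the same spatial shape as the input, values
#'   in `[0, 1]`.
#' @export
predict.sand_unet <- function(object, frames, batch_size = 32L, ...) {
  single <- is.matrix(frames)
  x <- as_frames(frames)
  pad <- pad_to_multiple8(x)
  d <- dim(pad$x)
  out <- array(0, d)
  for (start in seq(1L, d[3], by = batch_size)) {
    span <- start:min(d[3], start + batch_size - 1L)
    out[, , span] <- cpp_unet_forward(
      object$params, UNET_ENC, UNET_BOTT, object$spec$decoder_channels,
      pad$x[, , span, drop = FALSE], FALSE, c(0, 0, 0))
  }
  out <- crop_hw(out, pad$h, pad$w)
  if (single) out[, , 1] else out
}

# Internal: combined-loss or BCE gradient step on a padded batch.
unet_grad_step <- function(model, x, y, loss = c("combined", "bce"),
                           cfg_loss = loss_config(), training = TRUE) {
  loss <- match.arg(loss)
  cpp_unet_grad(model$params, UNET_ENC, UNET_BOTT,
                model$spec$decoder_channels, x, y,
                if (loss == "bce") 1L else 0L,
                cfg_loss$focal_gamma, cfg_loss$focal_alpha,
                cfg_loss$dice_weight, cfg_loss$dice_smooth,
                training, if (training) UNET_DROPOUT else c(0, 0, 0))
}

#' Loss configuration
#'
#' The training loss is `focal + dice_weight * dice`; the fixed
#' focal-to-dice weighting is 100:1 (`dice_weight = 0.01`), and only this
#' ratio matters to the optimizer up to the learning-rate scale.
#'
#' @param focal_gamma Focusing exponent (>= 0).
#' @param focal_alpha Scalar weight applied to the focal term, in (0, 1].
#' @param dice_weight Weight of the dice term relative to focal (ratio 100:1).
#' @param dice_smooth Stabilizer added to the dice numerator and denominator.
#' @return A `loss_config` list.
#' @export
loss_config <- function(focal_gamma = 2, focal_alpha = 0.25,
                        dice_weight = 0.01, dice_smooth = 1) {
  stopifnot(focal_gamma >= 0, focal_alpha > 0, focal_alpha <= 1,
            dice_weight >= 0, dice_smooth >= 0)
  structure(list(focal_gamma = focal_gamma, focal_alpha = focal_alpha,
                 dice_weight = dice_weight, dice_smooth = dice_smooth),
            class = "loss_config")
}

check_same_shape <- function(pred, target) {
  if (!identical(dim(pred) %||% length(pred), dim(target) %||% length(target)))
    sandseg_error("prediction and target shapes differ", "sandseg_shape_error")
}

#' Dice loss
#'
#' `1 - (2 * sum(pred * target) + s) / (sum(pred) + sum(target) + s)`.
#'
#' @param pred Probability map in `[0, 1]`.
#' @param target Binary mask of the same shape.
#' @param smooth Stabilizer `s` (avoids 0/0 on empty frames).
#' @return Nonnegative scalar.
#' @export
dice_loss <- function(pred, target, smooth = 1) {
  check_same_shape(pred, target)
  1 - (2 * sum(pred * target) + smooth) / (sum(pred) + sum(target) + smooth)
}

#' Focal loss
#'
#' Mean over pixels of `-alpha * (1 - p_t)^gamma * log(p_t)` where `p_t` is
#' the predicted probability of the true class; predictions are clipped to
#' `(1e-7, 1 - 1e-7)`. With `gamma = 0, alpha = 1` this is binary
#' cross-entropy.
#'
#' @inheritParams dice_loss
#' @param gamma Focusing exponent.
#' @param alpha Scalar weight.
#' @return Nonnegative scalar.
#' @export
focal_loss <- function(pred, target, gamma = 2, alpha = 0.25) {
  check_same_shape(pred, target)
  pt <- ifelse(target > 0.5, pred, 1 - pred)
  pt <- pmin(pmax(pt, LOSS_EPS), 1 - LOSS_EPS)
  mean(-alpha * (1 - pt)^gamma * log(pt))
}

#' Combined supervised loss: focal + 0.01 * dice
#'
#' @inheritParams dice_loss
#' @param cfg A [loss_config()].
#' @return Scalar loss.
#' @export
combined_loss <- function(pred, target, cfg = loss_config()) {
  focal_loss(pred, target, cfg$focal_gamma, cfg$focal_alpha) +
    cfg$dice_weight * dice_loss(pred, target, cfg$dice_smooth)
}

#' Binary cross-entropy against soft targets
#'
#' @param pred Probability map in `[0, 1]`.
#' @param soft_target Real-valued target map in `[0, 1]` (need not be binary).
#' @return Mean pixel-wise cross-entropy.
#' @export
bce_loss <- function(pred, soft_target) {
  check_same_shape(pred, soft_target)
  p <- pmin(pmax(pred, LOSS_EPS), 1 - LOSS_EPS)
  mean(-(soft_target * log(p) + (1 - soft_target) * log(1 - p)))
}
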