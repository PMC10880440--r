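# SAND's staged training schedule: supervised training of the three-variant
# ensemble, pseudolabel generation by averaging the ensemble's probability
# maps on unlabeled frames, binary-cross-entropy training of variant A on the
# soft pseudolabels, and a final supervised fine-tune on the labeled frames.

#' Training configuration
#'
#' Defaults follow the published schedule: 200 supervised epochs, 25
#' pseudolabel epochs, 200 fine-tuning epochs, Adam at learning rate 0.001,
#' 1,800 unlabeled frames for pseudolabels, and flip/rotation augmentation.
#'
#' @param epochs_supervised,epochs_pseudo,epochs_finetune Epoch counts (>= 1).
#' @param learning_rate Adam learning rate (> 0).
#' @param batch_size Frames per optimizer step.
#' @param n_unlabeled Unlabeled frames used for pseudolabels; when the video
#'   has fewer available frames, all remaining frames are used with a warning.
#' @param augment Apply random flips/rotations during training.
#' @param loss A [loss_config()].
#' @param seed Optional seed fixing the whole schedule's randomness.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs_supervised = 200L, epochs_pseudo = 25L,
                         epochs_finetune = 200L, learning_rate = 0.001,
                         batch_size = 4L, n_unlabeled = 1800L,
                         augment = TRUE, loss = loss_config(), seed = NULL) {
  if (epochs_supervised < 1 || epochs_pseudo < 1 || epochs_finetune < 1)
    sandseg_error("all epoch counts must be >= 1", "sandseg_config_error")
  if (learning_rate <= 0)
    sandseg_error("learning_rate must be positive", "sandseg_config_error")
  if (n_unlabeled < 1)
    sandseg_error("n_unlabeled must be >= 1", "sandseg_config_error")
  structure(list(epochs_supervised = as.integer(epochs_supervised),
                 epochs_pseudo = as.integer(epochs_pseudo),
                 epochs_finetune = as.integer(epochs_finetune),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 n_unlabeled = as.integer(n_unlabeled),
                 augment = isTRUE(augment), loss = loss, seed = seed),
            class = "train_config")
}

#' Reduced desk-scale training profile
#'
#' The published schedule shrunk to 50/10/50 epochs and 200 pseudolabel
#' frames, sized for single-CPU experimentation and the test suite.
#'
#' @param ... Overrides passed to [train_config()].
#' @return A `train_config`.
#' @export
desk_train_config <- function(...) {
  args <- list(epochs_supervised = 50L, epochs_pseudo = 10L,
               epochs_finetune = 50L, n_unlabeled = 200L)
  override <- list(...)
  args[names(override)] <- override
  do.call(train_config, args)
}

#' Select labeled training frames uniformly at random
#'
#' @param snr_video An `snr_video`/array, or an integer frame count.
#' @param n_frames Number of distinct frames to draw.
#' @param seed Optional seed.
#' @return Sorted integer frame indices (1-based).
#' @export
select_training_frames <- function(snr_video, n_frames, seed = NULL) {
  T_ <- if (is.numeric(snr_video) && length(snr_video) == 1L) as.integer(snr_video)
        else n_frames_of(snr_video)
  if (n_frames < 1 || n_frames > T_)
    sandseg_error(sprintf("n_frames must be in [1, %d]", T_), "sandseg_config_error")
  if (!is.null(seed)) set.seed(seed)
  sort(sample.int(T_, n_frames))
}

#' Bundle labeled frames and their masks
#'
#' @param frame_indices Unique 1-based frame indices.
#' @param snr_frames `H x W x n` array of the SNR frames at those indices.
#' @param temporal_masks `H x W x n` binary array: the per-frame union of
#'   active-neuron masks (the training target).
#' @param neuron_masks List of binary `H x W` masks, one per labeled neuron.
#' @param frame_neuron_masks Optional list (per frame) of lists of the
#'   individual neuron masks active on that frame; needed for the FLHO grid
#'   search.
#' @return A `labeled_set`.
#' @export
labeled_set <- function(frame_indices, snr_frames, temporal_masks,
                        neuron_masks = list(), frame_neuron_masks = NULL) {
  frame_indices <- as.integer(frame_indices)
  if (anyDuplicated(frame_indices))
    sandseg_error("duplicate frame indices", "sandseg_config_error")
  if (any(frame_indices < 1))
    sandseg_error("frame indices must be >= 1", "sandseg_config_error")
  snr_frames <- as_frames(snr_frames)
  temporal_masks <- as_frames(temporal_masks) != 0
  if (!identical(dim(snr_frames), dim(temporal_masks)) ||
      dim(snr_frames)[3] != length(frame_indices))
    sandseg_error("frames/masks shapes do not match the indices",
                  "sandseg_shape_error")
  if (length(neuron_masks) == 0L)
    warning("labeled set contains no neuron masks")
  structure(list(frame_indices = frame_indices, snr_frames = snr_frames,
                 temporal_masks = temporal_masks, neuron_masks = neuron_masks,
                 frame_neuron_masks = frame_neuron_masks,
                 labeled_neuron_count = length(neuron_masks)),
            class = "labeled_set")
}

#' Label the active neurons on selected frames of a synthetic scene
#'
#' Emulates a human annotator on a [generate_scene()] result: each selected
#' frame receives the union mask of the neurons active on it (SNR trace above
#' `activity_thresh`), and every neuron active on at least one selected frame
#' contributes its footprint as a labeled neuron mask.
#'
#' @param scene Ground-truth scene.
#' @param snr_video The scene's SNR video.
#' @param frame_indices Frames to label.
#' @param activity_thresh Activity threshold, SNR units.
#' @return A [labeled_set()].
#' @export
make_labeled_set <- function(scene, snr_video, frame_indices,
                             activity_thresh = 3) {
  frames <- as_frames(snr_video)
  tm <- derive_temporal_masks(scene, snr_video, activity_thresh)
  labeled_neurons <- which(vapply(
    tm$active_frames, function(a) any(frame_indices %in% a), logical(1)))
  per_frame <- lapply(frame_indices, function(f) {
    act <- labeled_neurons[vapply(tm$active_frames[labeled_neurons],
                                  function(a) f %in% a, logical(1))]
    lapply(act, function(i) scene$footprints[[i]])
  })
  ls <- labeled_set(
    frame_indices,
    frames[, , frame_indices, drop = FALSE],
    tm$masks[, , frame_indices, drop = FALSE],
    neuron_masks = lapply(labeled_neurons, function(i) scene$footprints[[i]]),
    frame_neuron_masks = per_frame)
  ls$neuron_ids <- labeled_neurons
  ls
}

#' Random flip/rotation augmentation of a frame/target pair
#'
#' Draws one element of the dihedral group (identity, flips, 90/180/270
#' rotations and their compositions) and applies the same transform to both
#' images. Non-square images are restricted to the transforms that preserve
#' their shape (identity, flips, 180 degrees).
#'
#' @param frame,target Matrices of identical shape.
#' @param choice Optional transform id in `0:7` (`choice %% 4` quarter-turns,
#'   preceded by a horizontal flip when `choice >= 4`); random when `NULL`.
#' @return List with transformed `frame`, `target` and the `choice` used.
#' @export
augment_pair <- function(frame, target, choice = NULL) {
  check_same_shape(frame, target)
  pool <- if (is_square(frame)) 0:7 else c(0L, 2L, 4L, 6L)
  if (is.null(choice)) choice <- sample(pool, 1L)
  if (!choice %in% pool)
    sandseg_error("rotation by 90 degrees requires square frames",
                  "sandseg_shape_error")
  list(frame = apply_dihedral(frame, choice),
       target = apply_dihedral(target, choice), choice = choice)
}

adam_init <- function(n, lr) {
  list(m = numeric(n), v = numeric(n), t = 0L, lr = lr,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(state, params, grad) {
  state$t <- state$t + 1L
  state$m <- state$beta1 * state$m + (1 - state$beta1) * grad
  state$v <- state$beta2 * state$v + (1 - state$beta2) * grad^2
  mhat <- state$m / (1 - state$beta1^state$t)
  vhat <- state$v / (1 - state$beta2^state$t)
  list(state = state,
       params = params - state$lr * mhat / (sqrt(vhat) + state$eps))
}

# Shared epoch loop over (frames, targets) arrays with a given loss.
train_loop <- function(model, x, y, cfg, epochs, loss) {
  pad <- pad_to_multiple8(x)
  ypad <- pad_to_multiple8(y)
  n <- dim(pad$x)[3]
  opt <- adam_init(length(model$params), cfg$learning_rate)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = cfg$batch_size)) {
      take <- ord[start:min(n, start + cfg$batch_size - 1L)]
      xb <- pad$x[, , take, drop = FALSE]
      yb <- ypad$x[, , take, drop = FALSE]
      if (cfg$augment) {
        for (k in seq_along(take)) {
          a <- augment_pair(xb[, , k], yb[, , k])
          xb[, , k] <- a$frame
          yb[, , k] <- a$target
        }
      }
      step <- unet_grad_step(model, xb, yb * 1.0, loss, cfg$loss)
      upd <- adam_step(opt, model$params, step$grad)
      opt <- upd$state
      model$params <- upd$params
      losses <- c(losses, step$loss)
    }
    history[ep] <- mean(losses)
  }
  attr(model, "loss_history") <- history
  model
}

#' Supervised training on labeled frames
#'
#' Trains with the combined focal + dice loss (100:1) and flip/rotation
#' augmentation using Adam.
#'
#' @param model A `sand_unet`.
#' @param labeled A [labeled_set()].
#' @param cfg A [train_config()]; `epochs_supervised` epochs are run.
#' @return The trained model, with the per-epoch mean loss in
#'   `attr(, "loss_history")`.
#' @export
train_supervised <- function(model, labeled, cfg = train_config()) {
  if (length(labeled$frame_indices) == 0L)
    sandseg_error("labeled set is empty", "sandseg_config_error")
  train_loop(model, labeled$snr_frames, labeled$temporal_masks * 1.0,
             cfg, cfg$epochs_supervised, "combined")
}

#' Generate soft pseudolabels from a three-model ensemble
#'
#' Samples `n_unlabeled` frames uniformly without replacement from the frames
#' not in `labeled_indices` and averages the three models' probability maps
#' per pixel.
#'
#' @param ensemble List of exactly three trained models.
#' @param snr_video `snr_video` or `H x W x T` array.
#' @param labeled_indices Frames excluded from sampling.
#' @param n_unlabeled Number of frames to pseudolabel; truncated (with a
#'   warning) when fewer unlabeled frames exist.
#' @param seed Optional seed for the frame draw.
#' @return A `pseudolabel_set`: list with `frame_indices` and `maps`
#'   (`H x W x n`, values in `[0, 1]`).
#' @export
generate_pseudolabels <- function(ensemble, snr_video, labeled_indices,
                                  n_unlabeled = 1800L, seed = NULL) {
  if (length(ensemble) != 3L)
    sandseg_error("ensemble must contain exactly 3 models", "sandseg_config_error")
  frames <- as_frames(snr_video)
  pool <- setdiff(seq_len(dim(frames)[3]), labeled_indices)
  if (length(pool) == 0L)
    sandseg_error("no unlabeled frames available", "sandseg_config_error")
  if (n_unlabeled > length(pool)) {
    warning("only ", length(pool), " unlabeled frames available; using all")
    n_unlabeled <- length(pool)
  }
  if (!is.null(seed)) set.seed(seed)
  take <- sort(sample(pool, n_unlabeled))
  xb <- frames[, , take, drop = FALSE]
  maps <- predict(ensemble[[1]], xb)
  for (m in ensemble[-1]) maps <- maps + predict(m, xb)
  maps <- maps / 3
  structure(list(frame_indices = take, maps = maps),
            class = "pseudolabel_set")
}

#' Continue training on soft pseudolabels with binary cross-entropy
#'
#' @param model The variant-A `sand_unet` to continue training.
#' @param pseudo A `pseudolabel_set`.
#' @param cfg A [train_config()]; `epochs_pseudo` epochs are run.
#' @return The trained model with `attr(, "loss_history")`.
#' @export
train_on_pseudolabels <- function(model, pseudo, cfg = train_config()) {
  if (length(pseudo$frame_indices) == 0L)
    sandseg_error("pseudolabel set is empty", "sandseg_config_error")
  train_loop(model, get_pseudo_frames(pseudo), pseudo$maps, cfg,
             cfg$epochs_pseudo, "bce")
}

# The pseudolabel inputs are the SNR frames themselves; stored alongside the
# maps when created through run_sand_training, otherwise supplied here.
get_pseudo_frames <- function(pseudo) {
  if (is.null(pseudo$snr_frames))
    sandseg_error("pseudolabel set lacks snr_frames; use run_sand_training or attach them",
                  "sandseg_config_error")
  pseudo$snr_frames
}

#' Fine-tune on the labeled frames
#'
#' Identical to [train_supervised()] but starting from the
#' pseudolabel-trained weights and running `epochs_finetune` epochs.
#'
#' @inheritParams train_supervised
#' @return The fine-tuned model with `attr(, "loss_history")`.
#' @export
finetune <- function(model, labeled, cfg = train_config()) {
  if (length(labeled$frame_indices) == 0L)
    sandseg_error("labeled set is empty", "sandseg_config_error")
  train_loop(model, labeled$snr_frames, labeled$temporal_masks * 1.0,
             cfg, cfg$epochs_finetune, "combined")
}

#' Run the full SAND training schedule
#'
#' Trains the three U-Net variants on the labeled frames, averages their
#' probability maps on unlabeled frames into soft pseudolabels, continues
#' training variant A on the pseudolabels with binary cross-entropy, and
#' fine-tunes variant A on the labeled frames.
#'
#' @param snr_video `snr_video` or `H x W x T` array.
#' @param labeled A [labeled_set()].
#' @param cfg A [train_config()].
#' @return A `sand_fit`: list with the final `model`, the supervised
#'   `ensemble`, the `pseudolabels`, and per-stage loss `histories`.
#' @export
run_sand_training <- function(snr_video, labeled, cfg = train_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  frames <- as_frames(snr_video)
  ensemble <- lapply(c("A", "B", "C"), function(v) build_unet(v))
  histories <- list()
  for (k in 1:3) {
    ensemble[[k]] <- train_supervised(ensemble[[k]], labeled, cfg)
    histories[[paste0("supervised_", ensemble[[k]]$variant)]] <-
      attr(ensemble[[k]], "loss_history")
  }
  pseudo <- generate_pseudolabels(ensemble, frames, labeled$frame_indices,
                                  cfg$n_unlabeled)
  pseudo$snr_frames <- frames[, , pseudo$frame_indices, drop = FALSE]
  model <- train_on_pseudolabels(ensemble[[1]], pseudo, cfg)
  histories$pseudo <- attr(model, "loss_history")
  model <- finetune(model, labeled, cfg)
  histories$finetune <- attr(model, "loss_history")
  structure(list(model = model, ensemble = ensemble,
                 pseudolabels = pseudo[c("frame_indices")],
                 histories = histories, config = cfg),
            class = "sand_fit")
}
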