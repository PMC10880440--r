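# Shared fixtures: tiny scenes, mock models, and mask builders. Everything
# is generated in code under fixed seeds.

tiny_scene_config <- function(seed = 7, ...) {
  args <- list(field_height = 32, field_width = 32, n_frames = 120,
               n_neurons = 4, spike_rate = 0.03, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(scene_config, args)
}

# Scene + SNR video + labeled set, small enough for fast training tests.
tiny_setup <- function(seed = 7, n_labeled = 6) {
  s <- generate_scene(tiny_scene_config(seed))
  k <- suppressWarnings(build_kernel_from_labels(s$video, s$scene$footprints))
  snr <- snr_normalize(temporal_filter(s$video, k))
  set.seed(seed + 500)
  idx <- select_training_frames(snr, n_labeled)
  lab <- make_labeled_set(s$scene, snr, idx)
  list(scene = s$scene, video = s$video, snr = snr, labeled = lab,
       kernel = k)
}

# Mask with a filled disc at (r0, c0) of radius rad.
disc_mask <- function(h, w, r0, c0, rad) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rr - r0)^2 + (cc - c0)^2 <= rad^2
}

mask_from_pixels <- function(h, w, rc) {
  m <- matrix(FALSE, h, w)
  m[rc] <- TRUE
  m
}

# A mock model whose predictions are a constant map; predict() dispatches on
# class, mirroring how the real ensemble is consumed.
constant_model <- function(value) {
  structure(list(value = value), class = "constant_model")
}

predict.constant_model <- function(object, frames, ...) {
  x <- if (is.matrix(frames)) array(frames, c(dim(frames), 1)) else frames
  if (inherits(x, "snr_video")) x <- x$frames
  array(object$value, dim(x))
}

registerS3method("predict", "constant_model", predict.constant_model,
                 envir = asNamespace("stats"))

# A field with three disjoint disc neurons whose in-mask probability is
# planted per neuron, plus an SNR video defining known active frames.
flho_fixture <- function(p_star = c(0.55, 0.65, 0.75),
                         active = list(1:6, 3:8, 5:10), T_ = 20) {
  h <- 24; w <- 24
  masks <- list(disc_mask(h, w, 6, 6, 2.5), disc_mask(h, w, 6, 18, 2.5),
                disc_mask(h, w, 18, 12, 2.5))
  snr <- array(0, c(h, w, T_))
  prob <- array(0, c(h, w, T_))
  for (i in seq_along(masks)) {
    for (t in active[[i]]) {
      snr[, , t][masks[[i]]] <- 10
      prob[, , t][masks[[i]]] <- p_star[i]
    }
  }
  labeled_idx <- 1:10
  per_frame <- lapply(labeled_idx, function(f) {
    act <- which(vapply(active, function(a) f %in% a, logical(1)))
    masks[act]
  })
  tm <- array(FALSE, c(h, w, length(labeled_idx)))
  for (k in seq_along(labeled_idx))
    for (m in per_frame[[k]]) tm[, , k] <- tm[, , k] | m
  lab <- labeled_set(labeled_idx, snr[, , labeled_idx], tm,
                     neuron_masks = masks, frame_neuron_masks = per_frame)
  list(masks = masks, snr = snr, prob = prob, lab = lab, active = active,
       p_star = p_star)
}
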