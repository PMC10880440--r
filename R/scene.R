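# Synthetic two-photon-like scenes with known ground truth. Somas are
# rasterized ellipses, activity is a Bernoulli spike train convolved with a
# double-exponential calcium transient, and the rendered video adds a smooth
# neuropil term and Gaussian noise.

#' Configuration of a synthetic calcium-imaging scene
#'
#' Bundles the geometry, kinetics and noise of a simulated two-photon video.
#' Amplitudes are expressed in raw intensity units; the effective peak SNR of
#' a neuron is roughly `transient_amplitude / noise_sigma` before matched
#' filtering (filtering then raises it by the filter gain).
#'
#' @param field_height,field_width Field of view in pixels.
#' @param n_frames Number of frames.
#' @param n_neurons Number of somas to place.
#' @param soma_radius_range Range of ellipse semi-axes, pixels.
#' @param max_pairwise_overlap Maximum allowed overlap between two footprints,
#'   as a fraction of the smaller footprint's area; must be `< 1`.
#' @param spike_rate Bernoulli probability of a spike per neuron per frame.
#' @param transient_rise,transient_decay Rise and decay time constants of the
#'   calcium transient, frames; `transient_decay > transient_rise > 0`.
#' @param transient_amplitude_range Range of per-event peak amplitudes,
#'   intensity units.
#' @param baseline Constant baseline intensity.
#' @param noise_sigma Standard deviation of the additive Gaussian noise.
#' @param neuropil_amplitude Amplitude of the smooth low-spatial-frequency
#'   neuropil term (0 disables it).
#' @param seed Integer seed; scenes are bit-reproducible given the seed.
#' @return A `scene_config` object (a validated list).
#' @export
scene_config <- function(field_height = 64, field_width = 64, n_frames = 1000,
                         n_neurons = 20, soma_radius_range = c(3, 5),
                         max_pairwise_overlap = 0.05, spike_rate = 0.008,
                         transient_rise = 2, transient_decay = 8,
                         transient_amplitude_range = c(5, 7), baseline = 20,
                         noise_sigma = 1, neuropil_amplitude = 1, seed = 1) {
  cfg <- list(
    field_height = as.integer(field_height), field_width = as.integer(field_width),
    n_frames = as.integer(n_frames), n_neurons = as.integer(n_neurons),
    soma_radius_range = as.numeric(soma_radius_range),
    max_pairwise_overlap = max_pairwise_overlap, spike_rate = spike_rate,
    transient_rise = transient_rise, transient_decay = transient_decay,
    transient_amplitude_range = as.numeric(transient_amplitude_range),
    baseline = baseline, noise_sigma = noise_sigma,
    neuropil_amplitude = neuropil_amplitude, seed = as.integer(seed))
  with(cfg, {
    if (field_height < 1 || field_width < 1 || n_frames < 1 || n_neurons < 0)
      sandseg_error("all sizes must be positive", "sandseg_config_error")
    if (max_pairwise_overlap < 0 || max_pairwise_overlap >= 1)
      sandseg_error("max_pairwise_overlap must lie in [0, 1)", "sandseg_config_error")
    if (!(transient_decay > transient_rise && transient_rise > 0))
      sandseg_error("need transient_decay > transient_rise > 0", "sandseg_config_error")
    if (spike_rate < 0 || spike_rate > 1)
      sandseg_error("spike_rate must be a per-frame probability", "sandseg_config_error")
    if (noise_sigma < 0 || any(transient_amplitude_range < 0))
      sandseg_error("noise and amplitudes must be nonnegative", "sandseg_config_error")
  })
  structure(cfg, class = "scene_config")
}

#' Preset scene configurations for the two benchmark SNR regimes
#'
#' `easy_scene_config()` is the default scene (median post-filter peak SNR
#' around 10, the regime where modern GCaMP sensors operate);
#' `hard_scene_config()` lowers transient amplitudes to 1.4-2.0 intensity
#' units, landing the median peak SNR near 5 (older sensors / deep imaging).
#'
#' @param seed Scene seed.
#' @param ... Overrides passed to [scene_config()].
#' @return A `scene_config`.
#' @export
easy_scene_config <- function(seed = 1, ...) {
  scene_config(seed = seed, ...)
}

#' @rdname easy_scene_config
#' @export
hard_scene_config <- function(seed = 1, ...) {
  args <- list(seed = seed, transient_amplitude_range = c(1.4, 2))
  override <- list(...)
  args[names(override)] <- override
  do.call(scene_config, args)
}

#' Double-exponential calcium transient kernel
#'
#' `(1 - exp(-t/rise)) * exp(-t/decay)` evaluated at frames `0, 1, ...`,
#' scaled so the continuous-time peak equals 1. The continuous peak sits at
#' `t* = rise * log((rise + decay) / rise)`.
#'
#' @param rise,decay Time constants in frames.
#' @param length_out Number of taps; defaults to when the tail falls below
#'   1% of the peak.
#' @return Numeric vector of kernel values.
#' @export
transient_kernel <- function(rise, decay, length_out = NULL) {
  shape <- function(t) (1 - exp(-t / rise)) * exp(-t / decay)
  t_peak <- rise * log((rise + decay) / rise)
  peak <- shape(t_peak)
  if (is.null(length_out))
    length_out <- max(ceiling(t_peak + decay * log(100)), 3)
  shape(seq_len(length_out) - 1) / peak
}

#' Render a noise-free fluorescence trace from spike times
#'
#' Each spike adds a [transient_kernel()] scaled by its amplitude, starting at
#' the spike frame.
#'
#' @param spike_times Integer frame indices (1-based).
#' @param amplitudes Per-spike peak amplitudes (recycled if length 1).
#' @param n_frames Trace length.
#' @param rise,decay Transient time constants, frames.
#' @return Numeric vector of length `n_frames`.
#' @export
render_trace <- function(spike_times, amplitudes, n_frames, rise, decay) {
  trace <- numeric(n_frames)
  if (length(spike_times) == 0L) return(trace)
  amplitudes <- rep_len(amplitudes, length(spike_times))
  kern <- transient_kernel(rise, decay)
  for (i in seq_along(spike_times)) {
    s <- spike_times[i]
    span <- s:min(n_frames, s + length(kern) - 1L)
    if (s > n_frames) next
    trace[span] <- trace[span] + amplitudes[i] * kern[seq_along(span)]
  }
  trace
}

#' Generate spike trains and fluorescence traces
#'
#' Spikes are Bernoulli per frame at `spike_rate`; each spike's amplitude is
#' drawn uniformly from `transient_amplitude_range`. Neuron `i` uses a
#' sub-seed derived from `config$seed` and `i`, so traces do not depend on the
#' placement of other neurons.
#'
#' @param config A [scene_config()].
#' @param n Number of neurons (`>= 1`).
#' @return List with `spike_times` (list of integer vectors), `amplitudes`
#'   (list of numeric vectors) and `traces` (`n x n_frames` matrix).
#' @export
generate_traces <- function(config, n) {
  if (!inherits(config, "scene_config"))
    sandseg_error("config must be a scene_config", "sandseg_config_error")
  if (n < 1) sandseg_error("n must be >= 1", "sandseg_config_error")
  T_ <- config$n_frames
  spike_times <- vector("list", n)
  amplitudes <- vector("list", n)
  traces <- matrix(0, n, T_)
  for (i in seq_len(n)) {
    set.seed(sub_seed(config$seed, i))
    st <- which(runif(T_) < config$spike_rate)
    am <- runif(length(st), config$transient_amplitude_range[1],
                config$transient_amplitude_range[2])
    spike_times[[i]] <- st
    amplitudes[[i]] <- am
    traces[i, ] <- render_trace(st, am, T_, config$transient_rise,
                                config$transient_decay)
  }
  list(spike_times = spike_times, amplitudes = amplitudes, traces = traces)
}

# Dilate a logical mask by one pixel (8-neighborhood).
dilate1 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- max(1, 1 + dr):min(h, h + dr)
    rt <- max(1, 1 - dr):min(h, h - dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    ct <- max(1, 1 - dc):min(w, w - dc)
    out[rt, ct] <- out[rt, ct] | m[rs, cs]
  }
  out
}

# Rasterize one elliptical footprint over pixel centers; logical H x W.
rasterize_ellipse <- function(h, w, r0, c0, a, b, theta) {
  rr <- matrix(seq_len(h), h, w) - r0
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - c0
  u <- (cc * cos(theta) + rr * sin(theta)) / a
  v <- (-cc * sin(theta) + rr * cos(theta)) / b
  u * u + v * v <= 1
}

place_footprints <- function(config) {
  h <- config$field_height; w <- config$field_width
  rng <- config$soma_radius_range
  placed <- list()
  areas <- integer(0)
  for (i in seq_len(config$n_neurons)) {
    ok <- FALSE
    for (try in seq_len(1000L)) {
      a <- runif(1, rng[1], rng[2])
      b <- runif(1, rng[1], rng[2])
      theta <- runif(1, 0, pi)
      rmax <- max(a, b)
      if (2 * rmax + 2 > min(h, w))
        sandseg_error("field too small for the requested soma size",
                      "sandseg_capacity_error")
      r0 <- runif(1, 1 + rmax, h - rmax)
      c0 <- runif(1, 1 + rmax, w - rmax)
      fp <- rasterize_ellipse(h, w, r0, c0, a, b, theta)
      area <- sum(fp)
      if (area < 3) next
      # The overlap cap is enforced on the 1-pixel dilation, so somas stay
      # separated by background except for deliberate overlaps, as in
      # two-photon recordings where neuropil separates most somas.
      fpd <- dilate1(fp)
      fine <- TRUE
      for (j in seq_along(placed)) {
        inter <- sum(fpd & placed[[j]])
        if (inter > config$max_pairwise_overlap * min(area, areas[j])) {
          fine <- FALSE
          break
        }
      }
      if (fine) {
        placed[[i]] <- fp
        areas[i] <- area
        ok <- TRUE
        break
      }
    }
    if (!ok)
      sandseg_error(sprintf(
        "could not place %d neurons under the overlap constraint; %d fit",
        config$n_neurons, i - 1L), "sandseg_capacity_error")
  }
  placed
}

# Smooth low-spatial-frequency field: coarse Gaussian grid, bilinearly
# upsampled, zero-mean, unit max-abs.
neuropil_field <- function(h, w) {
  g <- matrix(rnorm(8 * 8), 8, 8)
  ri <- seq(1, 8, length.out = h)
  ci <- seq(1, 8, length.out = w)
  r0 <- pmin(floor(ri), 7); c0 <- pmin(floor(ci), 7)
  fr <- ri - r0; fc <- ci - c0
  f <- matrix(0, h, w)
  for (cidx in seq_len(w)) {
    c1 <- c0[cidx]
    f[, cidx] <- (1 - fr) * ((1 - fc[cidx]) * g[cbind(r0, c1)] + fc[cidx] * g[cbind(r0, c1 + 1)]) +
      fr * ((1 - fc[cidx]) * g[cbind(r0 + 1, c1)] + fc[cidx] * g[cbind(r0 + 1, c1 + 1)])
  }
  f <- f - mean(f)
  f / max(abs(f), 1e-12)
}

#' Generate a synthetic scene and its rendered video
#'
#' `video = baseline + neuropil + sum_i trace_i * footprint_i + noise`.
#' Fully reproducible given `config$seed`; per-neuron randomness is sub-seeded
#' by neuron index so it does not depend on placement retries.
#'
#' @param config A [scene_config()].
#' @return List with `scene` (ground truth: `footprints`, `spike_times`,
#'   `traces`, `temporal_activity`) and `video` (`H x W x T` array).
#'   `temporal_activity` holds, per neuron, the frames whose noise-free trace
#'   exceeds 5% of the smallest configured amplitude (a nominal definition;
#'   use [derive_temporal_masks()] for SNR-based activity).
#' @export
generate_scene <- function(config) {
  if (!inherits(config, "scene_config"))
    sandseg_error("config must be a scene_config", "sandseg_config_error")
  set.seed(config$seed)
  footprints <- place_footprints(config)
  n <- config$n_neurons
  h <- config$field_height; w <- config$field_width; T_ <- config$n_frames
  tr <- if (n > 0) generate_traces(config, n) else
    list(spike_times = list(), amplitudes = list(), traces = matrix(0, 0, T_))

  set.seed(sub_seed(config$seed, 0))
  video <- array(if (config$noise_sigma > 0)
    rnorm(h * w * T_, config$baseline, config$noise_sigma)
    else config$baseline, c(h, w, T_))
  if (config$neuropil_amplitude > 0) {
    field <- neuropil_field(h, w)
    period <- max(200, T_ / 3)
    s_t <- sin(2 * pi * seq_len(T_) / period)
    video <- video + config$neuropil_amplitude *
      array(outer(c(field), s_t), c(h, w, T_))
  }
  dim(video) <- c(h * w, T_)
  for (i in seq_len(n)) {
    idx <- which(footprints[[i]])
    video[idx, ] <- video[idx, ] + rep(tr$traces[i, ], each = length(idx))
  }
  dim(video) <- c(h, w, T_)

  nominal <- 0.05 * config$transient_amplitude_range[1]
  activity <- lapply(seq_len(n), function(i) which(tr$traces[i, ] > nominal))
  scene <- structure(list(
    footprints = footprints, spike_times = tr$spike_times,
    amplitudes = tr$amplitudes, traces = tr$traces,
    temporal_activity = activity, config = config), class = "gt_scene")
  list(scene = scene, video = video)
}

#' Per-frame temporal masks from ground truth and an SNR video
#'
#' A neuron is active on frame `t` when its SNR trace (mean SNR over its
#' footprint) exceeds `activity_thresh`; frame `t`'s mask is the union of the
#' footprints of its active neurons.
#'
#' @param scene Ground-truth scene from [generate_scene()].
#' @param snr_video An [snr_normalize()] result (or `H x W x T` array) shaped
#'   like the scene's video.
#' @param activity_thresh Activity threshold, SNR units.
#' @return List with `masks` (logical `H x W x T` array) and `active_frames`
#'   (per-neuron integer vectors).
#' @export
derive_temporal_masks <- function(scene, snr_video, activity_thresh = 3) {
  frames <- as_frames(snr_video)
  d <- dim(frames)
  cfg <- scene$config
  if (d[1] != cfg$field_height || d[2] != cfg$field_width ||
      d[3] != cfg$n_frames)
    sandseg_error("snr_video shape does not match the scene", "sandseg_shape_error")
  n <- length(scene$footprints)
  active <- vector("list", n)
  masks <- array(FALSE, d)
  dim(masks) <- c(d[1] * d[2], d[3])
  for (i in seq_len(n)) {
    tr <- mask_trace(frames, scene$footprints[[i]])
    act <- which(tr > activity_thresh)
    active[[i]] <- act
    if (length(act)) masks[which(scene$footprints[[i]]), act] <- TRUE
  }
  dim(masks) <- d
  list(masks = masks, active_frames = active)
}
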