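test_that("invalid scene configurations are rejected", {
  expect_error(scene_config(max_pairwise_overlap = 1), class = "sandseg_config_error")
  expect_error(scene_config(transient_rise = 5, transient_decay = 3),
               class = "sandseg_config_error")
  expect_error(scene_config(n_frames = 0), class = "sandseg_config_error")
  expect_error(generate_traces(scene_config(), 0), class = "sandseg_config_error")
})

test_that("traces follow the double-exponential kernel", {
  cfg <- scene_config(spike_rate = 0, seed = 1)
  tr <- generate_traces(cfg, 3)
  expect_true(all(tr$traces == 0))
  expect_equal(lengths(tr$spike_times), rep(0L, 3))

  # One planted spike reproduces the analytic kernel shape.
  rise <- 2; decay <- 8
  trace <- render_trace(10L, 1, 100L, rise, decay)
  t_peak <- rise * log((rise + decay) / rise)
  shape <- function(t) (1 - exp(-t / rise)) * exp(-t / decay)
  L <- length(transient_kernel(rise, decay))
  expected <- shape(seq_len(L) - 1) / shape(t_peak)
  expect_equal(trace[10:(9 + L)], expected, tolerance = 1e-12)
  expect_true(all(trace[(10 + L):100] == 0))
  # Sampled peak sits at the integer offset maximizing the analytic kernel,
  # and its height is the analytic value there (bounded by the true maximum).
  expect_equal(which.max(trace), 9L + which.max(expected))
  expect_equal(max(trace), max(expected))
  expect_lte(max(trace), 1)
  expect_gt(max(trace), shape(floor(t_peak)) / shape(t_peak) - 1e-9)
})

test_that("trace generation is deterministic given the seed", {
  cfg <- scene_config(seed = 42)
  a <- generate_traces(cfg, 5)
  b <- generate_traces(cfg, 5)
  expect_identical(a, b)
  c2 <- generate_traces(scene_config(seed = 43), 5)
  expect_false(identical(a$spike_times, c2$spike_times))
})

test_that("scene rendering honors its composition contract", {
  # No spikes, no noise, no neuropil: every frame equals the baseline.
  cfg <- tiny_scene_config(spike_rate = 0, noise_sigma = 0,
                           neuropil_amplitude = 0, baseline = 17)
  out <- generate_scene(cfg)
  expect_true(all(out$video == 17))
  expect_length(out$scene$footprints, 4)

  # Noise standard deviation matches noise_sigma (law of large numbers).
  cfg2 <- tiny_scene_config(seed = 8, n_frames = 150, spike_rate = 0,
                            neuropil_amplitude = 0, noise_sigma = 2)
  out2 <- generate_scene(cfg2)
  expect_gt(length(out2$video), 1e5)
  expect_equal(sd(out2$video - mean(out2$video)), 2, tolerance = 0.05)
})

test_that("scenes are bit-identical for identical seeds and differ otherwise", {
  a <- generate_scene(tiny_scene_config(seed = 5))
  b <- generate_scene(tiny_scene_config(seed = 5))
  expect_identical(a$video, b$video)
  expect_identical(a$scene$footprints, b$scene$footprints)
  d <- generate_scene(tiny_scene_config(seed = 6))
  expect_false(identical(a$video, d$video))
})

test_that("footprint placement respects the overlap constraint or errors", {
  cfg <- tiny_scene_config(seed = 9)
  fp <- generate_scene(cfg)$scene$footprints
  areas <- vapply(fp, sum, numeric(1))
  for (i in seq_along(fp)) for (j in seq_len(i - 1)) {
    expect_lte(sum(fp[[i]] & fp[[j]]),
               cfg$max_pairwise_overlap * min(areas[i], areas[j]))
  }
  expect_error(
    generate_scene(scene_config(field_height = 16, field_width = 16,
                                n_frames = 10, n_neurons = 50, seed = 1)),
    class = "sandseg_capacity_error")
})

test_that("temporal masks threshold the SNR traces of each neuron", {
  st <- tiny_setup(seed = 7)
  tm <- derive_temporal_masks(st$scene, st$snr, activity_thresh = 3)
  all_fp <- Reduce(`|`, st$scene$footprints)
  for (t in seq_len(dim(tm$masks)[3])) {
    expect_true(all(!tm$masks[, , t] | all_fp))  # mask subset of footprints
  }
  # Frame masks equal the union of active neurons' footprints.
  for (t in c(1, 50, 100)) {
    act <- which(vapply(tm$active_frames, function(a) t %in% a, logical(1)))
    expected <- if (length(act)) Reduce(`|`, st$scene$footprints[act])
                else matrix(FALSE, 32, 32)
    expect_identical(tm$masks[, , t], expected)
  }
  # Threshold below the global minimum: every neuron active on every frame.
  lo <- min(vapply(st$scene$footprints,
                   function(f) min(snr_trace(st$snr, f)), numeric(1)))
  tm_all <- derive_temporal_masks(st$scene, st$snr, activity_thresh = lo - 1)
  expect_true(all(vapply(tm_all$active_frames, length, integer(1)) == 120L))
  expect_error(derive_temporal_masks(st$scene, st$snr$frames[, , 1:10]),
               class = "sandseg_shape_error")
})

test_that("a single neuron active on two frames yields exactly those masks", {
  h <- 16; w <- 16; T_ <- 8
  fp <- disc_mask(h, w, 8, 8, 3)
  snr <- array(0, c(h, w, T_))
  for (t in 3:4) snr[, , t][fp] <- 10
  scene <- structure(list(
    footprints = list(fp), spike_times = list(c(3L)),
    traces = matrix(0, 1, T_), temporal_activity = list(3:4),
    config = scene_config(field_height = h, field_width = w, n_frames = T_,
                          n_neurons = 1)), class = "gt_scene")
  tm <- derive_temporal_masks(scene, snr, activity_thresh = 3)
  expect_identical(tm$active_frames[[1]], 3:4)
  expect_identical(tm$masks[, , 3], fp)
  expect_identical(tm$masks[, , 4], fp)
  expect_true(all(!tm$masks[, , -(3:4)]))
})

test_that("higher noise lowers measured peak SNR on average", {
  psnr_at <- function(noise, seed) {
    s <- generate_scene(tiny_scene_config(seed = seed, noise_sigma = noise))
    snr <- snr_normalize(s$video)
    median(vapply(s$scene$footprints, function(f) neuron_psnr(snr, f),
                  numeric(1)))
  }
  for (seed in c(31, 32, 33)) {
    expect_gt(psnr_at(0.5, seed), psnr_at(2, seed))
  }
})
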