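test_that("training frame selection is uniform, distinct and seeded", {
  expect_identical(select_training_frames(100L, 100L), 1:100)
  a <- select_training_frames(1000L, 10, seed = 4)
  b <- select_training_frames(1000L, 10, seed = 4)
  expect_identical(a, b)
  expect_length(unique(a), 10L)
  expect_true(all(a >= 1 & a <= 1000))
  expect_error(select_training_frames(10L, 11), class = "sandseg_config_error")
})

test_that("augmentation applies one shared dihedral transform", {
  f <- matrix(rnorm(64), 8)
  t_ <- matrix(rbinom(64, 1, 0.3), 8)
  # Identity.
  a <- augment_pair(f, t_, choice = 0L)
  expect_identical(a$frame, f)
  expect_identical(a$target, t_)
  # Involutions return the original.
  for (ch in c(2L, 4L, 6L)) {
    once <- augment_pair(f, t_, choice = ch)
    twice <- augment_pair(once$frame, once$target, choice = ch)
    expect_equal(twice$frame, f)
    expect_equal(twice$target, t_)
  }
  # Every transform permutes pixels (multiset preserved) and moves frame and
  # target coherently.
  for (ch in 0:7) {
    a <- augment_pair(f, t_, choice = ch)
    expect_equal(sort(c(a$frame)), sort(c(f)))
    expect_identical(which(a$target == 1),
                     which(apply_dihedral_ref(t_, ch) == 1))
  }
  # Non-square frames reject quarter turns.
  expect_error(augment_pair(matrix(0, 2, 4), matrix(0, 2, 4), choice = 1L),
               class = "sandseg_shape_error")
})

test_that("pseudolabels are the ensemble mean and respect bookkeeping", {
  snr <- array(runif(16 * 16 * 30), c(16, 16, 30))
  labeled_idx <- c(2L, 9L)

  # Constants 0.2 / 0.4 / 0.6 average to 0.4.
  ens <- lapply(c(0.2, 0.4, 0.6), constant_model)
  ps <- generate_pseudolabels(ens, snr, labeled_idx, 5, seed = 1)
  expect_equal(max(abs(ps$maps - 0.4)), 0, tolerance = 1e-12)
  expect_length(ps$frame_indices, 5)
  expect_length(intersect(ps$frame_indices, labeled_idx), 0)

  # Three identical real models: pseudolabels equal a single model's output.
  m <- build_unet("A", seed = 21)
  ps2 <- generate_pseudolabels(list(m, m, m), snr, labeled_idx, 4, seed = 2)
  single <- predict(m, snr[, , ps2$frame_indices])
  expect_equal(max(abs(ps2$maps - single)), 0)
  expect_true(all(ps2$maps >= 0 & ps2$maps <= 1))

  # Ensemble size is enforced; oversampling uses all frames with a warning.
  expect_error(generate_pseudolabels(ens[1:2], snr, labeled_idx, 5),
               class = "sandseg_config_error")
  expect_warning(ps3 <- generate_pseudolabels(ens, snr, labeled_idx, 1000),
                 "available")
  expect_length(ps3$frame_indices, 28)
})

test_that("supervised training reduces the loss on a small labeled set", {
  finals <- c()
  firsts <- c()
  for (seed in c(51, 52, 53)) {
    st <- tiny_setup(seed = seed)
    set.seed(seed)
    m <- train_supervised(build_unet("A"), st$labeled,
                          train_config(epochs_supervised = 15))
    h <- attr(m, "loss_history")
    expect_length(h, 15)
    firsts <- c(firsts, h[1])
    finals <- c(finals, h[15])
  }
  expect_lt(median(finals), median(firsts))
  st <- tiny_setup(seed = 51)
  expect_error(train_config(epochs_supervised = 0),
               class = "sandseg_config_error")
})

test_that("pseudolabel training on self-consistent targets stays near its floor", {
  st <- tiny_setup(seed = 55)
  set.seed(1)
  m <- train_supervised(build_unet("A"), st$labeled,
                        train_config(epochs_supervised = 10))
  pool <- setdiff(seq_len(120), st$labeled$frame_indices)[1:20]
  maps <- predict(m, st$snr$frames[, , pool])
  pseudo <- structure(list(frame_indices = pool, maps = maps,
                           snr_frames = st$snr$frames[, , pool]),
                      class = "pseudolabel_set")
  cfg <- train_config(epochs_pseudo = 5, augment = FALSE,
                      learning_rate = 1e-4)
  m2 <- train_on_pseudolabels(m, pseudo, cfg)
  h <- attr(m2, "loss_history")
  expect_length(h, 5)
  # Targets are the model's own outputs: loss starts at its floor and must
  # not move materially.
  expect_lt(max(h) - min(h), 0.02)
})

test_that("the full schedule is deterministic and keeps frame sets disjoint", {
  st <- tiny_setup(seed = 57)
  cfg <- train_config(epochs_supervised = 3, epochs_pseudo = 2,
                      epochs_finetune = 3, n_unlabeled = 15, seed = 99)
  fit1 <- run_sand_training(st$snr, st$labeled, cfg)
  fit2 <- run_sand_training(st$snr, st$labeled, cfg)
  expect_identical(fit1$model$params, fit2$model$params)
  expect_identical(fit1$pseudolabels$frame_indices,
                   fit2$pseudolabels$frame_indices)
  expect_length(intersect(fit1$pseudolabels$frame_indices,
                          st$labeled$frame_indices), 0)
  expect_named(fit1$histories,
               c("supervised_A", "supervised_B", "supervised_C",
                 "pseudo", "finetune"))
  # Fine-tuning moves the weights.
  expect_false(identical(fit1$model$params, fit1$ensemble[[1]]$params))
})
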