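test_that("binarization is strict and validated", {
  m <- matrix(0.9, 3, 3)
  expect_true(all(binarize(m, 0.5)))
  expect_false(any(binarize(matrix(0.3, 3, 3), 0.5)))
  expect_false(any(binarize(matrix(0.5, 3, 3), 0.5)))  # strict inequality
  expect_error(binarize(m, 0), class = "sandseg_config_error")
  expect_error(binarize(m, 1.2), class = "sandseg_config_error")
})

test_that("component extraction uses 8-connectivity and min_area", {
  empty <- matrix(FALSE, 5, 5)
  expect_length(extract_components(empty), 0)

  diag2 <- matrix(FALSE, 5, 5)
  diag2[1, 1] <- TRUE; diag2[2, 2] <- TRUE
  expect_length(extract_components(diag2), 1)  # diagonal touch joins

  three <- matrix(FALSE, 5, 5)
  three[2, 2:4] <- TRUE
  expect_length(extract_components(three, min_area = 4), 0)
  cp <- extract_components(three, min_area = 3)[[1]]
  expect_equal(cp$area, 3L)
  expect_equal(cp$centroid, c(2, 3))
})

test_that("iou and consume match pixel counts", {
  h <- 5; w <- 5
  row3 <- mask_from_pixels(h, w, cbind(2, 1:3))
  row2 <- mask_from_pixels(h, w, cbind(2, 3:4))
  expect_equal(iou(row3, row3), 1)
  expect_equal(iou(row3, mask_from_pixels(h, w, cbind(5, 1:2))), 0)
  expect_equal(iou(row3, row2), 1 / 4)
  expect_warning(z <- iou(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)),
                 "undefined")
  expect_equal(z, 0)

  sub <- mask_from_pixels(h, w, cbind(2, 2:3))
  expect_equal(consume(row3, sub), 1)          # m2 inside m1
  expect_equal(consume(sub, row3), 2 / 3)
  m4 <- mask_from_pixels(h, w, cbind(2, 1:4))
  expect_equal(consume(row3, m4), 3 / 4)       # not > 0.75: no merge
  expect_error(consume(row3, matrix(FALSE, 5, 5)),
               class = "sandseg_empty_mask")
})

test_that("iou/consume obey their mutual inequalities", {
  set.seed(8)
  for (i in 1:20) {
    a <- matrix(runif(36) < 0.4, 6)
    b <- matrix(runif(36) < 0.4, 6)
    if (!any(a) || !any(b)) next
    expect_equal(iou(a, b), iou(b, a))
    expect_equal(consume(a, a), 1)
    expect_lte(iou(a, b), consume(a, b) + 1e-12)
    expect_lte(iou(a, b), consume(b, a) + 1e-12)
  }
})

test_that("colocalization branches fire independently", {
  h <- 20; w <- 20
  c1 <- extract_components(disc_mask(h, w, 5, 5, 2), frame_index = 1)[[1]]
  c2 <- extract_components(disc_mask(h, w, 6, 5, 2), frame_index = 2)[[1]]
  far <- extract_components(disc_mask(h, w, 15, 15, 2), frame_index = 2)[[1]]
  expect_true(components_colocalized(c1, c1, 0.5))   # IoU = 1
  expect_false(components_colocalized(c1, far, 2))
  # Distance branch alone: disjoint single-pixel masks 1 apart.
  p1 <- structure(list(frame = 1L, pixels = 22L, area = 1L,
                       centroid = c(2, 2), h = h, w = w), class = "roi_component")
  p2 <- structure(list(frame = 2L, pixels = 23L, area = 1L,
                       centroid = c(3, 2), h = h, w = w), class = "roi_component")
  expect_true(components_colocalized(p1, p2, 2))
  expect_false(components_colocalized(p1, p2, 1))
})

test_that("merging takes the transitive closure independent of order", {
  h <- 30; w <- 30
  mk <- function(r0, c0, f) extract_components(disc_mask(h, w, r0, c0, 3),
                                               frame_index = f)[[1]]
  # Identical component on frames 1..3: one record.
  same <- lapply(1:3, function(f) mk(10, 10, f))
  rec <- merge_components(same, 2)
  expect_length(rec, 1)
  expect_equal(rec[[1]]$active_frames, 1:3)
  expect_equal(sort(rec[[1]]$mask_pixels), sort(same[[1]]$pixels))

  # Never-colocalized components stay separate.
  two <- list(mk(8, 8, 1), mk(22, 22, 2))
  expect_length(merge_components(two, 2), 2)

  # Chain A~B, B~C with A and C not directly colocalized merges all three.
  A <- mk(10, 10, 1); B <- mk(10, 13, 2); C <- mk(10, 16, 3)
  expect_true(components_colocalized(A, B, 4))
  expect_true(components_colocalized(B, C, 4))
  expect_false(components_colocalized(A, C, 4))
  chain <- merge_components(list(A, B, C), 4)
  expect_length(chain, 1)
  # Any input order gives the same records.
  perm <- merge_components(list(C, A, B), 4)
  expect_identical(canonical_records(chain), canonical_records(perm))
})

test_that("consecutive-frame filtering keeps only long runs", {
  mkrec <- function(frames) structure(
    list(id = 1L, active_frames = as.integer(frames), mask_pixels = 1:3,
         h = 5, w = 5), class = "neuron_record")
  expect_length(filter_consecutive(list(mkrec(1:3)), 3), 1)
  expect_length(filter_consecutive(list(mkrec(c(1, 3, 5))), 2), 0)
  expect_length(filter_consecutive(list(mkrec(c(1, 3, 5))), 1), 1)
  expect_error(filter_consecutive(list(), 0), class = "sandseg_config_error")
})

test_that("postprocess recovers a planted neuron and rejects empty stacks", {
  expect_length(postprocess(array(0, c(16, 16, 10)),
                            hyperparams(0.5, 3, 2, 2)), 0)
  h <- 16; w <- 16
  fp <- disc_mask(h, w, 8, 8, 3)
  stack <- array(0.05, c(h, w, 12))
  for (t in 4:9) stack[, , t][fp] <- 0.95
  rec <- postprocess(stack, hyperparams(0.5, 5, 3, 4))
  expect_length(rec, 1)
  expect_gt(iou(record_mask(rec[[1]]), fp), 0.5)
  expect_equal(rec[[1]]$active_frames, 4:9)
})

test_that("postprocess equals the brute-force pairwise-closure oracle", {
  set.seed(501)
  hp <- hyperparams(0.5, 3, 2.5, 2)
  for (i in 1:8) {
    stack <- random_blob_stack()
    fast <- postprocess(stack, hp)
    slow <- brute_force_postprocess(stack, hp)
    expect_identical(canonical_records(fast), canonical_records(slow))
  }
})

test_that("raising each hyperparameter never grows its filtered quantity", {
  set.seed(502)
  for (i in 1:5) {
    stack <- random_blob_stack()
    # p_thresh: active pixel count per frame non-increasing.
    counts <- vapply(c(0.3, 0.5, 0.7),
                     function(p) sum(binarize(stack[, , 5], p)), numeric(1))
    expect_true(all(diff(counts) <= 0))
    # min_area: component count non-increasing.
    ncomp <- vapply(c(1, 3, 6), function(a)
      length(extract_components(binarize(stack[, , 5], 0.5), a)), numeric(1))
    expect_true(all(diff(ncomp) <= 0))
    # min_consecutive: final neuron count non-increasing.
    nrec <- vapply(c(1, 3, 6), function(mc)
      length(postprocess(stack, hyperparams(0.5, 3, 2.5, mc))), numeric(1))
    expect_true(all(diff(nrec) <= 0))
  }
})
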