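# Few Label Hyperparameter Optimization: estimates the four postprocessing
# hyperparameters from the labeled frames alone.
#
# Step 1: per labeled neuron, the median probability-map value inside its
#         mask over its active labeled frames; the 25th percentile of these
#         medians is the intermediate p_thresh, their median (capped at 0.8)
#         the final p_thresh.
# Step 2: grid search over (min_area, centroid_dist) maximizing frame-level
#         F1 on the labeled frames, binarizing at the intermediate p_thresh.
# Step 3: per neuron, the longest run of consecutive frames (over ALL
#         frames' probability maps at the final p_thresh) with a component
#         colocalized with its ground-truth mask.
# Step 4: min_consecutive = second smallest nonzero run length, capped at 8.

#' Grid for the FLHO spatial search
#'
#' @param min_area_values Strictly increasing candidate areas, pixels. The
#'   default 30:10:150 suits ~1 micron/pixel somas; `soma_radius` rescales it
#'   by `(soma_radius / 6)^2` for other magnifications.
#' @param centroid_dist_values Strictly increasing candidate distances,
#'   pixels.
#' @param soma_radius Typical soma radius in pixels used to rescale the
#'   default area grid.
#' @return A `grid_spec`.
#' @export
grid_spec <- function(min_area_values = NULL,
                      centroid_dist_values = seq(2, 10),
                      soma_radius = 6) {
  if (is.null(min_area_values))
    min_area_values <- unique(pmax(1L, as.integer(
      round(seq(30, 150, by = 10) * (soma_radius / 6)^2))))
  if (length(min_area_values) == 0L || length(centroid_dist_values) == 0L ||
      is.unsorted(min_area_values, strictly = TRUE) ||
      is.unsorted(centroid_dist_values, strictly = TRUE))
    sandseg_error("grid values must be nonempty and strictly increasing",
                  "sandseg_config_error")
  structure(list(min_area_values = min_area_values,
                 centroid_dist_values = centroid_dist_values),
            class = "grid_spec")
}

#' Frames on which each labeled neuron is active
#'
#' A neuron is active when its SNR trace (mean SNR over its mask) strictly
#' exceeds `activity_thresh`.
#'
#' @param snr_video `snr_video` or `H x W x T` array.
#' @param gt_masks List of binary neuron masks.
#' @param activity_thresh Threshold, SNR units.
#' @return List of integer frame vectors, one per neuron.
#' @export
neuron_active_frames <- function(snr_video, gt_masks, activity_thresh = 3) {
  lapply(gt_masks, function(m) which(mask_trace(snr_video, m) > activity_thresh))
}

#' Per-neuron median probability inside the mask on active labeled frames
#'
#' For each neuron the map value distribution is summarized per frame by the
#' median over its mask pixels, and across its active labeled frames by the
#' median of those frame medians. Neurons with no active labeled frame are
#' excluded (with a warning).
#'
#' @param prob_maps `H x W x n` probability maps of the labeled frames.
#' @param gt_masks List of binary neuron masks.
#' @param active_frames Per-neuron active frame vectors (video frame indices,
#'   from [neuron_active_frames()]).
#' @param labeled_indices The video frame indices of `prob_maps`' slices.
#' @return Data frame with `neuron`, `n_frames_used`, `median_probability`.
#' @export
probability_distribution <- function(prob_maps, gt_masks, active_frames,
                                     labeled_indices) {
  prob_maps <- as_frames(prob_maps)
  stats <- lapply(seq_along(gt_masks), function(i) {
    usable <- intersect(active_frames[[i]], labeled_indices)
    if (length(usable) == 0L) return(NULL)
    idx <- mask_pixels(gt_masks[[i]])
    per_frame <- vapply(match(usable, labeled_indices), function(k) {
      median(prob_maps[, , k][idx])
    }, numeric(1))
    data.frame(neuron = i, n_frames_used = length(usable),
               median_probability = median(per_frame))
  })
  dropped <- vapply(stats, is.null, logical(1))
  if (all(dropped))
    sandseg_error(paste(
      "no labeled neuron is active on any labeled frame;",
      "label more frames or lower activity_thresh"), "sandseg_flho_error")
  if (any(dropped))
    warning(sum(dropped), " neuron(s) with no active labeled frame excluded")
  do.call(rbind, stats[!dropped])
}

#' Estimate the probability threshold from the median-probability distribution
#'
#' @param stats Data frame from [probability_distribution()] (or a numeric
#'   vector of per-neuron medians).
#' @param percentile Percentile (of 100) used for the intermediate threshold.
#' @param cap Upper bound on the final threshold.
#' @return List with `intermediate` (the percentile) and `final`
#'   (`min(median, cap)`); percentiles interpolate linearly.
#' @export
estimate_p_thresh <- function(stats, percentile = 25, cap = 0.8) {
  p <- if (is.data.frame(stats)) stats$median_probability else as.numeric(stats)
  if (length(p) == 0L)
    sandseg_error("empty probability distribution", "sandseg_flho_error")
  list(intermediate = unname(quantile(p, percentile / 100, type = 7)),
       final = min(median(p), cap))
}

# Predicted per-frame masks after merging: every record active on a frame
# contributes its consolidated final mask there. Scoring the final masks
# (rather than the raw per-frame components) makes the grid search penalize
# merges that chain distinct neurons into one ROI, mirroring how the
# postprocessing output is ultimately evaluated.
frame_masks_after_merge <- function(records, frame_ids) {
  lapply(frame_ids, function(f) {
    out <- list()
    for (r in records) {
      if (!f %in% r$active_frames) next
      out[[length(out) + 1L]] <- r$mask_pixels
    }
    out
  })
}

# Shared machinery for the spatial grid search: extract components once at
# min_area = 1, then filter by area and merge per grid point.
eval_spatial_grid <- function(prob_maps, gt_per_frame, p_thresh_int, grid,
                              iou_threshold = 0.5) {
  prob_maps <- as_frames(prob_maps)
  h <- dim(prob_maps)[1]
  n <- dim(prob_maps)[3]
  ex <- cpp_extract_stack(prob_maps, p_thresh_int, 1L)
  gt_px <- lapply(gt_per_frame, function(ms) lapply(ms, mask_pixels))
  res <- expand.grid(min_area = grid$min_area_values,
                     centroid_dist = grid$centroid_dist_values)
  res$f1 <- NA_real_
  for (k in seq_len(nrow(res))) {
    keep <- ex$area >= res$min_area[k]
    if (!any(keep)) {
      n_gt <- sum(lengths(gt_px))
      res$f1[k] <- if (n_gt == 0L) 1 else 0
      next
    }
    comps <- lapply(which(keep), function(i) {
      structure(list(frame = ex$frame[i], pixels = ex$pixels[[i]],
                     area = ex$area[i], centroid = c(ex$cr[i], ex$cc[i]),
                     h = h, w = dim(prob_maps)[2]), class = "roi_component")
    })
    groups <- cpp_merge_components(ex$pixels[keep], ex$cr[keep], ex$cc[keep],
                                   ex$area[keep], h, res$centroid_dist[k])
    records <- records_from_groups(comps, groups, h, dim(prob_maps)[2])
    pred <- frame_masks_after_merge(records, seq_len(n))
    res$f1[k] <- pooled_frame_f1(pred, gt_px, iou_threshold)
  }
  res
}

#' Grid search for min_area and centroid_dist on the labeled frames
#'
#' Every grid point runs binarize (at the intermediate threshold), component
#' extraction, and cross-frame merging on the labeled frames, and is scored
#' by frame-level F1 against the per-frame ground-truth masks. Ties prefer
#' the smaller `centroid_dist`, then the larger `min_area` (conservative
#' merging and noise rejection).
#'
#' @param prob_maps `H x W x n` probability maps of the labeled frames.
#' @param gt_per_frame List (per labeled frame) of lists of binary masks of
#'   the neurons active on that frame.
#' @param p_thresh_int Intermediate probability threshold.
#' @param grid A [grid_spec()].
#' @return List with `min_area`, `centroid_dist`, `f1`, and the full `grid`
#'   evaluation (a data frame).
#' @export
grid_search_spatial <- function(prob_maps, gt_per_frame, p_thresh_int,
                                grid = grid_spec()) {
  res <- eval_spatial_grid(prob_maps, gt_per_frame, p_thresh_int, grid)
  ord <- order(-res$f1, res$centroid_dist, -res$min_area)
  best <- res[ord[1L], ]
  list(min_area = as.integer(best$min_area),
       centroid_dist = best$centroid_dist, f1 = best$f1, grid = res)
}

#' Longest consecutive detection run per neuron
#'
#' Thresholds all frames' probability maps at the final `p_thresh`, removes
#' components below `min_area`, and for each ground-truth neuron finds the
#' longest run of consecutive frames containing a component colocalized with
#' its mask (same criteria as merging).
#'
#' @param prob_maps `H x W x T` probability maps for all frames.
#' @param final_p_thresh Final probability threshold.
#' @param min_area Minimum component area.
#' @param gt_masks List of binary neuron masks.
#' @param centroid_dist Distance threshold used in the colocalization test.
#' @return Integer vector of per-neuron maximum run lengths (0 = never
#'   detected).
#' @export
max_consecutive_per_neuron <- function(prob_maps, final_p_thresh, min_area,
                                       gt_masks, centroid_dist) {
  prob_maps <- as_frames(prob_maps)
  h <- dim(prob_maps)[1]
  ex <- cpp_extract_stack(prob_maps, final_p_thresh, as.integer(min_area))
  gt <- lapply(gt_masks, function(m) {
    px <- mask_pixels(m)
    list(pixels = px, area = length(px),
         centroid = c(mean((px - 1L) %% h + 1L), mean((px - 1L) %/% h + 1L)))
  })
  counts <- integer(length(gt_masks))
  if (length(ex$frame) == 0L) return(counts)
  for (i in seq_along(gt)) {
    hit <- vapply(seq_along(ex$frame), function(k) {
      a <- list(pixels = ex$pixels[[k]], centroid = c(ex$cr[k], ex$cc[k]))
      components_colocalized(a, gt[[i]], centroid_dist)
    }, logical(1))
    counts[i] <- max_run(ex$frame[hit])
  }
  counts
}

#' Estimate min_consecutive from per-neuron run lengths
#'
#' Zero counts (undetected neurons) are dropped; the second smallest of the
#' remaining counts is taken (the minimum is occasionally an outlier),
#' falling back to the smallest when only one neuron remains; the result is
#' capped at 8 frames and floored at 1.
#'
#' @param counts Integer run lengths from [max_consecutive_per_neuron()].
#' @param cap Upper bound, frames.
#' @return Integer `min_consecutive`.
#' @export
estimate_min_consecutive <- function(counts, cap = 8L) {
  nz <- sort(counts[counts > 0])
  if (length(nz) == 0L) {
    warning("no neuron was ever detected; min_consecutive set to 1")
    return(1L)
  }
  pick <- if (length(nz) >= 2L) nz[2L] else nz[1L]
  max(1L, min(as.integer(pick), as.integer(cap)))
}

#' Run the full FLHO procedure
#'
#' Executes the four steps in order (see the module description) and returns
#' a complete [hyperparams()]. Only the labeled frames' ground truth is used;
#' unlabeled frames contribute probability maps alone.
#'
#' @param snr_video `snr_video` or `H x W x T` array (all frames).
#' @param prob_maps `H x W x T` probability maps for all frames.
#' @param labeled A [labeled_set()] with `frame_neuron_masks`.
#' @param gt_masks Binary masks of the labeled neurons; defaults to
#'   `labeled$neuron_masks`.
#' @param grid A [grid_spec()].
#' @param activity_thresh Activity threshold, SNR units.
#' @param percentile Intermediate percentile for the threshold estimate.
#' @return A [hyperparams()] with attribute `"flho_details"` recording the
#'   median-probability distribution, the grid evaluation and the run-length
#'   counts.
#' @export
run_flho <- function(snr_video, prob_maps, labeled,
                     gt_masks = labeled$neuron_masks, grid = grid_spec(),
                     activity_thresh = 3, percentile = 25) {
  prob_maps <- as_frames(prob_maps)
  li <- labeled$frame_indices
  active <- neuron_active_frames(snr_video, gt_masks, activity_thresh)
  stats <- probability_distribution(
    prob_maps[, , li, drop = FALSE], gt_masks, active, li)
  pt <- estimate_p_thresh(stats, percentile)
  gt_per_frame <- labeled$frame_neuron_masks
  if (is.null(gt_per_frame))
    sandseg_error("labeled set lacks frame_neuron_masks", "sandseg_flho_error")
  gs <- grid_search_spatial(prob_maps[, , li, drop = FALSE], gt_per_frame,
                            pt$intermediate, grid)
  counts <- max_consecutive_per_neuron(prob_maps, pt$final, gs$min_area,
                                       gt_masks, gs$centroid_dist)
  mc <- estimate_min_consecutive(counts)
  hp <- hyperparams(pt$final, gs$min_area, gs$centroid_dist, mc)
  attr(hp, "flho_details") <- list(
    probability_stats = stats, p_thresh_intermediate = pt$intermediate,
    grid_evaluation = gs$grid, grid_f1 = gs$f1, run_length_counts = counts)
  hp
}
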