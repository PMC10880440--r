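# Scoring predictions against ground truth: greedy one-to-one mask matching
# by IoU, recall/precision/F1, pooled frame-level F1, neuron peak SNR, and
# the convex-hull mask-quality ratio.

iou_pixels <- function(a, b) {
  u <- length(a) + length(b) - length(intersect(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

# Greedy one-to-one matching by descending IoU among pairs with IoU >=
# threshold; masks given as lists of pixel-index vectors.
match_pixel_lists <- function(pred, gt, iou_threshold) {
  np <- length(pred); ng <- length(gt)
  if (np == 0L || ng == 0L)
    return(list(pairs = data.frame(pred_id = integer(0), gt_id = integer(0),
                                   iou = numeric(0)),
                n_tp = 0L, n_gt = ng, n_pred = np))
  scores <- matrix(0, np, ng)
  for (i in seq_len(np))
    for (j in seq_len(ng))
      scores[i, j] <- iou_pixels(pred[[i]], gt[[j]])
  pairs <- which(scores >= iou_threshold, arr.ind = TRUE)
  ord <- order(scores[pairs], decreasing = TRUE)
  pairs <- pairs[ord, , drop = FALSE]
  used_p <- logical(np); used_g <- logical(ng)
  out <- list()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (used_p[i] || used_g[j]) next
    used_p[i] <- TRUE; used_g[j] <- TRUE
    out[[length(out) + 1L]] <- data.frame(pred_id = i, gt_id = j,
                                          iou = scores[i, j])
  }
  pairs_df <- if (length(out)) do.call(rbind, out)
              else data.frame(pred_id = integer(0), gt_id = integer(0),
                              iou = numeric(0))
  list(pairs = pairs_df, n_tp = nrow(pairs_df), n_gt = ng, n_pred = np)
}

as_pixel_list <- function(masks) {
  if (length(masks) == 0L) return(list())
  lapply(masks, function(m) {
    if (inherits(m, "neuron_record")) m$mask_pixels else mask_pixels(m)
  })
}

#' Match predicted masks to ground-truth masks
#'
#' Greedy one-to-one assignment by descending IoU among pairs with IoU at
#' least `iou_threshold`.
#'
#' @param pred,gt Lists of binary masks (matrices, `neuron_record`s, or
#'   pixel-index vectors).
#' @param iou_threshold Minimum IoU for a valid match.
#' @return A `match_result`: list with `pairs` (data frame `pred_id`,
#'   `gt_id`, `iou`), `n_tp`, `n_gt`, `n_pred`.
#' @export
match_masks <- function(pred, gt, iou_threshold = 0.5) {
  res <- match_pixel_lists(as_pixel_list(pred), as_pixel_list(gt),
                           iou_threshold)
  structure(res, class = "match_result")
}

#' Recall, precision and F1 from a match result
#'
#' `recall = TP / n_gt`, `precision = TP / n_pred`,
#' `F1 = 2 / (recall^-1 + precision^-1)` (0 when TP = 0).
#'
#' @param match A `match_result` (or a list with `n_tp`, `n_gt`, `n_pred`).
#' @return List with `recall`, `precision`, `f1`.
#' @export
precision_recall_f1 <- function(match) {
  if (match$n_gt == 0L && match$n_pred == 0L)
    sandseg_error("nothing to evaluate: no ground truth and no predictions",
                  "sandseg_empty_evaluation")
  recall <- if (match$n_gt > 0L) match$n_tp / match$n_gt else 0
  precision <- if (match$n_pred > 0L) match$n_tp / match$n_pred else 0
  f1 <- if (match$n_tp > 0L) 2 / (1 / recall + 1 / precision) else 0
  list(recall = recall, precision = precision, f1 = f1)
}

pooled_frame_f1 <- function(pred_frames, gt_frames, iou_threshold = 0.5) {
  tp <- 0L; ng <- 0L; np <- 0L
  for (k in seq_along(gt_frames)) {
    m <- match_pixel_lists(pred_frames[[k]], gt_frames[[k]], iou_threshold)
    tp <- tp + m$n_tp; ng <- ng + m$n_gt; np <- np + m$n_pred
  }
  if (ng == 0L && np == 0L) return(1)
  if (tp == 0L) return(0)
  precision_recall_f1(list(n_tp = tp, n_gt = ng, n_pred = np))$f1
}

#' Frame-level F1 with counts pooled across frames
#'
#' Each frame is matched independently; true-positive, ground-truth and
#' prediction counts are pooled over frames before computing one F1 (stable
#' when individual frames hold few neurons).
#'
#' @param pred_per_frame,gt_per_frame Lists (one element per frame) of lists
#'   of masks.
#' @param iou_threshold Minimum IoU for a match.
#' @return Scalar F1.
#' @export
frame_f1 <- function(pred_per_frame, gt_per_frame, iou_threshold = 0.5) {
  if (length(gt_per_frame) == 0L)
    sandseg_error("no frames to evaluate", "sandseg_empty_evaluation")
  if (length(pred_per_frame) != length(gt_per_frame))
    sandseg_error("prediction and ground-truth frame lists differ in length",
                  "sandseg_shape_error")
  pooled_frame_f1(lapply(pred_per_frame, as_pixel_list),
                  lapply(gt_per_frame, as_pixel_list), iou_threshold)
}

#' Peak SNR of a neuron
#'
#' Maximum over frames of the mean SNR inside the mask.
#'
#' @param snr_video `snr_video` or `H x W x T` array.
#' @param mask Nonempty binary mask.
#' @return Scalar, SNR units.
#' @export
neuron_psnr <- function(snr_video, mask) {
  max(mask_trace(snr_video, mask))
}

#' Convex-hull mask-quality ratio
#'
#' Mask area divided by the area of its rasterized convex hull (a pixel
#' belongs to the hull when its center lies inside or on the hull polygon of
#' the mask's pixel centers). 1 for convex, soma-like masks; masks with
#' fewer than 3 non-collinear pixels score 1.
#'
#' @param mask Nonempty binary `H x W` matrix.
#' @return Ratio in `(0, 1]`.
#' @export
mask_quality <- function(mask) {
  px <- mask_pixels(mask)
  if (length(px) == 0L)
    sandseg_error("mask is empty", "sandseg_empty_mask")
  h <- nrow(mask)
  r <- (px - 1L) %% h + 1L
  c <- (px - 1L) %/% h + 1L
  hull <- grDevices::chull(c, r)
  if (length(hull) < 3L) return(1)
  bb_r <- min(r):max(r); bb_c <- min(c):max(c)
  cand <- expand.grid(r = bb_r, c = bb_c)
  inside <- pracma::inpolygon(cand$c, cand$r, c[hull], r[hull],
                              boundary = TRUE)
  length(px) / sum(inside)
}
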