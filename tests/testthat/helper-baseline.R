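# SUNS-style reference: a single supervised U-Net plus an exhaustive grid
# search over all four postprocessing hyperparameters, scored by frame-level
# F1 on the labeled frames only. Used as a comparison oracle; deliberately
# not part of the package surface.

baseline_grid_search <- function(prob, lab, p_vals = c(0.3, 0.5, 0.7, 0.9),
                                 grid = grid_spec(soma_radius = 4),
                                 cd_vals = c(2, 4, 6),
                                 mc_vals = c(1, 2, 4, 8)) {
  li <- lab$frame_indices
  gt_px <- lapply(lab$frame_neuron_masks,
                  function(ms) lapply(ms, sandseg:::mask_pixels))
  h <- dim(prob)[1]; w <- dim(prob)[2]
  best <- NULL
  ma_vals <- grid$min_area_values[unique(pmin(length(grid$min_area_values),
                                              c(1, 4, 7, 10)))]
  for (pt in p_vals) {
    ex <- sandseg:::cpp_extract_stack(prob, pt, 1L)
    if (length(ex$frame) == 0) next
    for (ma in ma_vals) {
      keep <- ex$area >= ma
      if (!any(keep)) next
      comps <- lapply(which(keep), function(i) structure(
        list(frame = ex$frame[i], pixels = ex$pixels[[i]], area = ex$area[i],
             centroid = c(ex$cr[i], ex$cc[i]), h = h, w = w),
        class = "roi_component"))
      for (cd in cd_vals) {
        groups <- sandseg:::cpp_merge_components(
          ex$pixels[keep], ex$cr[keep], ex$cc[keep], ex$area[keep], h, cd)
        recs <- sandseg:::records_from_groups(comps, groups, h, w)
        for (mc in mc_vals) {
          surv <- filter_consecutive(recs, mc)
          pred <- sandseg:::frame_masks_after_merge(surv, li)
          f1 <- sandseg:::pooled_frame_f1(pred, gt_px)
          if (is.null(best) || f1 > best$f1)
            best <- list(f1 = f1, hp = hyperparams(pt, ma, cd, mc))
        }
      }
    }
  }
  best
}

# Single-model supervised baseline: ensemble member A after its supervised
# stage (identical training budget to one SAND supervised pass) plus the
# full grid search above.
baseline_suns_f1 <- function(run) {
  probA <- predict(run$fit$ensemble[[1]], run$snr)
  best <- baseline_grid_search(probA, run$labeled)
  if (is.null(best)) return(0)
  rec <- postprocess(probA, best$hp)
  if (length(rec) == 0) return(0)
  precision_recall_f1(match_masks(rec, run$scene$footprints))$f1
}
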