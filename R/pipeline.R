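# End-to-end pipeline: preprocess -> semi-supervised training -> inference
# on all frames -> FLHO -> postprocessing -> optional evaluation, with every
# stage's artifacts persisted to a run directory.

#' Build the matched kernel from labeled neuron masks
#'
#' Computes a preliminary (unfiltered) SNR representation of the raw video,
#' extracts each labeled neuron's SNR trace, collects peak-aligned transient
#' snippets with peak SNR in `[snr_lo, snr_hi]`, and averages them into a
#' matched-filter kernel. Falls back (with a warning) to all detected
#' transients when none falls in the band.
#'
#' @param video Raw `H x W x T` array.
#' @param neuron_masks List of binary masks of the labeled neurons.
#' @param snr_lo,snr_hi Peak-SNR selection band.
#' @return A `calcium_kernel`.
#' @export
build_kernel_from_labels <- function(video, neuron_masks, snr_lo = 5,
                                     snr_hi = 8) {
  snr0 <- snr_normalize(video)
  traces <- lapply(neuron_masks, function(m) snr_trace(snr0, m))
  snips <- collect_transients(traces, snr_lo, snr_hi)
  if (length(snips) == 0L) {
    # No transient inside the band: take the highest peaks available.
    snips <- collect_transients(traces, 0, Inf)
    if (length(snips) == 0L)
      sandseg_error("no transients found in the labeled neurons' traces",
                    "sandseg_kernel_error")
  }
  build_matched_kernel(snips, snr_lo, snr_hi)
}

#' Run the complete SAND pipeline
#'
#' Stages: matched-kernel construction and SNR preprocessing; staged
#' semi-supervised training ([run_sand_training()]); inference of probability
#' maps for all frames; FLHO hyperparameter estimation ([run_flho()]);
#' postprocessing into unique neuron masks ([postprocess()]); and, when
#' ground-truth footprints are supplied, neuron-level evaluation.
#'
#' @param video Raw `H x W x T` array (or a path readable by [read_video()]).
#' @param labeled A [labeled_set()] (or a path readable by [read_labels()];
#'   in that case the labels must reference SNR-space masks of this video).
#' @param out_dir Optional run directory; when given, the resolved config,
#'   kernel, model weights, hyperparameters, masks, metrics and a log are
#'   written there.
#' @param train_cfg A [train_config()].
#' @param grid A [grid_spec()] for FLHO.
#' @param activity_thresh Activity threshold, SNR units.
#' @param seed Seed for the whole run (overrides `train_cfg$seed`).
#' @param gt_footprints Optional list of ground-truth masks for evaluation.
#' @param verbose Print stage progress.
#' @return A `sand_run`: list with `kernel`, `snr_video`, `fit`,
#'   `prob_maps`, `hyperparams`, `records`, and `metrics` (NULL without
#'   ground truth).
#' @export
run_pipeline <- function(video, labeled, out_dir = NULL,
                         train_cfg = train_config(), grid = grid_spec(),
                         activity_thresh = 3, seed = NULL,
                         gt_footprints = NULL, verbose = FALSE) {
  t_start <- Sys.time()
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf("[%5.1fs] %s", as.numeric(Sys.time() - t_start, units = "secs"),
                    paste0(...))
    if (verbose) message(line)
    log_lines <<- c(log_lines, line)
  }
  if (is.character(video)) video <- read_video(video)
  stage <- "preprocess"
  res <- tryCatch({
    if (!is.null(seed)) train_cfg$seed <- seed
    say("preprocess: building matched kernel and SNR video")
    raw_labeled <- if (is.character(labeled)) read_labels(labeled) else labeled
    kernel <- build_kernel_from_labels(video, raw_labeled$neuron_masks)
    snr <- snr_normalize(temporal_filter(video, kernel))
    labeled_snr <- if (is.character(labeled)) read_labels(labeled, snr)
                   else labeled
    if (!inherits(labeled_snr, "labeled_set"))
      sandseg_error("labeled must be a labeled_set or a labels file",
                    "sandseg_config_error")

    stage <- "train"
    say("train: staged semi-supervised schedule (",
        train_cfg$epochs_supervised, "/", train_cfg$epochs_pseudo, "/",
        train_cfg$epochs_finetune, " epochs)")
    fit <- run_sand_training(snr, labeled_snr, train_cfg)

    stage <- "infer"
    say("infer: probability maps for all ", dim(snr$frames)[3], " frames")
    prob <- predict(fit$model, snr)

    stage <- "flho"
    say("flho: estimating the four postprocessing hyperparameters")
    hp <- run_flho(snr, prob, labeled_snr, grid = grid,
                   activity_thresh = activity_thresh)
    say("flho: p_thresh=", signif(hp$p_thresh, 3), " min_area=", hp$min_area,
        " centroid_dist=", hp$centroid_dist,
        " min_consecutive=", hp$min_consecutive)

    stage <- "postprocess"
    records <- postprocess(prob, hp)
    say("postprocess: ", length(records), " neurons")

    metrics <- NULL
    if (!is.null(gt_footprints)) {
      stage <- "evaluate"
      m <- match_masks(records, gt_footprints)
      metrics <- precision_recall_f1(m)
      metrics$n_pred <- m$n_pred
      metrics$n_gt <- m$n_gt
      say("evaluate: F1=", round(metrics$f1, 3),
          " recall=", round(metrics$recall, 3),
          " precision=", round(metrics$precision, 3))
    }
    list(kernel = kernel, snr_video = snr, fit = fit, prob_maps = prob,
         hyperparams = hp, records = records, metrics = metrics,
         labeled = labeled_snr)
  }, sandseg_error = function(e) {
    sandseg_error(paste0("stage '", stage, "' failed: ", conditionMessage(e)),
                  "sandseg_pipeline_error")
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(list(
      seed = train_cfg$seed, activity_thresh = activity_thresh,
      train = unclass(train_cfg[setdiff(names(train_cfg), "loss")]),
      loss = unclass(train_cfg$loss), grid = unclass(grid)),
      file.path(out_dir, "config.yaml"))
    jsonlite::write_json(list(taps = res$kernel$taps,
                              peak_index = res$kernel$peak_index),
                         file.path(out_dir, "kernel.json"),
                         auto_unbox = TRUE, digits = NA)
    saveRDS(res$fit$model, file.path(out_dir, "model.rds"))
    saveRDS(res$fit$ensemble, file.path(out_dir, "ensemble.rds"))
    jsonlite::write_json(list(frame_indices = res$fit$pseudolabels$frame_indices),
                         file.path(out_dir, "pseudolabel_frames.json"),
                         auto_unbox = TRUE, digits = NA)
    hp_out <- unclass(res$hyperparams)
    hp_out$details <- lapply(attr(res$hyperparams, "flho_details"),
                             function(x) x)
    jsonlite::write_json(hp_out, file.path(out_dir, "hyperparams.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    write_masks(res$records, file.path(out_dir, "masks.json"),
                height = dim(video)[1], width = dim(video)[2])
    losses <- res$fit$histories
    loss_df <- do.call(rbind, lapply(names(losses), function(nm)
      data.frame(stage = nm, epoch = seq_along(losses[[nm]]),
                 loss = losses[[nm]])))
    utils::write.csv(loss_df, file.path(out_dir, "loss_history.csv"),
                     row.names = FALSE)
    if (!is.null(res$metrics))
      jsonlite::write_json(res$metrics, file.path(out_dir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  structure(res, class = "sand_run")
}
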