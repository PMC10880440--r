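# File I/O. Videos travel as multi-page 32-bit TIFF stacks (values affinely
# rescaled to [0, 1] with the transform recorded in a JSON sidecar) or as
# RDS; labels and masks as sparse pixel-list JSON; configs as YAML.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a video stack
#'
#' `.tif`/`.tiff` writes a multi-page 32-bit TIFF; intensities are rescaled
#' to `[0, 1]` and the affine transform (`offset`, `scale`) is stored in a
#' `<path>.json` sidecar so reading recovers the original units. `.rds`
#' stores the array losslessly.
#'
#' @param video `H x W x T` array.
#' @param path Output file (`.tif`, `.tiff` or `.rds`).
#' @return `path`, invisibly.
#' @export
write_video <- function(video, path) {
  video <- as_frames(video)
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") {
    saveRDS(video, path)
  } else if (ext %in% c("tif", "tiff")) {
    lo <- min(video); hi <- max(video)
    scale <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_len(dim(video)[3]),
                    function(t) (video[, , t] - lo) / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    jsonlite::write_json(list(offset = lo, scale = scale,
                              dim = dim(video)),
                         sidecar_path(path), auto_unbox = TRUE, digits = NA)
  } else {
    sandseg_error("unsupported video format: .tif/.tiff/.rds expected",
                  "sandseg_io_error")
  }
  invisible(path)
}

#' Read a video stack
#'
#' Accepts the formats written by [write_video()]. A TIFF without a sidecar
#' is read as stored (values in `[0, 1]`).
#'
#' @param path Input file.
#' @return `H x W x T` numeric array.
#' @export
read_video <- function(path) {
  if (!file.exists(path))
    sandseg_error(paste("no such file:", path), "sandseg_io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") {
    video <- readRDS(path)
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(dim(pages[[1]])) != 2L)
      sandseg_error("expected single-channel grayscale TIFF pages",
                    "sandseg_io_error")
    video <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
    sc <- sidecar_path(path)
    if (file.exists(sc)) {
      meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
      video <- video * meta$scale + meta$offset
    }
  } else {
    sandseg_error("unsupported video format: .tif/.tiff/.rds expected",
                  "sandseg_io_error")
  }
  if (length(dim(video)) != 3L)
    sandseg_error("video must be 3-dimensional (H x W x T)", "sandseg_io_error")
  video
}

masks_to_sparse <- function(masks) {
  lapply(masks, function(m) {
    px <- mask_pixels(m)
    h <- if (is.matrix(m)) nrow(m) else attr(m, "h")
    cbind(row = (px - 1L) %% h + 1L, col = (px - 1L) %/% h + 1L)
  })
}

sparse_to_mask <- function(rc, h, w) {
  m <- matrix(FALSE, h, w)
  rc <- matrix(as.integer(unlist(rc)), ncol = 2, byrow = TRUE,
               dimnames = list(NULL, c("row", "col")))
  if (any(rc[, 1] < 1 | rc[, 1] > h | rc[, 2] < 1 | rc[, 2] > w))
    sandseg_error("mask pixel outside the field", "sandseg_io_error")
  m[rc] <- TRUE
  m
}

#' Write labeled frames as sparse pixel-list JSON
#'
#' Layout: `height`, `width`, `frames` (1-based indices), `frame_masks`
#' (per frame, per active neuron: pixel `[row, col]` lists) and
#' `neuron_masks` (per labeled neuron).
#'
#' @param labeled A [labeled_set()].
#' @param path Output `.json` file.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labeled, path) {
  d <- dim(labeled$snr_frames)
  per_frame <- lapply(labeled$frame_neuron_masks %||% list(), masks_to_sparse)
  jsonlite::write_json(list(
    height = d[1], width = d[2], frames = labeled$frame_indices,
    frame_masks = per_frame,
    neuron_masks = masks_to_sparse(labeled$neuron_masks)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read labels written by [write_labels()]
#'
#' @param path Input `.json` file.
#' @param snr_video Optional video/array; when given, the labeled frames are
#'   sliced from it, shapes are validated, and a full [labeled_set()] is
#'   returned. Otherwise the raw components are returned.
#' @return A `labeled_set` (with `snr_video`) or a list of components.
#' @export
read_labels <- function(path, snr_video = NULL) {
  if (!file.exists(path))
    sandseg_error(paste("no such file:", path), "sandseg_io_error")
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  h <- raw$height; w <- raw$width
  frames <- as.integer(unlist(raw$frames))
  if (anyDuplicated(frames))
    sandseg_error("duplicate frame indices in labels", "sandseg_io_error")
  neuron_masks <- lapply(raw$neuron_masks, sparse_to_mask, h = h, w = w)
  per_frame <- lapply(raw$frame_masks, function(f)
    lapply(f, sparse_to_mask, h = h, w = w))
  if (is.null(snr_video))
    return(list(frame_indices = frames, height = h, width = w,
                neuron_masks = neuron_masks, frame_neuron_masks = per_frame))
  arr <- as_frames(snr_video)
  if (dim(arr)[1] != h || dim(arr)[2] != w)
    sandseg_error("label field size does not match the video", "sandseg_io_error")
  if (any(frames > dim(arr)[3]))
    sandseg_error("labeled frame index beyond the video length", "sandseg_io_error")
  tm <- array(FALSE, c(h, w, length(frames)))
  for (k in seq_along(frames))
    for (m in per_frame[[k]]) tm[, , k] <- tm[, , k] | m
  labeled_set(frames, arr[, , frames, drop = FALSE], tm,
              neuron_masks = neuron_masks, frame_neuron_masks = per_frame)
}

#' Write neuron records as JSON
#'
#' Each record stores `id`, `area`, `centroid`, `active_frames` and the
#' sparse pixel list of its final mask.
#'
#' @param records List of `neuron_record`s from [postprocess()].
#' @param path Output `.json` file.
#' @param height,width Field size; taken from the records when omitted.
#' @return `path`, invisibly.
#' @export
write_masks <- function(records, path, height = NULL, width = NULL) {
  h <- height %||% (if (length(records)) records[[1]]$h else 0L)
  w <- width %||% (if (length(records)) records[[1]]$w else 0L)
  recs <- lapply(records, function(r) list(
    id = r$id, area = r$area, centroid = r$centroid,
    active_frames = r$active_frames,
    pixels = cbind(row = (r$mask_pixels - 1L) %% r$h + 1L,
                   col = (r$mask_pixels - 1L) %/% r$h + 1L)))
  jsonlite::write_json(list(height = h, width = w, neurons = recs), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read neuron records written by [write_masks()]
#'
#' @param path Input `.json` file.
#' @return List of `neuron_record`s.
#' @export
read_masks <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  h <- raw$height; w <- raw$width
  lapply(raw$neurons, function(r) {
    rc <- matrix(as.integer(unlist(r$pixels)), ncol = 2, byrow = TRUE)
    px <- sort((rc[, 2] - 1L) * h + rc[, 1])
    structure(list(id = r$id, member_components = NULL,
                   active_frames = as.integer(unlist(r$active_frames)),
                   mask_pixels = px, area = length(px),
                   centroid = as.numeric(unlist(r$centroid)), h = h, w = w),
              class = "neuron_record")
  })
}

#' Write a ground-truth scene to a directory
#'
#' Writes `video.tif` (+ sidecar), `ground_truth.json` (sparse footprints,
#' spike times, traces, nominal active frames) and `scene_config.yaml`.
#'
#' @param scene,video A [generate_scene()] result's two elements.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, video, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_video(video, file.path(dir, "video.tif"))
  jsonlite::write_json(list(
    footprints = masks_to_sparse(scene$footprints),
    spike_times = scene$spike_times,
    traces = scene$traces,
    active_frames = scene$temporal_activity),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(unclass(scene$config), file.path(dir, "scene_config.yaml"))
  invisible(dir)
}
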