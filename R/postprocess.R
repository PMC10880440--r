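# Probability maps -> unique neuron masks: strict probability thresholding,
# 8-connected component extraction with a minimum area, transitive merging of
# colocalized components across frames, and a consecutive-activity filter.

#' The four postprocessing hyperparameters
#'
#' @param p_thresh Probability threshold in (0, 1]; pixels are active when
#'   strictly above it. FLHO caps it at 0.8.
#' @param min_area Minimum component area, pixels (>= 1).
#' @param centroid_dist Center-of-mass distance below which two components
#'   are considered the same neuron, pixels.
#' @param min_consecutive Minimum length of a run of consecutive active
#'   frames required to keep a neuron (>= 1; FLHO caps it at 8).
#' @return A `hyperparams` list.
#' @export
hyperparams <- function(p_thresh, min_area, centroid_dist, min_consecutive) {
  if (p_thresh <= 0 || p_thresh > 1)
    sandseg_error("p_thresh must lie in (0, 1]", "sandseg_config_error")
  if (min_area < 1 || min_consecutive < 1 || centroid_dist < 0)
    sandseg_error("min_area/min_consecutive must be >= 1 and centroid_dist >= 0",
                  "sandseg_config_error")
  structure(list(p_thresh = p_thresh, min_area = as.integer(min_area),
                 centroid_dist = centroid_dist,
                 min_consecutive = as.integer(min_consecutive)),
            class = "hyperparams")
}

#' Binarize a probability map
#'
#' A pixel is active iff its value is strictly greater than `p_thresh`.
#'
#' @param prob_map `H x W` matrix in `[0, 1]`.
#' @param p_thresh Threshold in (0, 1].
#' @return Logical matrix.
#' @export
binarize <- function(prob_map, p_thresh) {
  if (p_thresh <= 0 || p_thresh > 1)
    sandseg_error("p_thresh must lie in (0, 1]", "sandseg_config_error")
  prob_map > p_thresh
}

new_component <- function(pixels, frame, h, w) {
  frame <- as.integer(frame)
  pixels <- sort(as.integer(pixels))
  r <- (pixels - 1L) %% h + 1L
  c <- (pixels - 1L) %/% h + 1L
  structure(list(frame = frame, pixels = pixels, area = length(pixels),
                 centroid = c(mean(r), mean(c)), h = h, w = w),
            class = "roi_component")
}

#' Extract connected components from a binary frame
#'
#' Components are 8-connected (diagonal neighbors touch); those smaller than
#' `min_area` are dropped. Centroids are unweighted means of pixel
#' coordinates (1-based rows/cols).
#'
#' @param binary_frame Logical/0-1 matrix.
#' @param min_area Minimum area in pixels.
#' @param frame_index Frame index recorded on each component.
#' @return List of `roi_component` objects (`frame`, `pixels` as sorted
#'   linear indices, `area`, `centroid`).
#' @export
extract_components <- function(binary_frame, min_area = 1L, frame_index = 1L) {
  lab <- cpp_label_components(matrix(as.integer(binary_frame != 0),
                                     nrow(binary_frame)))
  k <- max(lab)
  if (k == 0L) return(list())
  px <- split(which(lab > 0), lab[lab > 0])
  out <- lapply(px, new_component, frame = frame_index,
                h = nrow(binary_frame), w = ncol(binary_frame))
  out <- out[vapply(out, function(cp) cp$area >= min_area, logical(1))]
  unname(out)
}

mask_pixels <- function(m) {
  if (is.matrix(m)) which(m != 0) else sort(as.integer(m))
}

#' Intersection-over-union of two binary masks
#'
#' @param m1,m2 Binary masks (matrices of identical shape).
#' @return `|m1 & m2| / |m1 | m2|` in `[0, 1]`; 0 with a warning when both
#'   masks are empty.
#' @export
iou <- function(m1, m2) {
  check_same_shape(m1, m2)
  a <- mask_pixels(m1); b <- mask_pixels(m2)
  u <- length(union(a, b))
  if (u == 0L) {
    warning("IoU of two empty masks is undefined; returning 0")
    return(0)
  }
  length(intersect(a, b)) / u
}

#' Consume ratio of two binary masks
#'
#' Fraction of `m2` covered by `m1`.
#'
#' @param m1,m2 Binary masks; `m2` must be nonempty.
#' @return `|m1 & m2| / |m2|` in `[0, 1]`.
#' @export
consume <- function(m1, m2) {
  check_same_shape(m1, m2)
  a <- mask_pixels(m1); b <- mask_pixels(m2)
  if (length(b) == 0L)
    sandseg_error("consume is undefined for an empty m2", "sandseg_empty_mask")
  length(intersect(a, b)) / length(b)
}

component_pixels <- function(x) {
  if (inherits(x, "neuron_record")) x$mask_pixels
  else if (is.list(x) && !is.null(x$pixels)) x$pixels
  else mask_pixels(x)
}

component_centroid <- function(x, h = NULL) {
  if (!is.null(x$centroid)) return(x$centroid)
  px <- component_pixels(x)
  h <- h %||% nrow(x)
  c(mean((px - 1L) %% h + 1L), mean((px - 1L) %/% h + 1L))
}

#' Are two components the same neuron?
#'
#' True when the centers of mass are within `centroid_dist`, or IoU > 0.5, or
#' the larger mask consumes more than 0.75 of the smaller one.
#'
#' @param a,b `roi_component`/`neuron_record` objects (or binary matrices).
#' @param centroid_dist Distance threshold, pixels.
#' @return Logical.
#' @export
components_colocalized <- function(a, b, centroid_dist) {
  pa <- component_pixels(a); pb <- component_pixels(b)
  ca <- component_centroid(a); cb <- component_centroid(b)
  if (sqrt(sum((ca - cb)^2)) < centroid_dist) return(TRUE)
  inter <- length(intersect(pa, pb))
  if (inter == 0L) return(FALSE)
  if (inter / length(union(pa, pb)) > 0.5) return(TRUE)
  small <- if (length(pa) <= length(pb)) pa else pb
  inter / length(small) > 0.75
}

# Build neuron records from components and their group assignment.
records_from_groups <- function(components, groups, h, w) {
  recs <- lapply(sort(unique(groups)), function(g) {
    member <- components[groups == g]
    counts <- table(unlist(lapply(member, `[[`, "pixels")))
    keep <- as.integer(names(counts)[counts * 2L >= length(member)])
    if (length(keep) == 0L) keep <- as.integer(names(counts))
    keep <- sort(keep)
    r <- (keep - 1L) %% h + 1L
    c <- (keep - 1L) %/% h + 1L
    structure(list(id = g, member_components = member,
                   active_frames = sort(unique(as.integer(
                     vapply(member, function(m) m$frame, numeric(1))))),
                   mask_pixels = keep, area = length(keep),
                   centroid = c(mean(r), mean(c)), h = h, w = w),
              class = "neuron_record")
  })
  unname(recs)
}

#' Merge colocalized components across frames into neuron records
#'
#' Takes the transitive closure of pairwise colocalization
#' ([components_colocalized()]) over all components via union-find; the
#' result is independent of input ordering. Each record's final mask keeps
#' the pixels present in at least 50% of its member components (falling back
#' to the union when that is empty).
#'
#' @param components List of `roi_component`s from one or more frames.
#' @param centroid_dist Distance threshold, pixels.
#' @return List of `neuron_record`s (`mask_pixels`, `active_frames`,
#'   `member_components`, `centroid`).
#' @export
merge_components <- function(components, centroid_dist) {
  if (length(components) == 0L) return(list())
  h <- components[[1]]$h; w <- components[[1]]$w
  groups <- cpp_merge_components(
    lapply(components, `[[`, "pixels"),
    vapply(components, function(cp) cp$centroid[1], numeric(1)),
    vapply(components, function(cp) cp$centroid[2], numeric(1)),
    vapply(components, `[[`, integer(1), "area"),
    h, centroid_dist)
  records_from_groups(components, groups, h, w)
}

#' Keep neurons active for enough consecutive frames
#'
#' @param records List of `neuron_record`s.
#' @param min_consecutive Minimum run length, frames.
#' @return The surviving records.
#' @export
filter_consecutive <- function(records, min_consecutive) {
  if (min_consecutive < 1)
    sandseg_error("min_consecutive must be >= 1", "sandseg_config_error")
  keep <- vapply(records, function(r) max_run(r$active_frames) >= min_consecutive,
                 logical(1))
  records[keep]
}

#' Render a record's final mask as a logical matrix
#'
#' @param record A `neuron_record`.
#' @return Logical `H x W` matrix.
#' @export
record_mask <- function(record) {
  m <- matrix(FALSE, record$h, record$w)
  m[record$mask_pixels] <- TRUE
  m
}

#' Full postprocessing chain: probability maps to unique neurons
#'
#' Composition of [binarize()], [extract_components()],
#' [merge_components()] and [filter_consecutive()].
#'
#' @param prob_maps `H x W x T` array of probability maps.
#' @param hp A [hyperparams()].
#' @return List of `neuron_record`s; each holds its final mask pixels and the
#'   set of frames on which it was active.
#' @export
postprocess <- function(prob_maps, hp) {
  stopifnot(inherits(hp, "hyperparams"))
  prob_maps <- as_frames(prob_maps)
  h <- dim(prob_maps)[1]; w <- dim(prob_maps)[2]
  ex <- cpp_extract_stack(prob_maps, hp$p_thresh, hp$min_area)
  if (length(ex$frame) == 0L) return(list())
  components <- lapply(seq_along(ex$frame), function(i) {
    structure(list(frame = ex$frame[i], pixels = ex$pixels[[i]],
                   area = ex$area[i], centroid = c(ex$cr[i], ex$cc[i]),
                   h = h, w = w), class = "roi_component")
  })
  groups <- cpp_merge_components(ex$pixels, ex$cr, ex$cc, ex$area, h,
                                 hp$centroid_dist)
  records <- records_from_groups(components, groups, h, w)
  filter_consecutive(records, hp$min_consecutive)
}
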