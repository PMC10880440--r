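# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

sandseg_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "sandseg_error")))
}

# Deterministic per-component sub-seed derived from a scene/run seed, kept
# within 32-bit integer range. Index 0 is reserved for scene-level noise.
sub_seed <- function(seed, index) {
  (as.numeric(seed) * 10007 + 7919 * index) %% 2147483647
}

# Accept an snr_video object, a plain H x W x T array, or a single H x W
# matrix (promoted to one frame); return the H x W x T array.
as_frames <- function(x) {
  if (inherits(x, "snr_video")) return(x$frames)
  if (is.matrix(x)) return(array(x, c(nrow(x), ncol(x), 1L)))
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stop("expected an snr_video, an H x W x T array, or an H x W matrix")
}

n_frames_of <- function(x) dim(as_frames(x))[3L]

# Mean value inside `mask` for every frame; `mask` is a logical/0-1 matrix
# or a vector of linear pixel indices.
mask_trace <- function(frames, mask) {
  frames <- as_frames(frames)
  d <- dim(frames)
  idx <- if (is.matrix(mask)) which(mask != 0) else as.integer(mask)
  if (length(idx) == 0L) sandseg_error("mask is empty", "sandseg_empty_mask")
  m <- matrix(frames, d[1L] * d[2L], d[3L])
  colMeans(m[idx, , drop = FALSE])
}

# Longest run of consecutive integers in a set of frame indices.
max_run <- function(frames) {
  frames <- sort(unique(as.integer(frames)))
  if (length(frames) == 0L) return(0L)
  if (length(frames) == 1L) return(1L)
  r <- rle(diff(frames) == 1L)
  runs <- r$lengths[r$values]
  if (length(runs) == 0L) 1L else max(runs) + 1L
}

# Indices implementing reflect padding of 1:n up to length n + pad.
reflect_tail <- function(n, pad) {
  if (pad == 0L) return(seq_len(n))
  c(seq_len(n), seq(n, by = -1L, length.out = pad))
}

# Pad an H x W (x B) array to multiples of 8 by edge reflection; returns the
# padded array plus the original size for cropping.
pad_to_multiple8 <- function(x) {
  d <- dim(x)
  h <- d[1L]; w <- d[2L]
  ph <- (8L - h %% 8L) %% 8L
  pw <- (8L - w %% 8L) %% 8L
  if (ph == 0L && pw == 0L) return(list(x = x, h = h, w = w))
  ri <- reflect_tail(h, ph)
  ci <- reflect_tail(w, pw)
  x <- if (length(d) == 2L) x[ri, ci, drop = FALSE] else x[ri, ci, , drop = FALSE]
  list(x = x, h = h, w = w)
}

crop_hw <- function(x, h, w) {
  if (length(dim(x)) == 2L) x[seq_len(h), seq_len(w), drop = FALSE]
  else x[seq_len(h), seq_len(w), , drop = FALSE]
}

# The dihedral group of the square: choice 0..7 encodes rotation by
# 90 * (choice %% 4) degrees, preceded by a horizontal flip when choice >= 4.
apply_dihedral <- function(m, choice) {
  stopifnot(choice %in% 0:7)
  if (choice >= 4L) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  k <- choice %% 4L
  rot90 <- function(x) t(x[rev(seq_len(nrow(x))), , drop = FALSE])
  for (i in seq_len(k)) m <- rot90(m)
  m
}

is_square <- function(m) nrow(m) == ncol(m)
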