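# Independent reference implementations used as test oracles. They share no
# code with the implementation paths they check: closure over the
# colocalization graph is recomputed with igraph (or plain reachability),
# and mask matching is checked against an exact maximum bipartite matching.

# Brute-force postprocessing: enumerate every component pair, build the full
# colocalization graph, take connected components, consolidate masks with
# the >= 50% membership rule, and apply the consecutive filter.
brute_force_postprocess <- function(prob_maps, hp) {
  h <- dim(prob_maps)[1]; w <- dim(prob_maps)[2]
  comps <- list()
  for (t in seq_len(dim(prob_maps)[3])) {
    comps <- c(comps, extract_components(binarize(prob_maps[, , t], hp$p_thresh),
                                         hp$min_area, frame_index = t))
  }
  n <- length(comps)
  if (n == 0L) return(list())
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (i != j)
        adj[i, j] <- components_colocalized(comps[[i]], comps[[j]],
                                            hp$centroid_dist)
  g <- igraph::graph_from_adjacency_matrix(adj | t(adj), mode = "undirected")
  membership <- igraph::components(g)$membership
  records <- lapply(unique(membership), function(gid) {
    member <- comps[membership == gid]
    counts <- table(unlist(lapply(member, `[[`, "pixels")))
    keep <- sort(as.integer(names(counts)[counts * 2L >= length(member)]))
    if (length(keep) == 0L) keep <- sort(as.integer(names(counts)))
    list(mask_pixels = keep,
         active_frames = sort(unique(vapply(member, `[[`, integer(1), "frame"))))
  })
  keep <- vapply(records, function(r) {
    fr <- r$active_frames
    if (length(fr) == 1L) run <- 1L
    else {
      rl <- rle(diff(fr) == 1L)
      good <- rl$lengths[rl$values]
      run <- if (length(good)) max(good) + 1L else 1L
    }
    run >= hp$min_consecutive
  }, logical(1))
  records[keep]
}

# Canonical form for comparing record sets up to id relabeling.
canonical_records <- function(records) {
  sig <- lapply(records, function(r) list(
    mask = sort(as.integer(if (!is.null(r$mask_pixels)) r$mask_pixels else r$mask)),
    frames = sort(as.integer(r$active_frames))))
  sig[order(vapply(sig, function(s) paste(s$mask, collapse = ","), character(1)))]
}

# Random probability stack with <= max_blobs planted discs, each active on a
# random run of frames, plus uniform noise speckle.
random_blob_stack <- function(h = 16, w = 16, T_ = 30, max_blobs = 4) {
  stack <- array(runif(h * w * T_, 0, 0.25), c(h, w, T_))
  for (b in seq_len(sample.int(max_blobs, 1))) {
    m <- disc_mask(h, w, sample(3:(h - 3), 1), sample(3:(w - 3), 1),
                   runif(1, 1.5, 3))
    start <- sample.int(T_ - 5L, 1)
    len <- sample.int(8L, 1)
    for (t in start:min(T_, start + len)) {
      stack[, , t][m] <- runif(sum(m), 0.6, 1)
    }
  }
  stack
}

# Exact maximum bipartite matching (augmenting paths) on pairs with IoU >=
# threshold; returns the maximum number of one-to-one matches.
max_matching_tp <- function(pred_px, gt_px, iou_threshold = 0.5) {
  np <- length(pred_px); ng <- length(gt_px)
  if (np == 0L || ng == 0L) return(0L)
  ok <- matrix(FALSE, np, ng)
  for (i in seq_len(np))
    for (j in seq_len(ng)) {
      inter <- length(intersect(pred_px[[i]], gt_px[[j]]))
      uni <- length(pred_px[[i]]) + length(gt_px[[j]]) - inter
      ok[i, j] <- uni > 0 && inter / uni >= iou_threshold
    }
  match_of_gt <- rep(0L, ng)
  visited <- rep(FALSE, ng)
  try_assign <- function(i) {
    for (j in which(ok[i, ])) {
      if (visited[j]) next
      visited[j] <<- TRUE
      if (match_of_gt[j] == 0L || try_assign(match_of_gt[j])) {
        match_of_gt[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  tp <- 0L
  for (i in seq_len(np)) {
    visited <- rep(FALSE, ng)
    if (try_assign(i)) tp <- tp + 1L
  }
  tp
}

# Independent dihedral reference: horizontal flip first (choice >= 4), then
# choice %% 4 clockwise quarter-turns via transpose + column reversal.
apply_dihedral_ref <- function(m, choice) {
  if (choice >= 4) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  for (i in seq_len(choice %% 4)) {
    m <- t(m)
    m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  }
  m
}
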