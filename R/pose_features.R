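feature_names <- function() {
  self <- c("head_length", "body_length", "head_body_angle",
            "ear_nose_left", "ear_nose_right",
            "ear_body_angle_left", "ear_body_angle_right",
            "disp_angle", "disp_dist")
  c(paste0(self, "_A"), paste0(self, "_B"),
    "body_body_angle", "head_head_angle",
    "nose_nose_distance", "nose_nose_angle",
    "tail_nose_dist_AB", "tail_nose_angle_AB",
    "tail_nose_dist_BA", "tail_nose_angle_BA")
}

#' Per-frame 26-feature series of a two-mouse pose session
#'
#' Nine self features per mouse (head length, body length, head-body
#' angle, two ear-to-nose lengths, two ear-body angles, displacement
#' angle and distance between consecutive frames) and eight interaction
#' features (body-body and head-head angles, nose-nose distance and
#' angle, and tail-to-opposite-nose distance and angle both ways).
#' Lengths are in pixels; angles in degrees -- undirected angles in
#' \[0, 180\] except the displacement angle, reported as a polar heading
#' in \[0, 360).  The first frame inherits the second frame's
#' displacement so every frame has a complete vector.
#'
#' @param session A `pose_session` (see [gen_pose_session()]).
#' @return frames x 26 numeric matrix with feature column names.
#' @export
compute_features <- function(session) {
  co <- session$coords
  n <- dim(co)[1]
  if (n < 2) stop("displacement undefined for a single-frame session")
  if (any(!is.finite(co))) stop("coordinates must be finite (interpolate gaps first)")
  get <- function(animal, node) co[, animal, node, ]  # n x 2
  self_feats <- function(animal) {
    nose <- get(animal, "nose"); head <- get(animal, "head")
    cen <- get(animal, "body_centroid"); tail <- get(animal, "tail_base")
    eL <- get(animal, "left_ear"); eR <- get(animal, "right_ear")
    hv <- nose - head           # head direction
    bv <- head - cen            # body direction
    ang <- function(u, v) {
      vapply(seq_len(n), function(i) vector_angle_deg(u[i, ], v[i, ]), 0)
    }
    len <- function(u) sqrt(rowSums(u^2))
    disp <- cen - rbind(cen[1, , drop = FALSE], cen[-n, , drop = FALSE])
    disp[1, ] <- disp[2, ]
    disp_angle <- (rad2deg(atan2(disp[, 2], disp[, 1]))) %% 360
    disp_angle[rowSums(abs(disp)) == 0] <- 0
    cbind(head_length = len(hv), body_length = len(head - tail),
          head_body_angle = ang(hv, bv),
          ear_nose_left = len(eL - nose), ear_nose_right = len(eR - nose),
          ear_body_angle_left = ang(eL - head, bv),
          ear_body_angle_right = ang(eR - head, bv),
          disp_angle = disp_angle, disp_dist = len(disp))
  }
  fa <- self_feats("A"); fb <- self_feats("B")
  axis <- function(animal) get(animal, "head") - get(animal, "tail_base")
  hdir <- function(animal) get(animal, "nose") - get(animal, "head")
  angv <- function(u, v) vapply(seq_len(n), function(i) vector_angle_deg(u[i, ], v[i, ]), 0)
  noseA <- get("A", "nose"); noseB <- get("B", "nose")
  tailA <- get("A", "tail_base"); tailB <- get("B", "tail_base")
  nn <- noseB - noseA
  inter <- cbind(
    body_body_angle = angv(axis("A"), axis("B")),
    head_head_angle = angv(hdir("A"), hdir("B")),
    nose_nose_distance = sqrt(rowSums(nn^2)),
    nose_nose_angle = angv(nn, hdir("A")),
    tail_nose_dist_AB = sqrt(rowSums((noseB - tailA)^2)),
    tail_nose_angle_AB = angv(noseB - tailA, axis("A")),
    tail_nose_dist_BA = sqrt(rowSums((noseA - tailB)^2)),
    tail_nose_angle_BA = angv(noseA - tailB, axis("B"))
  )
  out <- cbind(fa, fb, inter)
  colnames(out) <- feature_names()
  out
}

#' Aggregate frame features into 500 ms clips
#'
#' Divides the session into non-overlapping clips (dropping a trailing
#' partial clip), averages the frame features within each clip, and
#' z-scores every feature across clips.  A zero-variance feature z-scores
#' to 0 and is flagged.
#'
#' @param features frames x 26 matrix from [compute_features()].
#' @param fps Frames per second. @param clip_ms Clip length (default 500).
#' @return List: `clips` (clips x 26 z-scored matrix), `raw` (clip
#'   means), `start_frame`, `constant` (flagged zero-SD features).
#' @export
make_clips <- function(features, fps, clip_ms = 500) {
  per <- round(fps * clip_ms / 1000)
  n_clips <- floor(nrow(features) / per)
  if (n_clips < 1) stop("session shorter than one clip")
  idx <- rep(seq_len(n_clips), each = per)
  raw <- apply(features[seq_len(n_clips * per), , drop = FALSE], 2,
               function(col) tapply(col, idx, mean))
  raw <- matrix(raw, nrow = n_clips, dimnames = list(NULL, colnames(features)))
  mu <- colMeans(raw); sdv <- apply(raw, 2, stats::sd)
  constant <- sdv == 0 | !is.finite(sdv)
  z <- sweep(raw, 2, mu)
  z <- sweep(z, 2, ifelse(constant, 1, sdv), "/")
  z[, constant] <- 0
  list(clips = z, raw = raw, start_frame = (seq_len(n_clips) - 1L) * per + 1L,
       constant = names(which(constant)))
}

#' Hierarchical clustering of behavior clips into motifs
#'
#' Agglomerative clustering on the z-scored clip vectors using Euclidean
#' distance (Ward linkage by default; single/complete/average available).
#' Clusters listed in `noise` are dropped (labelled NA) after cutting.
#'
#' @param clips Clips x features matrix. @param n_clusters Target number
#'   of clusters (or use `cut_height`). @param cut_height Dendrogram cut
#'   height alternative.
#' @param linkage hclust method (default `"ward.D2"`).
#' @param noise Integer motif ids to drop as noise.
#' @return List: `labels` (motif id per clip, NA for noise), `hclust`.
#' @export
cluster_motifs <- function(clips, n_clusters = NULL, cut_height = NULL,
                           linkage = "ward.D2", noise = integer()) {
  if (nrow(clips) < 2) stop("need >= 2 clips")
  if (!is.null(n_clusters) && n_clusters > nrow(clips)) {
    stop("n_clusters exceeds number of clips")
  }
  hc <- stats::hclust(stats::dist(clips), method = linkage)
  labels <- if (!is.null(n_clusters)) {
    stats::cutree(hc, k = n_clusters)
  } else if (!is.null(cut_height)) {
    stats::cutree(hc, h = cut_height)
  } else {
    stop("supply n_clusters or cut_height")
  }
  labels[labels %in% noise] <- NA_integer_
  list(labels = labels, hclust = hc)
}

#' Paper-preset motif-to-class mapping
#'
#' Motifs 17 and 18 are snatch, 2 and 4 retreat, 16 other; motifs 1, 6
#' and 8 are noise and dropped.
#' @return List with `mapping` (named class per motif id) and `noise`.
#' @export
motif_class_preset <- function() {
  list(mapping = c(`17` = "snatch", `18` = "snatch", `2` = "retreat",
                   `4` = "retreat", `16` = "other"),
       noise = c(1L, 6L, 8L))
}

#' Map motif labels to behavior classes
#'
#' @param labels Motif id per clip (NA = noise, dropped).
#' @param mapping Named character vector motif id -> class.
#' @return Factor of classes with NA for dropped clips.
#' @export
classify_behavior <- function(labels, mapping) {
  out <- rep(NA_character_, length(labels))
  keep <- !is.na(labels)
  unmapped <- setdiff(unique(labels[keep]), as.integer(names(mapping)))
  if (length(unmapped)) {
    stop("unmapped non-noise motifs: ", paste(unmapped, collapse = ", "))
  }
  out[keep] <- unname(mapping[as.character(labels[keep])])
  factor(out, levels = behavior_classes)
}

#' Event counts and durations from a class series
#'
#' An event is a maximal run of identical class labels; its duration is
#' the run length times the clip width.
#'
#' @param classes Behavior class per clip (factor or character).
#' @param clip_s Clip width in seconds (default 0.5).
#' @return Data frame per class: `events`, `total_s`, plus a `durations`
#'   list column of per-event durations.
#' @export
event_metrics <- function(classes, clip_s = 0.5) {
  classes <- as.character(classes)
  r <- rle(classes)
  out <- lapply(behavior_classes, function(cl) {
    runs <- r$lengths[!is.na(r$values) & r$values == cl]
    data.frame(class = cl, events = length(runs),
               total_s = sum(runs) * clip_s)
  })
  res <- do.call(rbind, out)
  res$durations <- lapply(behavior_classes, function(cl) {
    r$lengths[!is.na(r$values) & r$values == cl] * clip_s
  })
  res
}

#' Food-possession occupancy under the 3-second defender rule
#'
#' The first mouse to hold the pellet is the defender.  A challenger's
#' take only becomes a defender switch if the challenger keeps the pellet
#' for at least 3 s; shorter holds are logged as failed bouts and the
#' defender is unchanged.  Cumulative occupancy is total time spent as
#' defender.
#'
#' @param timeline Data frame `t` (seconds, strictly increasing) and
#'   `holder` ("A", "B" or "none") giving possession changes.
#' @param session_end Session end time in seconds.
#' @param hold_s Required hold for a defender switch (default 3).
#' @return List: `occupancy` (named seconds), `defender_timeline`
#'   (data frame start/end/defender), `bouts` (challenge log),
#'   `win_rate` (successful challenges / challenges per mouse).
#' @export
occupancy_score <- function(timeline, session_end, hold_s = 3) {
  stopifnot(all(c("t", "holder") %in% names(timeline)))
  if (is.unsorted(timeline$t, strictly = TRUE)) {
    stop("overlapping or unordered possession claims")
  }
  if (any(timeline$t > session_end)) stop("claim after session end")
  holders <- as.character(timeline$holder)
  ts <- timeline$t
  defender <- NA_character_
  seg_start <- NA_real_
  segs <- list(); bouts <- list()
  n <- length(ts)
  for (i in seq_len(n)) {
    h <- holders[i]
    t_end_hold <- if (i < n) ts[i + 1] else session_end
    if (h == "none") next
    if (is.na(defender)) {            # first pickup
      defender <- h; seg_start <- ts[i]
    } else if (h != defender) {       # challenge
      success <- (t_end_hold - ts[i]) >= hold_s
      bouts[[length(bouts) + 1]] <- data.frame(
        t = ts[i], challenger = h, success = success)
      if (success) {
        segs[[length(segs) + 1]] <- data.frame(
          start = seg_start, end = ts[i], defender = defender)
        defender <- h; seg_start <- ts[i]
      }
    }
  }
  if (!is.na(defender)) {
    segs[[length(segs) + 1]] <- data.frame(
      start = seg_start, end = session_end, defender = defender)
  }
  segs <- if (length(segs)) do.call(rbind, segs) else
    data.frame(start = numeric(), end = numeric(), defender = character())
  occ <- c(A = 0, B = 0)
  for (m in c("A", "B")) {
    occ[m] <- sum(segs$end[segs$defender == m] - segs$start[segs$defender == m])
  }
  bouts <- if (length(bouts)) do.call(rbind, bouts) else
    data.frame(t = numeric(), challenger = character(), success = logical())
  win <- c(A = NA_real_, B = NA_real_)
  for (m in c("A", "B")) {
    nb <- sum(bouts$challenger == m)
    if (nb > 0) win[m] <- sum(bouts$success[bouts$challenger == m]) / nb
  }
  list(occupancy = occ, defender_timeline = segs, bouts = bouts,
       win_rate = win)
}

#' Intersection-over-union of two axis-aligned boxes
#'
#' @param a,b Boxes as `c(x1, y1, x2, y2)`.
#' @return IoU in \[0, 1\].
#' @export
box_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (union <= 0) return(0)
  inter / union
}

#' Detection precision and keypoint error
#'
#' A detection is a true positive iff its category matches the paired
#' ground truth and the box IoU exceeds the threshold (default 0.60).
#' Precision = TP / (TP + FP).  Keypoint error is the mean Euclidean
#' pixel distance between paired predicted and true positions.
#'
#' @param pred,truth Data frames with columns `category`, `x1`, `y1`,
#'   `x2`, `y2`, paired row by row.
#' @param pred_points,true_points Optional paired n x 2 keypoint
#'   matrices.
#' @param iou_threshold IoU cut (default 0.6, strict >).
#' @return List: `precision`, `tp`, `fp`, `rmse` (NA without keypoints).
#' @export
detection_eval <- function(pred, truth, pred_points = NULL,
                           true_points = NULL, iou_threshold = 0.6) {
  stopifnot(nrow(pred) == nrow(truth))
  tp <- 0L; fp <- 0L
  for (i in seq_len(nrow(pred))) {
    iou <- box_iou(as.numeric(pred[i, c("x1", "y1", "x2", "y2")]),
                   as.numeric(truth[i, c("x1", "y1", "x2", "y2")]))
    if (pred$category[i] == truth$category[i] && iou > iou_threshold) {
      tp <- tp + 1L
    } else {
      fp <- fp + 1L
    }
  }
  rmse <- NA_real_
  if (!is.null(pred_points)) {
    rmse <- mean(sqrt(rowSums((as.matrix(pred_points) -
                                 as.matrix(true_points))^2)))
  }
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       tp = tp, fp = fp, rmse = rmse)
}
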