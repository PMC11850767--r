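# Build a minimal two-mouse session from explicit node coordinates.
make_session <- function(frames_list, fps = 30) {
  n <- length(frames_list)
  co <- array(NA_real_, c(n, 2, 6, 2),
              dimnames = list(NULL, c("A", "B"),
                              c("nose", "left_ear", "right_ear", "head",
                                "body_centroid", "tail_base"),
                              c("x", "y")))
  for (f in seq_len(n)) {
    for (an in c("A", "B")) co[f, an, , ] <- frames_list[[f]][[an]]
  }
  structure(list(fps = fps, frames = n, coords = co, labels = NULL),
            class = "pose_session")
}

basic_mouse <- function(shift = c(0, 0)) {
  rbind(nose = c(0, 2), left_ear = c(-0.3, 1.2), right_ear = c(0.3, 1.2),
        head = c(0, 1), body_centroid = c(0, 0), tail_base = c(0, -1)) +
    rep(shift, each = 6)
}

test_that("feature identities hold on constructed frames", {
  fr <- list(A = basic_mouse(), B = basic_mouse(c(3, 4)))
  sess <- make_session(list(fr, fr))
  f <- compute_features(sess)
  expect_equal(ncol(f), 26)
  # collinear head: length 1 px, head-body angle 0 (same direction)
  expect_equal(unname(f[1, "head_length_A"]), 1)
  expect_equal(unname(f[1, "head_body_angle_A"]), 0)
  # 3-4-5 triangle between the noses
  expect_equal(unname(f[1, "nose_nose_distance"]), 5)
  # static frames: zero displacement, constant self lengths
  expect_equal(unname(f[, "disp_dist_A"]), c(0, 0))
  expect_equal(f[1, "body_length_B"], f[2, "body_length_B"])
  expect_error(compute_features(make_session(list(fr))), "single-frame")
  fr_bad <- fr; fr_bad$A[1, 1] <- NA
  expect_error(compute_features(make_session(list(fr_bad, fr))), "finite")
})

test_that("features are rigid-motion equivariant except the displacement angle", {
  sess <- gen_pose_session(data.frame(class = c("chase", "snatch"),
                                      duration = c(1, 1)), seed = 31)
  f0 <- compute_features(sess)
  th <- 35 * pi / 180
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sess2 <- sess
  for (an in 1:2) for (nd in 1:6) {
    sess2$coords[, an, nd, ] <- sess$coords[, an, nd, ] %*% t(Rm) +
      rep(c(40, -17), each = sess$frames)
  }
  f1 <- compute_features(sess2)
  keep <- setdiff(colnames(f0), c("disp_angle_A", "disp_angle_B"))
  expect_equal(f1[, keep], f0[, keep], tolerance = 1e-8)
  moving <- f0[, "disp_dist_A"] > 1e-6
  dshift <- (f1[moving, "disp_angle_A"] - f0[moving, "disp_angle_A"]) %% 360
  expect_equal(unname(dshift), rep(35, sum(moving)), tolerance = 1e-6)
})

test_that("clips average frames and z-score across the session", {
  withr::with_seed(2, feats <- matrix(rnorm(150 * 26), 150, 26,
                                      dimnames = list(NULL, paste0("f", 1:26))))
  cl <- make_clips(feats, fps = 30)
  expect_equal(nrow(cl$clips), 10)   # 150 frames at 30 fps -> 10 clips
  # brute-force mean oracle for clip 3
  expect_equal(cl$raw[3, ], colMeans(feats[31:45, ]))
  expect_equal(unname(colMeans(cl$clips)), rep(0, 26), tolerance = 1e-12)
  expect_equal(unname(apply(cl$clips, 2, sd)), rep(1, 26), tolerance = 1e-12)
  # degenerate constant feature -> zeros, flagged
  feats2 <- feats; feats2[, 5] <- 7
  cl2 <- make_clips(feats2, fps = 30)
  expect_equal(unname(cl2$clips[, 5]), rep(0, 10))
  expect_equal(cl2$constant, "f5")
  expect_error(make_clips(feats[1:10, ], fps = 30), "shorter")
})

test_that("motif clustering separates blobs and respects options", {
  withr::with_seed(3, {
    blob1 <- matrix(rnorm(20 * 4, 0, 0.2), 20, 4)
    blob2 <- matrix(rnorm(20 * 4, 5, 0.2), 20, 4)
  })
  clips <- rbind(blob1, blob2)
  cm <- cluster_motifs(clips, n_clusters = 2)
  expect_equal(length(unique(cm$labels[1:20])), 1)
  expect_equal(length(unique(cm$labels[21:40])), 1)
  expect_true(cm$labels[1] != cm$labels[21])
  # duplicated clips land in the same cluster
  dup <- rbind(clips, clips[1, , drop = FALSE])
  cmd <- cluster_motifs(dup, n_clusters = 2)
  expect_equal(cmd$labels[1], cmd$labels[41])
  # cutting at height 0 isolates every distinct clip
  cm0 <- cluster_motifs(clips, cut_height = 0)
  expect_equal(length(unique(cm0$labels)), 40)
  expect_error(cluster_motifs(clips, n_clusters = 99), "exceeds")
  # noise motifs are dropped
  cmn <- cluster_motifs(clips, n_clusters = 2, noise = 1L)
  expect_true(any(is.na(cmn$labels)))
  # label structure is invariant to row order (up to renaming)
  idx <- sample(40)
  cmp <- cluster_motifs(clips[idx, ], n_clusters = 2)
  agree <- table(cm$labels[idx], cmp$labels)
  expect_equal(sum(apply(agree, 1, max)), 40)
})

test_that("agglomerative clustering agrees with a brute-force oracle", {
  # O(n^3) single-linkage oracle on a small set
  withr::with_seed(9, pts <- matrix(rnorm(24 * 3), 24, 3))
  oracle_single <- function(X, k) {
    n <- nrow(X)
    D <- as.matrix(dist(X)); diag(D) <- Inf
    groups <- as.list(seq_len(n))
    while (length(groups) > k) {
      best <- c(Inf, 0, 0)
      for (i in seq_along(groups)) for (j in seq_along(groups)) {
        if (j <= i) next
        d <- min(D[groups[[i]], groups[[j]]])
        if (d < best[1]) best <- c(d, i, j)
      }
      groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
      groups[[best[3]]] <- NULL
    }
    lab <- integer(n)
    for (g in seq_along(groups)) lab[groups[[g]]] <- g
    lab
  }
  lab_o <- oracle_single(pts, 4)
  lab_h <- cluster_motifs(pts, n_clusters = 4, linkage = "single")$labels
  agree <- table(lab_o, lab_h)
  expect_equal(sum(apply(agree, 1, max)), 24)
})

test_that("motif-to-class mapping follows the preset and validates input", {
  preset <- motif_class_preset()
  out <- classify_behavior(c(17L, 2L), preset$mapping)
  expect_equal(as.character(out), c("snatch", "retreat"))
  expect_equal(length(classify_behavior(integer(), preset$mapping)), 0)
  expect_error(classify_behavior(c(17L, 99L), preset$mapping), "unmapped")
  # noise-dropped motifs (NA labels) pass through as NA
  out2 <- classify_behavior(c(NA_integer_, 18L), preset$mapping)
  expect_true(is.na(out2[1]) && out2[2] == "snatch")
})

test_that("event metrics equal a run-length oracle", {
  ev <- event_metrics(c("snatch", "snatch", "retreat", "other", "snatch"))
  expect_equal(ev$events[ev$class == "snatch"], 2)
  expect_equal(ev$total_s[ev$class == "snatch"], 1.5)
  expect_equal(ev$events[ev$class == "retreat"], 1)
  expect_equal(ev$total_s[ev$class == "retreat"], 0.5)
  expect_equal(ev$events[ev$class == "chase"], 0)
  # all-other series and reversal symmetry
  expect_equal(sum(event_metrics(rep("other", 5))$events[-1]), 0)
  withr::with_seed(6, s <- sample(c("other", "snatch", "chase", "retreat"),
                                  60, replace = TRUE))
  ev1 <- event_metrics(s); ev2 <- event_metrics(rev(s))
  expect_equal(ev1$events, ev2$events)
  expect_equal(ev1$total_s, ev2$total_s)
  # totals equal the label histogram x clip width
  expect_equal(ev1$total_s, as.numeric(table(factor(s, levels =
    c("other", "snatch", "chase", "retreat")))) * 0.5)
})

test_that("the 3-second defender rule governs possession scoring", {
  # uninterrupted hold
  o1 <- occupancy_score(data.frame(t = 0, holder = "A"), session_end = 60)
  expect_equal(o1$occupancy, c(A = 60, B = 0))
  # failed challenge: B holds < 3 s, no switch, bout logged as loss
  tl2 <- data.frame(t = c(0, 10, 12), holder = c("A", "B", "A"))
  o2 <- occupancy_score(tl2, session_end = 20)
  expect_equal(o2$occupancy, c(A = 20, B = 0))
  expect_equal(nrow(o2$bouts), 1)
  expect_false(o2$bouts$success[1])
  expect_equal(unname(o2$win_rate["B"]), 0)
  # successful challenge: B holds >= 3 s, defender switches at the take
  tl3 <- data.frame(t = c(0, 10), holder = c("A", "B"))
  o3 <- occupancy_score(tl3, session_end = 15)
  expect_equal(o3$occupancy, c(A = 10, B = 5))
  expect_true(o3$bouts$success[1])
  expect_error(occupancy_score(data.frame(t = c(5, 5),
                                          holder = c("A", "B")), 10),
               "overlapping|unordered")
})

test_that("detection metrics implement precision, IoU and pixel error", {
  expect_equal(box_iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
  boxes <- data.frame(category = c("m", "m", "m", "m"),
                      x1 = 0, y1 = 0, x2 = 2, y2 = 2)
  pred <- boxes
  pred$x1[4] <- 1; pred$y1[4] <- 1; pred$x2[4] <- 3; pred$y2[4] <- 3
  ev <- detection_eval(pred, boxes)
  expect_equal(ev$precision, 0.75)    # 3 TP, 1 FP (IoU 1/7 < 0.6)
  # category mismatch fails even with perfect overlap
  pred2 <- boxes; pred2$category[1] <- "x"
  expect_equal(detection_eval(pred2, boxes)$precision, 0.75)
  # identical predictions: precision 1, zero keypoint error
  pts <- matrix(runif(10), 5, 2)
  ev3 <- detection_eval(boxes, boxes, pred_points = pts, true_points = pts)
  expect_equal(ev3$precision, 1)
  expect_equal(ev3$rmse, 0)
  # keypoint error is the mean Euclidean distance
  ev4 <- detection_eval(boxes, boxes, pred_points = pts + 3,
                        true_points = pts)
  expect_equal(ev4$rmse, 3 * sqrt(2), tolerance = 1e-12)
})
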