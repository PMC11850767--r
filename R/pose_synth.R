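pose_nodes <- c("nose", "left_ear", "right_ear", "head",
                "body_centroid", "tail_base")

rot2 <- function(deg) {
  w <- deg2rad(deg)
  matrix(c(cos(w), sin(w), -sin(w), cos(w)), 2, 2)
}

# Place the six keypoints of one mouse from its kinematic state.
mouse_nodes <- function(p, heading_deg, bend_deg = 0, body_len = 60,
                        head_len = 18) {
  dir <- c(cos(deg2rad(heading_deg)), sin(deg2rad(heading_deg)))
  tail <- p - 0.5 * body_len * dir
  head <- p + 0.5 * body_len * dir
  hdir <- as.numeric(rot2(bend_deg) %*% dir)
  nose <- head + head_len * hdir
  earL <- head + 0.5 * head_len * as.numeric(rot2(60) %*% hdir)
  earR <- head + 0.5 * head_len * as.numeric(rot2(-60) %*% hdir)
  rbind(nose = nose, left_ear = earL, right_ear = earR, head = head,
        body_centroid = p, tail_base = tail)
}

#' Generate a scripted two-mouse pose session
#'
#' Produces 30 Hz keypoint tracks for two mice acting out a script of
#' behavior episodes.  Episode kinematics are chosen so the 26-feature
#' signatures match the field's cluster descriptions: snatch brings the
#' noses together with a strongly bent head (high head-body angle);
#' chase has both mice translating fast in file; retreat has a stretched,
#' fast, receding mouse; other is near-static.
#'
#' @param script Data frame (or list of pairs) with columns `class`
#'   (other/snatch/chase/retreat) and `duration` in seconds (> 0).
#' @param seed RNG seed. @param fps Frames per second (default 30).
#' @param jitter Keypoint jitter SD in pixels.
#' @return A `pose_session`: list with `fps`, `frames`, `coords`
#'   (array frame x animal x node x 2) and per-frame `labels`.
#' @export
gen_pose_session <- function(script, seed = 1, fps = 30, jitter = 1) {
  if (is.list(script) && !is.data.frame(script)) {
    script <- data.frame(class = vapply(script, function(s) as.character(s[[1]]), ""),
                         duration = vapply(script, function(s) as.numeric(s[[2]]), 0))
  }
  if (!nrow(script)) stop("empty script")
  if (any(script$duration <= 0)) stop("durations must be > 0")
  if (!all(script$class %in% behavior_classes)) stop("unknown behavior class in script")
  n_frames <- sum(round(script$duration * fps))
  coords <- array(NA_real_, dim = c(n_frames, 2, length(pose_nodes), 2),
                  dimnames = list(NULL, c("A", "B"), pose_nodes, c("x", "y")))
  labels <- character(n_frames)
  with_seed(seed, {
    f <- 1L
    for (s in seq_len(nrow(script))) {
      cls <- script$class[s]
      nf <- round(script$duration[s] * fps)
      centre <- c(300, 300) + stats::rnorm(2, sd = 20)
      phi <- stats::runif(1, 0, 360)
      for (i in seq_len(nf)) {
        if (cls == "other") {
          pA <- centre + c(-125, 0)
          pB <- centre + c(125, 0)
          nA <- mouse_nodes(pA, phi, bend_deg = 5, body_len = 60)
          nB <- mouse_nodes(pB, phi + 180, bend_deg = -5, body_len = 60)
        } else if (cls == "snatch") {
          gap <- 42  # nose-to-nose around 8 px given head geometry
          pA <- centre + c(-gap, 0); pB <- centre + c(gap, 0)
          nA <- mouse_nodes(pA, 0, bend_deg = 115 * sign(sin(i / 3) + 0.5),
                            body_len = 55)
          nB <- mouse_nodes(pB, 180, bend_deg = 20 * sin(i / 4), body_len = 55)
        } else if (cls == "chase") {
          step <- 15 * i
          head_turn <- 2 * i
          pB <- centre + step * c(cos(deg2rad(phi + head_turn)),
                                  sin(deg2rad(phi + head_turn)))
          pA <- pB - 85 * c(cos(deg2rad(phi + head_turn)),
                            sin(deg2rad(phi + head_turn)))
          nA <- mouse_nodes(pA, phi + head_turn, bend_deg = 10, body_len = 65)
          nB <- mouse_nodes(pB, phi + head_turn, bend_deg = 0, body_len = 65)
        } else {  # retreat: B flees from a stationary A, stretched body
          pA <- centre
          pB <- centre + c(120 + 20 * i, 0)
          nA <- mouse_nodes(pA, 0, bend_deg = 15, body_len = 60)
          nB <- mouse_nodes(pB, 0, bend_deg = 0, body_len = 80)
        }
        coords[f, "A", , ] <- nA + matrix(stats::rnorm(12, sd = jitter), 6, 2)
        coords[f, "B", , ] <- nB + matrix(stats::rnorm(12, sd = jitter), 6, 2)
        labels[f] <- cls
        f <- f + 1L
      }
    }
  })
  structure(list(fps = fps, frames = n_frames, coords = coords,
                 labels = factor(labels, levels = behavior_classes)),
            class = "pose_session")
}
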