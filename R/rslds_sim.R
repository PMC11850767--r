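#' Discrete-state transition probabilities
#'
#' The recurrent softmax transition: `p(z_t = i | z_{t-1} = j, x_{t-1})` is
#' proportional to `exp(log P[j, i] + W[i, ] %*% u + R[i, ] %*% x_prev)`.
#' With `R = W = 0` this reduces exactly to row j of the base matrix P.
#'
#' @param z_prev Previous discrete state (1..K).
#' @param x_prev Previous continuous latent (length D).
#' @param u Input vector (the analyses use all-zero input).
#' @param params An [rslds_params()] object.
#' @return A length-K probability vector summing to 1.
#' @export
transition_probs <- function(z_prev, x_prev, u, params) {
  stopifnot(inherits(params, "rslds_params"))
  row <- params$P[z_prev, ]
  if (all(row == 0)) {
    stop("zero base-transition row: probabilities undefined")
  }
  logits <- log(row) + as.numeric(params$R %*% x_prev) +
    as.numeric(params$W %*% u)
  softmax(logits)
}

#' One generative step of the rSLDS
#'
#' Applies the state-`z` dynamics to `x_prev` and emits an observation.
#' With `noise = FALSE` both the process and emission noise are switched
#' off (the Poisson emission then returns its rate).
#'
#' @param x_prev Previous latent. @param z Active discrete state.
#' @param u Input vector. @param params [rslds_params()].
#' @param noise Draw process/emission noise?
#' @return List with `x` (new latent) and `y` (emission).
#' @export
rslds_step <- function(x_prev, z, u, params, noise = TRUE) {
  A <- params$A[[z]]; b <- params$b[[z]]; V <- params$V[[z]]
  x <- as.numeric(A %*% x_prev + V %*% u + b)
  if (noise) x <- rmvnorm1(x, params$Q[[z]])
  eta <- as.numeric(params$C[[z]] %*% x + params$d[[z]] + params$F_[[z]] %*% u)
  y <- if (params$emission_kind == "poisson") {
    lam <- exp(eta)
    if (noise) stats::rpois(length(lam), lam) else lam
  } else {
    if (noise) rmvnorm1(eta, params$S[[z]]) else eta
  }
  list(x = x, y = y)
}

#' Simulate one session from an rSLDS
#'
#' Samples the discrete chain, latent trajectory and emissions, and labels
#' every bin with a behavior class through the phase rule in `cfg`
#' (see [behavior_from_phase()]).  With `noise = FALSE` the trajectory is
#' the deterministic iteration of the dynamics with argmax transitions.
#'
#' @param params [rslds_params()]. @param cfg [sim_config()].
#' @param noise Sample process/emission noise (default TRUE).
#' @return List with `latents` (list `T`, `z`, `x` D x T, `u`), `rates`
#'   (N x T emission matrix) and `truth` (ground-truth bundle: params,
#'   behavior labels, angle series and reference geometry).
#' @export
simulate_session <- function(params, cfg, noise = TRUE) {
  stopifnot(inherits(params, "rslds_params"), inherits(cfg, "sim_config"))
  if (params$D != cfg$n_latent || params$N != cfg$n_units ||
      params$K != cfg$n_states) {
    stop("params dimensions inconsistent with cfg")
  }
  for (k in seq_len(params$K)) {
    if (!is_psd(params$Q[[k]]) || !is_psd(params$S[[k]])) {
      stop("noise covariances must be symmetric PSD")
    }
  }
  T_ <- cfg$n_timesteps
  u <- rep(0, ncol(params$W))
  sim <- function() {
    z <- integer(T_); x <- matrix(0, params$D, T_)
    y <- matrix(0, params$N, T_)
    xp <- params$x0; zp <- params$z0
    for (t in seq_len(T_)) {
      pr <- transition_probs(zp, xp, u, params)
      z[t] <- if (noise) sample.int(params$K, 1, prob = pr) else which.max(pr)
      st <- rslds_step(xp, z[t], u, params, noise = noise)
      x[, t] <- st$x; y[, t] <- st$y
      xp <- st$x; zp <- z[t]
    }
    list(z = z, x = x, y = y)
  }
  out <- if (noise) with_seed(cfg$seed, sim()) else sim()
  latents <- list(T = T_, z = out$z, x = out$x,
                  u = matrix(0, ncol(params$W), T_))
  beh <- behavior_from_phase(latents, cfg$behavior_rule, params = params)
  truth <- list(params = params, latents = latents,
                behavior_labels = beh$labels, angle = beh$angle,
                attractor = beh$attractor, median = beh$median,
                direction = beh$direction)
  list(latents = latents, rates = out$y, truth = truth)
}

#' Label time bins by rotational phase
#'
#' Computes the rotation-angle series of the latent trajectory (first two
#' dimensions), exactly as [rotation_angle()] does, and assigns each bin
#' the behavior class whose interval of `rule` contains its angle.
#'
#' @param latents Latent bundle (`x` is D x T, optional `z`).
#' @param rule Named list of degree intervals partitioning \[0, 360).
#' @param attractor,median Optional 2-D reference points; when missing the
#'   median is the Weiszfeld geometric median of the trajectory and the
#'   attractor is located from the state-1 bins (needs `params` and `z`)
#'   or defaults to `median + (1, 0)`.
#' @param params Optional [rslds_params()] used to locate the state-1
#'   point attractor.
#' @return List: `labels` (factor per bin), `angle` (degrees), and the
#'   reference geometry used.
#' @export
behavior_from_phase <- function(latents, rule, attractor = NULL,
                                median = NULL, params = NULL) {
  validate_behavior_rule(rule)
  x <- latents$x
  if (nrow(x) < 2) stop("latents need >= 2 dimensions")
  pts <- t(x[1:2, , drop = FALSE])
  if (is.null(median)) median <- geometric_median(pts)
  if (is.null(attractor)) {
    z <- latents$z
    if (!is.null(params) && !is.null(z) && any(z == 1)) {
      attractor <- point_attractor(x, z, params$A[[1]])
    } else {
      attractor <- median + c(1, 0)
    }
  }
  ra <- rotation_angle(pts, attractor, median)
  iv <- do.call(rbind, rule)
  labels <- rep(NA_character_, nrow(pts))
  for (cl in names(rule)) {
    sel <- !is.na(ra$angle) & ra$angle >= rule[[cl]][1] & ra$angle < rule[[cl]][2]
    labels[sel] <- cl
  }
  list(labels = factor(labels, levels = behavior_classes),
       angle = ra$angle, attractor = attractor, median = median,
       direction = ra$direction)
}
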