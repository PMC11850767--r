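pipeline_stages <- c("simulate", "features", "units", "track_units",
                     "fit", "dynamics", "glm", "crosscorr")

#' Demo pipeline configuration
#'
#' A small, fully reproducible configuration exercising every stage on
#' synthetic data within a few minutes on one CPU.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    stages = pipeline_stages,
    sim = list(n_states = 3, n_latent = 2, n_units = 20,
               n_timesteps = 400, bin_s = 0.5),
    features = list(n_clusters = 6),
    units = list(n_example_units = 8),
    track = list(n_units = 12, drift_sd = 0.05),
    fit = list(K = 3, D = 2, max_iter = 20),
    glm = list(lambda = 0.1, train_frac = 0.8),
    crosscorr = list(n_days = 12, n_perm = 500)
  )
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the stages in dependency order -- simulate, pose features,
#' peri-event unit analysis, cross-day unit tracking, rSLDS fit,
#' dynamics metrics, state-GLM decoding, longitudinal cross-correlation
#' -- writing each stage's outputs (CSV/JSON) plus a manifest with the
#' seeds and MD5 hashes of every output.  Reruns with the same
#' configuration are bit-identical.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Output directory (created if needed).
#' @return The manifest list, invisibly written to `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  unknown <- setdiff(config$stages, pipeline_stages)
  if (length(unknown)) stop("undefined stage name: ", paste(unknown, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  env <- new.env()
  add <- function(path) outputs <<- c(outputs, path)
  need <- function(what, stage) {
    if (!exists(what, envir = env)) {
      stop("stage '", stage, "' requires output of an earlier stage ('",
           what, "' missing); run the producing stage first")
    }
    get(what, envir = env)
  }
  seed <- config$seed

  if ("simulate" %in% config$stages) {
    sc <- config$sim
    cfg <- sim_config(n_states = sc$n_states, n_latent = sc$n_latent,
                      n_units = sc$n_units, n_timesteps = sc$n_timesteps,
                      bin_s = sc$bin_s, seed = seed)
    params <- make_rotational_params(cfg)
    sess <- simulate_session(params, cfg)
    assign("cfg", cfg, env); assign("params", params, env)
    assign("sess", sess, env)
    f <- file.path(out_dir, "rates.csv")
    write_rates_csv(sess$rates, f); add(f)
    f <- file.path(out_dir, "latents.csv")
    utils::write.csv(data.frame(bin = seq_len(sess$latents$T),
                                z = sess$latents$z, t(sess$latents$x)),
                     f, row.names = FALSE); add(f)
    f <- file.path(out_dir, "behavior.csv")
    utils::write.csv(data.frame(bin = seq_len(sess$latents$T),
                                behavior = as.character(sess$truth$behavior_labels),
                                angle = sess$truth$angle),
                     f, row.names = FALSE); add(f)
    # scripted pose session mirroring the simulated behavior sequence
    r <- rle(as.character(sess$truth$behavior_labels))
    keep <- !is.na(r$values)
    script <- data.frame(class = r$values[keep],
                         duration = r$lengths[keep] * cfg$bin_s)
    pose <- gen_pose_session(script, seed = seed + 1L)
    assign("pose", pose, env)
    f <- file.path(out_dir, "pose.csv")
    write_pose_csv(pose, f); add(f)
  }

  if ("features" %in% config$stages) {
    pose <- need("pose", "features")
    feats <- compute_features(pose)
    clips <- make_clips(feats, pose$fps)
    cm <- cluster_motifs(clips$clips, n_clusters = config$features$n_clusters)
    # demo mapping: majority ground-truth label per motif
    per_clip_truth <- vapply(seq_len(nrow(clips$clips)), function(i) {
      idx <- clips$start_frame[i]:(clips$start_frame[i] + 14)
      names(which.max(table(pose$labels[idx])))
    }, "")
    mapping <- vapply(split(per_clip_truth, cm$labels),
                      function(v) names(which.max(table(v))), "")
    classes <- classify_behavior(cm$labels, mapping)
    ev <- event_metrics(classes)
    assign("clip_classes", classes, env)
    f <- file.path(out_dir, "clips.csv")
    utils::write.csv(data.frame(clip = seq_len(nrow(clips$clips)),
                                motif = cm$labels,
                                class = as.character(classes),
                                clips$clips), f, row.names = FALSE); add(f)
    f <- file.path(out_dir, "events.csv")
    utils::write.csv(ev[, c("class", "events", "total_s")], f,
                     row.names = FALSE); add(f)
  }

  if ("units" %in% config$stages) {
    sess <- need("sess", "units"); cfg <- need("cfg", "units")
    t_max <- cfg$n_timesteps * cfg$bin_s
    beh <- as.character(sess$truth$behavior_labels)
    onsets <- which(beh == "snatch" & c("", beh[-length(beh)]) != "snatch") *
      cfg$bin_s
    nu <- min(config$units$n_example_units, cfg$n_units)
    rows <- list()
    for (u in seq_len(nu)) {
      lam <- pmax(sess$rates[u, ], 0.1)
      spikes <- with_seed(seed + 100L + u, {
        unlist(lapply(seq_along(lam), function(b) {
          n <- stats::rpois(1, lam[b] * cfg$bin_s)
          sort(stats::runif(n, (b - 1) * cfg$bin_s, b * cfg$bin_s))
        }))
      })
      pr <- peri_event_z(spikes, onsets, t_max)
      rows[[u]] <- data.frame(unit = u,
                              excluded = pr$excluded,
                              mean_z = pr$mean_z %||% NA_real_,
                              p = pr$p %||% NA_real_,
                              responsive = isTRUE(pr$responsive))
    }
    f <- file.path(out_dir, "unit_responses.csv")
    utils::write.csv(do.call(rbind, rows), f, row.names = FALSE); add(f)
  }

  if ("track_units" %in% config$stages) {
    tu <- gen_unit_days(config$track$n_units, 2, config$track$drift_sd,
                        seed = seed + 2L)
    m <- match_units(tu$days[[1]], tu$days[[2]], seed = seed + 3L)
    f <- file.path(out_dir, "unit_matches.csv")
    utils::write.csv(m, f, row.names = FALSE); add(f)
    assign("matches", m, env); assign("track_truth", tu, env)
  }

  if ("fit" %in% config$stages) {
    sess <- need("sess", "fit")
    fit <- fit_rslds(sess$rates, config$fit$K, config$fit$D,
                     max_iter = config$fit$max_iter, seed = seed + 4L)
    assign("fit", fit, env)
    f <- file.path(out_dir, "fit_summary.json")
    write_report_json(list(
      K = config$fit$K, D = config$fit$D,
      elbo = max(fit$elbo_trace), iterations = length(fit$elbo_trace),
      converged = fit$converged,
      variance_explained = fit$variance_explained), f); add(f)
    f <- file.path(out_dir, "posterior.csv")
    utils::write.csv(data.frame(bin = seq_along(fit$posterior$z),
                                z = fit$posterior$z, t(fit$posterior$x)),
                     f, row.names = FALSE); add(f)
  }

  if ("dynamics" %in% config$stages) {
    fit <- need("fit", "dynamics"); sess <- need("sess", "dynamics")
    rep_ <- dynamics_report(fit, behavior = sess$truth$behavior_labels)
    f <- file.path(out_dir, "dynamics_report.json")
    write_report_json(rep_, f); add(f)
    assign("dyn", rep_, env)
  }

  if ("glm" %in% config$stages) {
    fit <- need("fit", "glm"); sess <- need("sess", "glm")
    pose <- need("pose", "glm")
    feats <- compute_features(pose)
    clips <- make_clips(feats, pose$fps)
    nb <- min(ncol(fit$posterior$x), nrow(clips$raw))
    zsc <- function(v) if (stats::sd(v) == 0) v * 0 else (v - mean(v)) / stats::sd(v)
    cues <- cbind(apply(t(fit$posterior$x[, seq_len(nb), drop = FALSE]),
                        2, zsc),
                  distance = zsc(clips$raw[seq_len(nb), "nose_nose_distance"]),
                  facing = zsc(clips$raw[seq_len(nb), "nose_nose_angle"]))
    colnames(cues) <- c(paste0("Dim", seq_len(nrow(fit$posterior$x))),
                        "distance", "facing_angle")
    beh <- sess$truth$behavior_labels[seq_len(nb)]
    z <- fit$posterior$z[seq_len(nb)]
    ok <- !is.na(beh)
    cues <- cues[ok, , drop = FALSE]; beh <- beh[ok]; z <- z[ok]
    ntr <- floor(config$glm$train_frac * length(z))
    tr <- seq_len(ntr); te <- (ntr + 1):length(z)
    gfit <- fit_state_glm(cues[tr, ], beh[tr], z[tr],
                          lambda = config$glm$lambda)
    ch <- chance_model(beh[tr], test = beh[te])
    dec <- decode_behavior(cues[te, ], z[te], gfit, behaviors = beh[te],
                           chance = ch)
    f <- file.path(out_dir, "glm_report.json")
    write_report_json(list(
      loglik = gfit$loglik, accuracy = dec$accuracy,
      chance_accuracy = dec$chance_accuracy,
      chance_prob = as.list(ch$prob),
      filters = lapply(gfit$filters, function(m) as.data.frame(m))), f)
    add(f)
  }

  if ("crosscorr" %in% config$stages) {
    cc_cfg <- config$crosscorr
    sc <- config$sim
    vel2 <- numeric(cc_cfg$n_days); snatch_s <- numeric(cc_cfg$n_days)
    for (d in seq_len(cc_cfg$n_days)) {
      cfg_d <- sim_config(n_states = sc$n_states, n_latent = sc$n_latent,
                          n_units = sc$n_units, n_timesteps = 150,
                          bin_s = sc$bin_s, seed = seed + 500L + d)
      # slow daily drift of the rotational speed drives both series
      par_d <- make_rotational_params(cfg_d,
                                      omega_deg = c(10 + 2 * d, 20))
      s_d <- simulate_session(par_d, cfg_d)
      vel2[d] <- dynamic_velocity(par_d, s_d$latents$x, s_d$latents$z)[2]
      snatch_s[d] <- sum(s_d$truth$behavior_labels == "snatch",
                         na.rm = TRUE) * sc$bin_s
    }
    cc <- cross_correlation(vel2, snatch_s)
    pt <- xcorr_permutation_test(vel2, snatch_s, n = cc_cfg$n_perm,
                                 seed = seed + 6L)
    f <- file.path(out_dir, "crosscorr.json")
    write_report_json(list(r = cc, optimal_lag = optimal_lag(cc),
                           p = pt$p), f); add(f)
  }

  manifest <- list(
    package = "competedyn",
    version = as.character(utils::packageVersion("competedyn")),
    seed = seed, stages = config$stages,
    config = config,
    outputs = lapply(outputs, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    }))
  write_report_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

#' Dynamics report of a fitted session
#'
#' Bundles the post-fit metrics: PCA transform, normalized dynamic
#' velocities, transition matrix and dwell times, per-state attractor
#' scores, rotation-angle series and (optionally) per-behavior angle
#' ECDF 50% points.
#'
#' @param fit An `rslds_fit`. @param behavior Optional behavior labels.
#' @return List of metrics (JSON-serializable).
#' @export
dynamics_report <- function(fit, behavior = NULL) {
  p <- fit$params
  x <- fit$posterior$x; z <- fit$posterior$z
  pca <- pca_transform(x, p$C[[1]])
  vel <- dynamic_velocity(p, x, z)
  ts <- transition_stats(z, K = p$K,
                         boundaries = which(diff(fit$seg) != 0))
  att <- lapply(seq_len(p$K), function(k) {
    a <- attractor_scores(p$A[[k]])
    list(stability = a$stability, line_score = a$line_score,
         tau = a$tau)
  })
  pts <- t(pca$x2[1:2, , drop = FALSE])
  med <- geometric_median(pts)
  proj <- function(v) as.numeric(pca$transform %*% (v - pca$center))
  attp <- if (any(z == 1)) point_attractor(x, z, p$A[[1]], project = proj)
          else med + c(1, 0)
  ra <- rotation_angle(pts, attp, med)
  out <- list(
    dynamic_velocity = as.list(vel),
    transition_matrix = as.data.frame(ts$matrix),
    self_transition = as.list(stats::setNames(ts$self,
                                              paste0("state", seq_len(p$K)))),
    mean_dwell_bins = lapply(ts$dwell, mean),
    attractor = att,
    pc_variance_frac = pca$var_frac,
    rotation_direction = ra$direction)
  if (!is.null(behavior)) {
    ec <- angle_behavior_ecdf(ra$angle, behavior)
    out$angle_p50 <- lapply(ec, function(e) e$p50)
  }
  out
}
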