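test_that("rotational parameters have the designed spectral structure", {
  cfg <- sim_config(n_states = 3, n_latent = 2, n_units = 10,
                    n_timesteps = 100, seed = 1)
  p <- make_rotational_params(cfg)
  # state 2 block is exactly rho * rotation(omega)
  expect_equal(p$A[[2]], rotation_block(10, 0.98), tolerance = 1e-12)
  # state 1 is a point attractor: all eigenvalue magnitudes < 1
  expect_true(all(Mod(eigen(p$A[[1]])$values) < 1))
  # emission matrix has full column rank
  expect_equal(qr(p$C[[1]])$rank, 2)
  # deterministic under the seed
  p2 <- make_rotational_params(cfg)
  expect_identical(p, p2)
  # no rotation plane in 1-D
  expect_error(sim_config(n_latent = 1), "n_latent")
})

test_that("line-attractor parameters realize requested eigenvalues", {
  cfg <- sim_config(n_states = 3, n_latent = 2, n_units = 10,
                    n_timesteps = 100, seed = 2)
  p <- make_line_attractor_params(cfg, line_state = 3,
                                  line_eigs = c(0.999, 0.8))
  mags <- sort(Mod(eigen(p$A[[3]])$values), decreasing = TRUE)
  expect_equal(mags, c(0.999, 0.8), tolerance = 1e-9)
  expect_gt(attractor_scores(p$A[[3]])$line_score, 1)
  # an equal-magnitude conjugate pair scores zero
  expect_equal(attractor_scores(p$A[[2]])$line_score, 0, tolerance = 1e-9)
})

test_that("noise-free simulation equals deterministic iteration of the model", {
  cfg <- sim_config(n_states = 3, n_latent = 2, n_units = 8,
                    n_timesteps = 40, seed = 3)
  p <- make_rotational_params(cfg)
  s <- simulate_session(p, cfg, noise = FALSE)
  # independent oracle: literal iteration with argmax transitions
  x <- p$x0; z <- p$z0
  for (t in seq_len(cfg$n_timesteps)) {
    pr <- log(p$P[z, ]) + as.numeric(p$R %*% x)
    z <- which.max(pr)
    x <- as.numeric(p$A[[z]] %*% x + p$b[[z]])
    expect_equal(s$latents$z[t], z)
    expect_equal(s$latents$x[, t], x, tolerance = 1e-12)
    expect_equal(s$rates[, t],
                 as.numeric(p$C[[z]] %*% x + p$d[[z]]), tolerance = 1e-12)
  }
})

test_that("simulation is reproducible and validates noise covariances", {
  cfg <- sim_config(n_latent = 2, n_units = 6, n_timesteps = 60, seed = 4)
  p <- make_rotational_params(cfg)
  s1 <- simulate_session(p, cfg)
  s2 <- simulate_session(p, cfg)
  expect_identical(s1$latents$z, s2$latents$z)
  expect_identical(s1$rates, s2$rates)
  p_bad <- p
  p_bad$Q[[1]] <- matrix(c(1, 2, 2, 1), 2, 2)  # indefinite
  expect_error(simulate_session(p_bad, cfg), "PSD")
})

test_that("noise-free rotational run advances phase monotonically", {
  cfg <- sim_config(n_states = 2, n_latent = 2, n_units = 5,
                    n_timesteps = 60, seed = 5)
  # single effective regime: both states share the same pure rotation
  p <- make_rotational_params(cfg)
  p$A[[1]] <- rotation_block(10, 1); p$b[[1]] <- c(0, 0)
  p$A[[2]] <- rotation_block(10, 1); p$b[[2]] <- c(0, 0)
  s <- simulate_session(p, cfg, noise = FALSE)
  ph <- atan2(s$latents$x[2, ], s$latents$x[1, ]) * 180 / pi
  dph <- diff(ph) %% 360
  expect_equal(dph, rep(10, length(dph)), tolerance = 1e-8)
})

test_that("poisson emissions are counts with the exp-link mean", {
  cfg <- sim_config(n_latent = 2, n_units = 5, n_timesteps = 5000,
                    seed = 6, emission_kind = "poisson")
  p <- make_rotational_params(cfg)
  # mild intensities for a stable mean check
  p$d <- rep(list(rep(1, 5)), 3)
  p$C <- rep(list(matrix(0.3, 5, 2)), 3)
  s <- simulate_session(p, cfg)
  expect_true(all(s$rates >= 0))
  expect_true(all(s$rates == round(s$rates)))
  lam <- exp(p$C[[1]] %*% s$latents$x + p$d[[1]])
  for (u in 1:5) {
    se <- sqrt(mean(lam[u, ])) / sqrt(ncol(lam))
    expect_lt(abs(mean(s$rates[u, ]) - mean(lam[u, ])), 3 * se + 0.05)
  }
})

test_that("behavior_from_phase labels bins by their angular sector", {
  # constructed latents at known angles around median (0,0), attractor (1,0)
  ang <- c(10, 100, 200, 300)
  x <- rbind(cos(ang * pi / 180), sin(ang * pi / 180))
  latents <- list(x = x)
  rule <- list(snatch = c(0, 180), retreat = c(180, 360))
  out <- behavior_from_phase(latents, rule, attractor = c(1, 0),
                             median = c(0, 0))
  expect_equal(as.character(out$labels),
               c("snatch", "snatch", "retreat", "retreat"))
  # an all-other rule labels everything other
  out2 <- behavior_from_phase(latents, list(other = c(0, 360)),
                              attractor = c(1, 0), median = c(0, 0))
  expect_true(all(out2$labels == "other"))
  # rules that do not partition [0, 360) are rejected
  expect_error(behavior_from_phase(latents, list(snatch = c(0, 100))),
               "partition")
  # pure function of the angle series: permuting bins permutes labels
  idx <- c(3, 1, 4, 2)
  outp <- behavior_from_phase(list(x = x[, idx]), rule,
                              attractor = c(1, 0), median = c(0, 0))
  expect_equal(as.character(outp$labels), as.character(out$labels)[idx])
})

test_that("scripted pose sessions carry the intended feature signatures", {
  sess <- gen_pose_session(data.frame(
    class = c("snatch", "retreat", "other"),
    duration = c(2, 2, 1)), seed = 11)
  expect_equal(sess$frames, 150)
  f <- compute_features(sess)
  nn <- f[, "nose_nose_distance"]
  expect_lt(median(nn[sess$labels == "snatch"]),
            median(nn[sess$labels == "retreat"]))
  # retreat: stretched, fast
  expect_gt(median(f[sess$labels == "retreat", "body_length_B"]),
            median(f[sess$labels == "snatch", "body_length_B"]))
  expect_gt(median(f[sess$labels == "retreat", "disp_dist_B"]),
            median(f[sess$labels == "other", "disp_dist_B"]))
  # static episode without jitter: no displacement
  still <- gen_pose_session(data.frame(class = "other", duration = 1),
                            seed = 1, jitter = 0)
  fs <- compute_features(still)
  expect_equal(max(fs[, c("disp_dist_A", "disp_dist_B")]), 0)
  # reproducibility and input validation
  expect_identical(gen_pose_session(list(list("snatch", 1)), seed = 2)$coords,
                   gen_pose_session(list(list("snatch", 1)), seed = 2)$coords)
  expect_error(gen_pose_session(data.frame(class = character(),
                                           duration = numeric())), "empty")
})

test_that("unit-day generator produces matched and distractor units", {
  gu <- gen_unit_days(n_units = 4, n_days = 2, drift_sd = 0, seed = 21)
  d1 <- gu$days[[1]]; d2 <- gu$days[[2]]
  # zero drift: identical waveforms across days -> similarity exactly 1
  for (i in 1:4) {
    expect_equal(waveform_similarity(d1[[i]]$waveform, d2[[i]]$waveform)$w, 1)
    # identical ISIH parameters both days -> score 0
    sc <- isih_score(d1[[i]]$isih_true, d2[[i]]$isih_true, rep(1, 8))
    expect_equal(sc$I, 0)
  }
  # every later-day unit maps to at most one earlier unit
  im <- gu$identity_map
  expect_true(all(table(im$true_id, im$day) <= 1))
  expect_gt(length(d2), length(d1))  # distractors added on day 2
  # heavy drift destroys cross-day similarity
  gu2 <- gen_unit_days(n_units = 12, n_days = 2, drift_sd = 0.6, seed = 22)
  w <- vapply(1:12, function(i) {
    waveform_similarity(gu2$days[[1]][[i]]$waveform,
                        gu2$days[[2]][[i]]$waveform)$w
  }, 0)
  expect_lt(median(w), 0.81)
})
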