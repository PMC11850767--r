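test_that("geometric median solves the Fermat point problem", {
  expect_equal(geometric_median(rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))),
               c(0, 0), tolerance = 1e-7)
  expect_equal(geometric_median(rbind(c(3, 4))), c(3, 4))
  # grid-search oracle on random points
  withr::with_seed(7, {
    pts <- matrix(rnorm(40), 20, 2)
  })
  m <- geometric_median(pts)
  obj <- function(p) sum(sqrt(rowSums(sweep(pts, 2, p)^2)))
  g <- as.matrix(expand.grid(seq(-1, 1, length.out = 400),
                             seq(-1, 1, length.out = 400)))
  grid_min <- min(sqrt(outer(g[, 1], pts[, 1], "-")^2 +
                         outer(g[, 2], pts[, 2], "-")^2) %*% rep(1, 20))
  expect_lt(obj(m), grid_min + 1e-4)
  # coincidence guard: median of an odd collinear set is the middle point
  expect_equal(geometric_median(rbind(c(0, 0), c(1, 0), c(2, 0))),
               c(1, 0), tolerance = 1e-6)
})

test_that("point attractor is the visited state-1 point minimizing ||A1 x||", {
  x <- cbind(c(1, 0), c(0.1, 0), c(2, 2))
  z <- c(1, 1, 2)
  expect_equal(point_attractor(x, z, diag(2)), c(0.1, 0))
  # A1 = 0: all norms tie at zero; earliest state-1 bin wins
  expect_equal(point_attractor(x, z, matrix(0, 2, 2)), c(1, 0))
  expect_error(point_attractor(x, c(2, 2, 2), diag(2)), "never visited")
  # exhaustive-scan oracle on a random toy
  withr::with_seed(3, {
    xr <- matrix(rnorm(20), 2, 10)
    A1 <- matrix(rnorm(4), 2, 2)
  })
  zr <- rep(1, 10)
  norms <- apply(xr, 2, function(v) sqrt(sum((A1 %*% v)^2)))
  expect_equal(point_attractor(xr, zr, A1), xr[, which.min(norms)])
})

test_that("rotation angle follows the dot/cross-product construction", {
  med <- c(0, 0); att <- c(1, 0)
  # counterclockwise trajectory context
  traj <- t(sapply(seq(0, 350, by = 10), function(a) {
    c(cos(a * pi / 180), sin(a * pi / 180))
  }))
  ra <- rotation_angle(traj, att, med)
  expect_equal(ra$direction, 1)
  expect_equal(ra$angle, seq(0, 350, by = 10), tolerance = 1e-8)
  # the worked cases: (0,1) -> 90, (0,-1) -> 270, collinear (2,0) -> 0
  pts <- rbind(c(0, 1), c(0, -1), c(2, 0))
  ra2 <- rotation_angle(pts, att, med, direction = 1)
  expect_equal(ra2$angle, c(90, 270, 0), tolerance = 1e-8)
  # clockwise trajectory flips the adjustment
  ra3 <- rotation_angle(rbind(c(0, 1)), att, med, direction = -1)
  expect_equal(ra3$angle, 270)
  # degenerate: point at the median is masked; equal references error
  expect_true(is.na(rotation_angle(rbind(c(0, 0)), att, med,
                                   direction = 1)$angle))
  expect_error(rotation_angle(traj, med, med), "differ")
})

test_that("noise-free rotation advances the angle by the generating step", {
  x <- matrix(0, 2, 100); x[, 1] <- c(1, 0)
  Rm <- rotation_block(7, 1)
  for (t in 2:100) x[, t] <- Rm %*% x[, t - 1]
  ra <- rotation_angle(t(x), c(1, 0), c(0, 0))
  steps <- diff(ra$angle) %% 360
  expect_equal(steps, rep(7, 99), tolerance = 1e-6)
})

test_that("dynamic velocity matches the per-bin norm average and normalizes to state 1", {
  cfg <- sim_config(n_latent = 2, n_units = 5, n_timesteps = 50, seed = 2)
  p <- make_rotational_params(cfg)
  # closed-form check: A = 0.9 I, all ||x|| = 2 -> raw velocity 1.8
  p$A[[2]] <- diag(0.9, 2)
  x <- rbind(c(2, 0, -2, 0), c(0, 2, 0, -2))
  z <- rep(2, 4)
  zz <- c(1, z); xx <- cbind(c(1, 1), x)  # one state-1 bin for normalization
  v <- dynamic_velocity(p, xx, zz, normalize = FALSE)
  expect_equal(unname(v[2]), 1.8, tolerance = 1e-12)
  # A = 0 gives zero velocity
  p$A[[3]] <- matrix(0, 2, 2)
  v0 <- dynamic_velocity(p, cbind(xx, c(1, 2)), c(zz, 3), normalize = FALSE)
  expect_equal(unname(v0[3]), 0)
  # brute-force oracle on a random toy + state-1 normalization
  withr::with_seed(5, {
    xr <- matrix(rnorm(200), 2, 100)
    zr <- sample(1:3, 100, replace = TRUE)
  })
  vr <- dynamic_velocity(p, xr, zr)
  expect_equal(unname(vr[1]), 1)
  brute <- sapply(1:3, function(k) {
    mean(apply(xr[, zr == k, drop = FALSE], 2,
               function(v) sqrt(sum((p$A[[k]] %*% v)^2))))
  })
  expect_equal(unname(vr), brute / brute[1], tolerance = 1e-10)
  expect_error(dynamic_velocity(p, xr, rep(2, 100)), "state 1")
})

test_that("attractor scores agree with closed-form time constants", {
  s <- attractor_scores(diag(c(0.5, 0.1)))
  expect_equal(s$stability, 1 / abs(log(0.5)), tolerance = 1e-12)
  expect_equal(s$stability, 1.442695, tolerance = 1e-6)
  s2 <- attractor_scores(diag(c(0.99, 0.9)))
  expect_equal(s2$tau, c(1 / abs(log(0.99)), 1 / abs(log(0.9))),
               tolerance = 1e-9)
  expect_equal(s2$line_score, log2((1 / abs(log(0.99))) / (1 / abs(log(0.9)))),
               tolerance = 1e-12)
  expect_equal(s2$line_score, 3.39, tolerance = 1e-2)
  # complex-conjugate pair: equal magnitudes, zero line score
  expect_equal(attractor_scores(rotation_block(30, 0.95))$line_score, 0,
               tolerance = 1e-9)
  # unit eigenvalue -> infinite time constant, flagged
  s3 <- attractor_scores(diag(c(1, 0.5)))
  expect_true(is.infinite(s3$stability) && s3$flag)
  # zero eigenvalue -> zero time constant
  expect_equal(min(attractor_scores(diag(c(0, 0.5)))$tau), 0)
})

test_that("transition statistics count runs and normalize visited rows", {
  ts <- transition_stats(c(1, 1, 2, 2, 2, 3), K = 3)
  expect_equal(ts$matrix[1, ], c(0.5, 0.5, 0))
  expect_equal(ts$matrix[2, ], c(0, 2 / 3, 1 / 3))
  expect_true(all(is.na(ts$matrix[3, ])))  # state 3 never left
  expect_equal(ts$dwell[[2]], 3)
  cz <- transition_stats(rep(2, 10), K = 2)
  expect_equal(cz$self[2], 1)
  expect_equal(cz$dwell[[2]], 10)
  # rows of visited states sum to 1
  withr::with_seed(8, zr <- sample(1:3, 500, replace = TRUE))
  tr <- transition_stats(zr, K = 3)
  expect_equal(unname(rowSums(tr$matrix)), rep(1, 3))
  # boundaries are excluded from counts
  tb <- transition_stats(c(1, 1, 2, 2), K = 2, boundaries = 2)
  expect_equal(tb$counts[1, 2], 0)
})

test_that("a Markov chain's transition matrix is recovered from its path", {
  P <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, 2, byrow = TRUE)
  T_ <- 50000
  withr::with_seed(4, {
    z <- integer(T_); z[1] <- 1
    for (t in 2:T_) z[t] <- sample(1:2, 1, prob = P[z[t - 1], ])
  })
  ts <- transition_stats(z, K = 2)
  for (j in 1:2) {
    n_j <- sum(ts$counts[j, ])
    for (k in 1:2) {
      se <- sqrt(P[j, k] * (1 - P[j, k]) / n_j)
      expect_lt(abs(ts$matrix[j, k] - P[j, k]), 3 * se)
    }
  }
})

test_that("quartile levels bin a ladder and respect tie conventions", {
  q <- quartile_levels(1:8)
  expect_equal(as.character(q),
               c("DV1", "DV1", "DV2", "DV2", "DV3", "DV3", "DV4", "DV4"))
  expect_true(all(quartile_levels(rep(5, 6)) == "DV1"))
  cc <- quartile_levels(1:8, scheme = "C")
  expect_equal(as.character(cc),
               c("C4", "C4", "C3", "C3", "C2", "C2", "C1", "C1"))
  expect_error(quartile_levels(1:3), ">= 4")
})

test_that("PCA transform whitens, orders variance, and preserves dynamics", {
  withr::with_seed(11, {
    D <- 3; N <- 12; T_ <- 400
    A <- diag(0.9, D); A[1:2, 1:2] <- rotation_block(12, 0.98)
    x <- matrix(0, D, T_); x[, 1] <- c(1, 0, 0.5)
    for (t in 2:T_) x[, t] <- A %*% x[, t - 1]   # noise-free trajectory
    C <- matrix(rnorm(N * D), N, D)
  })
  pca <- pca_transform(x, C)
  # whitened latents have identity covariance
  wx <- pca$W_white %*% sweep(x, 1, rowMeans(x))
  expect_equal(cov(t(wx)), diag(D), tolerance = 1e-6)
  # component variances are sorted descending
  v <- apply(pca$x2, 1, var)
  expect_true(all(diff(v) <= 1e-8))
  expect_equal(pca$var_frac, v / sum(v), tolerance = 1e-12)
  # transform commutes with the dynamics: mapping the trajectory then
  # iterating the transformed dynamics equals mapping the next point
  Tm <- pca$transform
  A2 <- Tm %*% A %*% solve(Tm)
  lhs <- Tm %*% (x[, 2:10] - pca$center)
  rhs <- A2 %*% (Tm %*% (x[, 1:9] - pca$center)) +
    as.numeric(Tm %*% (A %*% pca$center - pca$center))
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("flow fields reflect each state's dynamics geometry", {
  cfg <- sim_config(n_latent = 2, n_units = 10, n_timesteps = 300, seed = 9)
  p <- make_rotational_params(cfg)
  s <- simulate_session(p, cfg)
  pca <- pca_transform(s$latents$x, p$C[[1]])
  grid <- as.matrix(expand.grid(seq(-1, 1, 0.5), seq(-1, 1, 0.5)))
  ff <- flow_field(p, pca, grid)
  # identity dynamics -> zero field
  p0 <- p; p0$A[[2]] <- diag(2); p0$b[[2]] <- c(0, 0)
  ff0 <- flow_field(p0, pca, grid)
  expect_equal(max(abs(ff0[[2]][, c("dx", "dy")])), 0, tolerance = 1e-10)
  # rotation state: constant curl sign around the cycle (skip centre rows)
  away <- rowSums(grid^2) > 0.4
  curl_sign <- sign(grid[away, 1] * ff[[2]][away, "dy"] -
                      grid[away, 2] * ff[[2]][away, "dx"])
  expect_true(length(unique(curl_sign[curl_sign != 0])) == 1)
  # pure contraction state: vectors shrink the distance to the fixed point
  pc <- p; pc$A[[1]] <- diag(0.5, 2); pc$b[[1]] <- c(0, 0)
  ffc <- flow_field(pc, pca, grid)
  d0 <- sqrt(rowSums((grid - matrix(rep(pca$transform %*% (c(0, 0) - pca$center),
                                        each = nrow(grid)), ncol = 2))^2))
  nxt <- grid + ffc[[1]][, c("dx", "dy")]
  d1 <- sqrt(rowSums((nxt - matrix(rep(pca$transform %*% (c(0, 0) - pca$center),
                                       each = nrow(grid)), ncol = 2))^2))
  expect_true(all(d1 <= d0 + 1e-10))
})

test_that("angle ECDF 50% points summarize per-class angle distributions", {
  ec <- angle_behavior_ecdf(rep(120, 10), rep("chase", 10))
  expect_equal(ec$chase$p50, 120)
  withr::with_seed(12, a <- runif(4000, 0, 360))
  ecu <- angle_behavior_ecdf(a, rep("other", 4000))
  expect_lt(abs(ecu$other$p50 - 180), 10)
  # construction: snatch in [0, 180) sits below retreat in [180, 360)
  ang <- c(runif(200, 0, 180), runif(200, 180, 360))
  lab <- rep(c("snatch", "retreat"), each = 200)
  ec2 <- angle_behavior_ecdf(ang, lab)
  expect_lt(ec2$snatch$p50, ec2$retreat$p50)
})

test_that("sequentiality index separates ridges from shuffled activity", {
  T_ <- 80; n <- 12
  ridge <- t(sapply(seq_len(n), function(i) {
    mu <- i * T_ / n
    exp(-0.5 * ((seq_len(T_) - mu) / 2)^2)
  }))
  si <- sequentiality_index(ridge, n_shuffle = 200, seed = 3)
  expect_gt(si$index, quantile(si$null, 0.99))
  # i.i.d. noise is within the central mass of its own null
  withr::with_seed(5, noise <- matrix(rnorm(n * T_), n, T_))
  sn <- sequentiality_index(noise, n_shuffle = 200, seed = 4)
  expect_gt(sn$index, quantile(sn$null, 0.005))
  expect_lt(sn$index, quantile(sn$null, 0.995))
  # invariant to unit (row) permutation
  si2 <- sequentiality_index(ridge[n:1, ], n_shuffle = 2, seed = 1)
  expect_equal(si2$index, si$index)
  expect_error(sequentiality_index(ridge[1:3, ]), ">= 5")
})
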