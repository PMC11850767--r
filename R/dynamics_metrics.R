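#' Geometric median (Weiszfeld algorithm)
#'
#' Iterates the Weiszfeld fixed point to tolerance 1e-8 (max 1000
#' iterations).  If an iterate lands exactly on a data point, that point is
#' returned when it minimizes the objective (the classical coincidence
#' guard).
#'
#' @param points n x 2 matrix of points.
#' @param tol,max_iter Convergence controls.
#' @return Length-2 numeric vector.
#' @export
geometric_median <- function(points, tol = 1e-8, max_iter = 1000) {
  points <- as.matrix(points)
  if (nrow(points) == 0) stop("need >= 1 point")
  if (nrow(points) == 1) return(as.numeric(points[1, ]))
  obj <- function(m) sum(sqrt(rowSums(sweep(points, 2, m)^2)))
  m <- colMeans(points)
  for (i in seq_len(max_iter)) {
    d <- sqrt(rowSums(sweep(points, 2, m)^2))
    hit <- which(d < 1e-12)
    if (length(hit)) {
      # iterate coincides with a data point: accept if it is the minimizer
      cand <- points[hit[1], ]
      others <- d >= 1e-12
      if (!any(others)) return(as.numeric(cand))
      g <- colSums(sweep(points[others, , drop = FALSE], 2, cand) /
                     d[others])
      if (sqrt(sum(g^2)) <= length(hit)) return(as.numeric(cand))
      # move off the data point along the descent direction
      m <- cand + 1e-8 * g / sqrt(sum(g^2))
      next
    }
    w <- 1 / d
    m_new <- colSums(points * w) / sum(w)
    if (sqrt(sum((m_new - m)^2)) < tol) return(as.numeric(m_new))
    m <- m_new
  }
  as.numeric(m)
}

#' State-1 point attractor
#'
#' The visited state-1 latent point with the lowest `||A1 x_t||`
#' (earliest bin on ties), returned in the first two latent dimensions
#' (or mapped through `project` when supplied).
#'
#' @param x D x T latent matrix. @param z Discrete-state series.
#' @param A1 State-1 dynamics matrix.
#' @param project Optional function mapping a latent vector to 2-D
#'   coordinates (e.g. a fitted PCA transform).
#' @return Length-2 numeric vector.
#' @export
point_attractor <- function(x, z, A1, project = NULL) {
  idx <- which(z == 1)
  if (!length(idx)) stop("state 1 never visited")
  norms <- vapply(idx, function(t) sqrt(sum((A1 %*% x[, t])^2)), 0)
  best <- idx[which.min(norms)]  # which.min takes the earliest tie
  xt <- x[, best]
  if (is.null(project)) as.numeric(xt[1:2]) else as.numeric(project(xt))[1:2]
}

#' Rotation-angle series
#'
#' For each trajectory point, the angle between `u = attractor - median`
#' and `v = point - median` (via the dot product, in degrees), adjusted by
#' the 2-D cross-product sign: when the per-bin sign matches the
#' trajectory's global rotation direction the raw angle is kept, otherwise
#' `360 - angle` is used, so the series advances with the rotation.
#'
#' @param points T x 2 trajectory in the PC (or latent) plane.
#' @param attractor,median Length-2 reference points (must differ).
#' @param direction Optional +1 (counterclockwise) or -1 (clockwise);
#'   by default the sign of the mean signed angular increment of `v`.
#' @return List: `angle` (degrees in \[0, 360), NA where the point
#'   coincides with the median) and `direction`.
#' @export
rotation_angle <- function(points, attractor, median, direction = NULL) {
  points <- as.matrix(points)
  u <- attractor - median
  if (sqrt(sum(u^2)) < 1e-12) stop("median must differ from the attractor")
  v <- sweep(points, 2, median)
  nv <- sqrt(rowSums(v^2))
  if (is.null(direction)) {
    phase <- atan2(v[, 2], v[, 1])
    dph <- diff(phase)
    dph <- (dph + pi) %% (2 * pi) - pi   # wrap to (-pi, pi]
    direction <- if (length(dph) && sum(dph) < 0) -1 else 1
  }
  nu <- sqrt(sum(u^2))
  cosang <- clamp((v %*% u) / (nu * pmax(nv, 1e-300)), -1, 1)
  theta <- rad2deg(acos(cosang))
  cross <- u[1] * v[, 2] - u[2] * v[, 1]
  flip <- cross * direction < 0
  theta[flip] <- 360 - theta[flip]
  theta <- as.numeric(theta) %% 360
  theta[nv < 1e-12] <- NA_real_
  list(angle = theta, direction = direction)
}

#' Per-state dynamic velocity
#'
#' `V_z = mean over bins in state z of ||A_z x_t||`, the literal average
#' norm of the state's dynamics map applied to the visited latents,
#' reported relative to state 1 when `normalize = TRUE`.  An alternate
#' displacement reading `||(A_z - I) x_t + b_z||` is available for
#' sensitivity analysis.
#'
#' @param params [rslds_params()]. @param x D x T latents. @param z states.
#' @param normalize Divide by state 1's value (default TRUE).
#' @param mode `"literal"` (default) or `"displacement"`.
#' @return Named numeric vector of length K; `NA` for unvisited states.
#' @export
dynamic_velocity <- function(params, x, z, normalize = TRUE,
                             mode = c("literal", "displacement")) {
  mode <- match.arg(mode)
  K <- params$K
  V <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    idx <- which(z == k)
    if (!length(idx)) next
    A <- params$A[[k]]
    nrm <- vapply(idx, function(t) {
      if (mode == "literal") sqrt(sum((A %*% x[, t])^2))
      else sqrt(sum(((A - diag(params$D)) %*% x[, t] + params$b[[k]])^2))
    }, 0)
    V[k] <- mean(nrm)
  }
  names(V) <- paste0("state", seq_len(K))
  if (normalize) {
    if (is.na(V[1])) stop("state 1 never visited; cannot normalize")
    V <- V / V[1]
  }
  V
}

#' Attractor time constants and scores
#'
#' From the eigenvalues of a state's dynamics matrix: per-mode time
#' constants `tau = |1 / log(|lambda|)|`, the stability score (largest
#' tau), and the line-attractor score `log2(tau_max / tau_second)` --
#' near zero for an equal-magnitude (e.g. complex-conjugate) leading pair
#' and greater than one for a line attractor.
#'
#' @param A_z Square dynamics matrix.
#' @return List: `eigenvalues`, `tau`, `stability`, `line_score`,
#'   `flag` (TRUE when a unit-magnitude eigenvalue made tau infinite).
#' @export
attractor_scores <- function(A_z) {
  stopifnot(nrow(A_z) == ncol(A_z))
  lam <- eigen(A_z, only.values = TRUE)$values
  mag <- abs(lam)
  tau <- ifelse(mag == 0, 0, abs(1 / log(mag)))
  tau[mag == 1] <- Inf
  ord <- order(tau, decreasing = TRUE)
  tau_s <- tau[ord]
  line <- if (length(tau_s) >= 2) log2(tau_s[1] / tau_s[2]) else NA_real_
  list(eigenvalues = lam[ord], tau = tau_s, stability = tau_s[1],
       line_score = line, flag = any(mag == 1))
}

#' Empirical transition statistics of a discrete-state series
#'
#' Counts `z_t -> z_{t+1}` transitions (excluding trial boundaries),
#' normalizes rows of visited states, and collects per-state dwell times
#' (run lengths in bins).
#'
#' @param z Integer state series. @param K Number of states.
#' @param boundaries Optional indices t such that the step t -> t+1
#'   crosses a trial boundary and is excluded from the counts.
#' @return List: `matrix` (K x K, NA rows for states never left),
#'   `counts`, `self` (self-transition probabilities), `dwell` (list of
#'   per-state run lengths), `unvisited`.
#' @export
transition_stats <- function(z, K = max(z), boundaries = integer()) {
  T_ <- length(z)
  if (T_ < 2) stop("need a series of length >= 2")
  cnt <- matrix(0, K, K)
  for (t in seq_len(T_ - 1)) {
    if (t %in% boundaries) next
    cnt[z[t], z[t + 1]] <- cnt[z[t], z[t + 1]] + 1
  }
  rs <- rowSums(cnt)
  mat <- cnt / ifelse(rs > 0, rs, NA)
  r <- rle(z)
  dwell <- lapply(seq_len(K), function(k) r$lengths[r$values == k])
  list(matrix = mat, counts = cnt, self = diag(mat), dwell = dwell,
       unvisited = which(tabulate(z, K) == 0))
}

#' Quartile level labels
#'
#' Bins values into quartiles: DV labels ascend with the value (DV1 low)
#' and C labels descend (C1 high).  Ties spanning a boundary fall in the
#' lower bin; all-equal inputs are all DV1/C4.
#'
#' @param values Numeric vector (>= 4 values).
#' @param scheme `"DV"` (ascending) or `"C"` (descending).
#' @return Factor of labels.
#' @export
quartile_levels <- function(values, scheme = c("DV", "C")) {
  scheme <- match.arg(scheme)
  if (length(values) < 4) stop("need >= 4 values")
  qs <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  bin <- 1L + vapply(values, function(v) sum(v > qs), 0L)
  lab <- if (scheme == "DV") paste0("DV", bin) else paste0("C", 5L - bin)
  lv <- if (scheme == "DV") paste0("DV", 1:4) else paste0("C", 4:1)
  factor(lab, levels = lv)
}

#' Angle ECDF per behavior class
#'
#' Empirical cumulative distribution of the rotation angle for the bins of
#' each class, and the 50% point (smallest angle with ECDF >= 0.5).
#'
#' @param angle Angle series in degrees. @param labels Class per bin.
#' @return List per class: `ecdf` function, `p50`, `n`.
#' @export
angle_behavior_ecdf <- function(angle, labels) {
  labels <- as.character(labels)
  keep <- !is.na(angle) & !is.na(labels)
  out <- list()
  for (cl in unique(labels[keep])) {
    a <- sort(angle[keep & labels == cl])
    Fn <- stats::ecdf(a)
    p50 <- a[which(Fn(a) >= 0.5)[1]]
    out[[cl]] <- list(ecdf = Fn, p50 = p50, n = length(a))
  }
  out
}

#' PCA transform of a fitted latent space
#'
#' Latent states are only identified up to linear maps, so the fitted
#' space is rotated into ordered principal coordinates: whiten the latents
#' (`W`), map the emission to `C' = C W^-1`, take its SVD `C' = U S V^T`,
#' and form `x'' = S V^T W x`.  The emission in the new coordinates is the
#' orthonormal `U`, so component variances are ordered by the singular
#' values (PC1 largest).
#'
#' @param x D x T latent matrix (posterior means of a fit).
#' @param C N x D emission matrix of the fit.
#' @return Object of class `pca2d`: `W_white`, `P` (= S V^T), `transform`
#'   (= P W), `x2` (transformed latents, D x T), `var_frac` (descending),
#'   `U` (new emission matrix).
#' @export
pca_transform <- function(x, C) {
  D <- nrow(x)
  cv <- stats::cov(t(x))
  ei <- eigen(cv, symmetric = TRUE)
  vals <- pmax(ei$values, 1e-12)
  W <- diag(1 / sqrt(vals), D) %*% t(ei$vectors)
  Winv <- ei$vectors %*% diag(sqrt(vals), D)
  Cp <- C %*% Winv
  if (qr(Cp)$rank < D) warning("rank-deficient emission; using pseudo-inverse geometry")
  sv <- svd(Cp)
  P <- diag(sv$d, D) %*% t(sv$v)
  Tm <- P %*% W
  x2 <- Tm %*% sweep(x, 1, rowMeans(x))
  v <- apply(x2, 1, stats::var)
  structure(list(W_white = W, P = P, transform = Tm, center = rowMeans(x),
                 x2 = x2, var_frac = v / sum(v), U = sv$u),
            class = "pca2d")
}

#' Per-state flow field on the PC plane
#'
#' Displacement of each state's dynamics map at grid points of the first
#' two principal coordinates (remaining coordinates held at 0).
#'
#' @param params [rslds_params()]. @param pca A [pca_transform()] result.
#' @param grid Two-column matrix of PC1/PC2 grid points.
#' @return List per state of matrices `cbind(grid, dx, dy)`.
#' @export
flow_field <- function(params, pca, grid) {
  grid <- as.matrix(grid)
  D <- params$D
  Tm <- pca$transform; Tinv <- solve(Tm)
  lapply(seq_len(params$K), function(k) {
    A <- params$A[[k]]; b <- params$b[[k]]
    out <- t(apply(grid, 1, function(g) {
      x2 <- c(g, rep(0, D - 2))
      x <- as.numeric(Tinv %*% x2) + pca$center
      nx <- as.numeric(A %*% x + b)
      n2 <- as.numeric(Tm %*% (nx - pca$center))
      n2[1:2] - g
    }))
    cbind(grid, dx = out[, 1], dy = out[, 2])
  })
}

#' Sequentiality index of a population rate matrix
#'
#' A descriptive scalar for ridge-like sequential activation: the
#' normalized entropy of the units' peak-time distribution plus the mean
#' log ridge-to-background rate ratio.  The null distribution is the same
#' statistic on per-unit independent circular time shifts and on
#' size-matched i.i.d. Gaussian matrices.  This definition is one
#' reasonable operationalization; it is not canonical.
#'
#' @param rates Units x time matrix (>= 5 units).
#' @param n_shuffle Circular-shift null draws (default 1000).
#' @param n_bins Histogram bins for the peak-time entropy.
#' @param ridge_frac Half-width of the ridge window as a fraction of T.
#' @param seed RNG seed for the null.
#' @return List: `index`, `null` (shift null), `null_gauss`, `p`
#'   (upper-tail vs shift null).
#' @export
sequentiality_index <- function(rates, n_shuffle = 1000, n_bins = 10,
                                ridge_frac = 0.05, seed = 1) {
  rates <- as.matrix(rates)
  n <- nrow(rates); T_ <- ncol(rates)
  if (n < 5) stop("need >= 5 units")
  stat <- function(m) {
    peaks <- apply(m, 1, which.max)
    h <- tabulate(pmin(n_bins, 1L + floor((peaks - 1) / T_ * n_bins)), n_bins)
    p <- h / sum(h)
    ent <- -sum(ifelse(p > 0, p * log(p), 0)) / log(n_bins)
    w <- max(1L, round(ridge_frac * T_))
    rr <- vapply(seq_len(n), function(i) {
      idx <- ((peaks[i] - w):(peaks[i] + w) - 1) %% T_ + 1
      ridge <- mean(m[i, idx])
      bg <- mean(m[i, -idx])
      log(max(ridge, 1e-12) / max(bg, 1e-12))
    }, 0)
    ent + mean(rr)
  }
  idx <- stat(rates)
  with_seed(seed, {
    null <- vapply(seq_len(n_shuffle), function(s) {
      m <- t(vapply(seq_len(n), function(i) {
        k <- sample.int(T_, 1)
        rates[i, c(seq(k, T_), seq_len(k - 1))]
      }, numeric(T_)))
      stat(m)
    }, 0)
    null_g <- vapply(seq_len(min(n_shuffle, 200)), function(s) {
      stat(matrix(stats::rnorm(n * T_), n, T_))
    }, 0)
    p <- (1 + sum(null >= idx)) / (n_shuffle + 1)
    list(index = idx, null = null, null_gauss = null_g, p = p)
  })
}
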