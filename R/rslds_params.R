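#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generator: model sizes, the
#' 500 ms binning convention, the emission family, and the rule coupling
#' rotational phase to behavior classes.
#'
#' @param n_states Number of discrete states K (>= 2).
#' @param n_latent Continuous latent dimension D (>= 2; the first two
#'   dimensions carry the rotation plane).
#' @param n_units Number of observed units N.
#' @param n_timesteps Number of time bins T.
#' @param bin_s Bin width in seconds (default 0.5, i.e. 500 ms bins).
#' @param seed Integer seed; every generator draw is reproducible under it.
#' @param emission_kind `"gaussian"` (rates, the default) or `"poisson"`
#'   (counts via an exponential link).
#' @param behavior_rule Named list mapping behavior classes to angular
#'   intervals `c(lo, hi)` in degrees that must partition \[0, 360).
#'   Classes must come from `other`, `snatch`, `chase`, `retreat`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_states = 3, n_latent = 6, n_units = 30,
                       n_timesteps = 1000, bin_s = 0.5, seed = 1,
                       emission_kind = c("gaussian", "poisson"),
                       behavior_rule = default_behavior_rule()) {
  emission_kind <- match.arg(emission_kind)
  if (n_states < 2) stop("n_states must be >= 2")
  if (n_latent < 2) stop("n_latent must be >= 2 (no rotation plane otherwise)")
  if (bin_s <= 0) stop("bin_s must be > 0")
  validate_behavior_rule(behavior_rule)
  structure(list(
    n_states = as.integer(n_states), n_latent = as.integer(n_latent),
    n_units = as.integer(n_units), n_timesteps = as.integer(n_timesteps),
    bin_s = bin_s, seed = as.integer(seed), emission_kind = emission_kind,
    behavior_rule = behavior_rule
  ), class = "sim_config")
}

#' Default phase-to-behavior rule
#'
#' Four equal 90-degree sectors in the order other, snatch, chase, retreat.
#' @return Named list of `c(lo, hi)` degree intervals.
#' @export
default_behavior_rule <- function() {
  list(other  = c(0, 90),  snatch  = c(90, 180),
       chase  = c(180, 270), retreat = c(270, 360))
}

behavior_classes <- c("other", "snatch", "chase", "retreat")

validate_behavior_rule <- function(rule) {
  if (!length(rule) || is.null(names(rule))) {
    stop("behavior_rule must be a named list of angular intervals")
  }
  if (!all(names(rule) %in% behavior_classes)) {
    stop("behavior_rule classes must be among: ",
         paste(behavior_classes, collapse = ", "))
  }
  iv <- do.call(rbind, rule)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  ok <- iv[1, 1] == 0 && iv[nrow(iv), 2] == 360 &&
    (nrow(iv) == 1 || all(abs(iv[-1, 1] - iv[-nrow(iv), 2]) < 1e-12))
  if (!ok) stop("behavior_rule intervals must partition [0, 360)")
  invisible(rule)
}

#' rSLDS parameter container
#'
#' Holds every parameter of the generative model: the row-stochastic base
#' transition matrix P, recurrent weights R (and input weights W), and the
#' per-state dynamics (A_k, b_k, V_k, Q_k) and emission (C_k, d_k, F_k,
#' S_k) parameters.  The discrete state at time t follows a softmax over
#' `log P[j, ] + W x u + R x x_{t-1}`; the continuous latent follows
#' `x_t = A_k x_{t-1} + V_k u_t + b_k + w_t`; the observation is an affine
#' map of x_t (Gaussian) or its exponential (Poisson counts).
#'
#' @param K,D,N Numbers of discrete states, latent dims, observed units.
#' @param P K x K row-stochastic base transition matrix.
#' @param R K x D recurrent weights (row i weights state i's logit).
#' @param W K x M input weights (all zero here; no external input is used).
#' @param A,b,V,Q Lists of per-state dynamics parameters.
#' @param C,d,F_,S Lists of per-state emission parameters.
#' @param emission_kind `"gaussian"` or `"poisson"`.
#' @param x0 Initial latent (length D). @param z0 Initial discrete state.
#' @return Object of class `rslds_params`.
#' @export
rslds_params <- function(K, D, N, P, R, W, A, b, V, Q, C, d, F_, S,
                         emission_kind = "gaussian",
                         x0 = rep(0, D), z0 = 1L) {
  p <- structure(list(K = as.integer(K), D = as.integer(D), N = as.integer(N),
                      P = P, R = R, W = W, A = A, b = b, V = V, Q = Q,
                      C = C, d = d, F_ = F_, S = S,
                      emission_kind = emission_kind,
                      x0 = x0, z0 = as.integer(z0)), class = "rslds_params")
  validate_rslds_params(p)
  p
}

validate_rslds_params <- function(p) {
  stopifnot(p$K >= 1, p$D >= 1, p$N >= 1)
  if (!all(dim(p$P) == c(p$K, p$K))) stop("P must be K x K")
  if (any(p$P < 0) || any(abs(rowSums(p$P) - 1) > 1e-8)) {
    stop("P rows must be nonnegative and sum to 1")
  }
  if (!all(dim(p$R) == c(p$K, p$D))) stop("R must be K x D")
  for (k in seq_len(p$K)) {
    if (!all(dim(p$A[[k]]) == c(p$D, p$D))) stop("A_k must be D x D")
    if (length(p$b[[k]]) != p$D) stop("b_k must have length D")
    if (!is_psd(p$Q[[k]])) stop("process noise covariance Q_k must be symmetric PSD")
    if (!all(dim(p$C[[k]]) == c(p$N, p$D))) stop("C_k must be N x D")
    if (length(p$d[[k]]) != p$N) stop("d_k must have length N")
    if (!is_psd(p$S[[k]])) stop("emission noise covariance S_k must be symmetric PSD")
  }
  invisible(p)
}

#' Rotational rSLDS parameters
#'
#' Constructs a generative model whose state 1 is a point attractor (all
#' dynamics eigenvalues inside the unit circle) and whose remaining states
#' embed a 2-D rotation block (complex-conjugate eigenvalues of magnitude
#' `rho`) in the first two latent dimensions; any extra dimensions contract.
#' The recurrent weights partition the rotation plane into K angular
#' sectors so the discrete state tracks rotational phase.
#'
#' @param cfg A [sim_config()].
#' @param rho Rotation eigenvalue magnitude (default 0.98).
#' @param omega_deg Per-state rotation step in degrees for states
#'   2..K (recycled; default 10 for state 2, then +10 per state).
#' @param kappa Recurrent-weight gain; larger values make the discrete
#'   state a sharper function of phase.
#' @param process_sd,emission_sd Noise scales.
#' @return An [rslds_params()] object.
#' @export
make_rotational_params <- function(cfg, rho = 0.98, omega_deg = NULL,
                                   kappa = 20, process_sd = 0.1,
                                   emission_sd = 0.1) {
  stopifnot(inherits(cfg, "sim_config"))
  K <- cfg$n_states; D <- cfg$n_latent; N <- cfg$n_units
  if (D < 2) stop("n_latent must be >= 2 (no rotation plane)")
  if (is.null(omega_deg)) omega_deg <- c(10, 22, 10 * (3 + seq_len(max(0, K - 3))))[seq_len(K - 1)]
  omega_deg <- rep_len(omega_deg, K - 1)

  with_seed(cfg$seed, {
    A <- vector("list", K); b <- vector("list", K)
    # state 1: a damped spiral -- a point attractor (all |eigenvalue| < 1)
    # whose phase still advances, so the trajectory sweeps on through its
    # sector instead of being trapped at the fixed point
    centers <- (360 / K) * (seq_len(K) - 1) - 90  # state 1 centered at -90 deg
    A1 <- diag(0.6, D)
    A1[1:2, 1:2] <- rotation_block(4, 0.93)
    A[[1]] <- A1
    # distinct fixed points per state: each state orbits (or spirals
    # into) its own centre, displaced toward its sector
    centre_of <- function(k, r = 0.25) {
      ck <- rep(0, D)
      ck[1:2] <- r * c(cos(deg2rad(centers[k])), sin(deg2rad(centers[k])))
      ck
    }
    b[[1]] <- as.numeric((diag(D) - A[[1]]) %*% centre_of(1, 0.15))
    for (k in 2:K) {
      Ak <- diag(0.8, D)
      Ak[1:2, 1:2] <- rotation_block(omega_deg[k - 1], rho)
      A[[k]] <- Ak
      b[[k]] <- as.numeric((diag(D) - Ak) %*% centre_of(k))
    }
    # recurrent phase partition: logit of state k peaks in its sector
    R <- matrix(0, K, D)
    for (k in seq_len(K)) {
      R[k, 1:2] <- kappa * c(cos(deg2rad(centers[k])), sin(deg2rad(centers[k])))
    }
    P <- matrix(0.2 / (K - 1), K, K); diag(P) <- 0.8
    Q <- rep(list(diag(process_sd^2, D)), K)
    C1 <- matrix(stats::rnorm(N * D, sd = 1 / sqrt(D)), N, D)
    if (qr(C1)$rank < D) stop("emission matrix is column-rank deficient")
    d1 <- stats::runif(N, 2, 8)
    Cl <- rep(list(C1), K); dl <- rep(list(d1), K)
    S <- rep(list(diag(emission_sd^2, N)), K)
    x0 <- rep(0, D); x0[1] <- 0.7
    rslds_params(K, D, N, P, R, W = matrix(0, K, 1), A, b,
                 V = rep(list(matrix(0, D, 1)), K), Q,
                 Cl, dl, F_ = rep(list(matrix(0, N, 1)), K), S,
                 emission_kind = cfg$emission_kind, x0 = x0, z0 = 2L)
  })
}

#' Line-attractor rSLDS parameters
#'
#' Like [make_rotational_params()], but one designated state's dynamics
#' matrix is built (by orthogonal similarity transform) to have exactly one
#' eigenvalue magnitude >= 0.995 with all others <= 0.9, so its
#' line-attractor score ([attractor_scores()]) exceeds 1.
#'
#' @param cfg A [sim_config()].
#' @param line_state Which state carries the line attractor (default 3).
#' @param line_eigs Requested eigenvalues; default `c(0.999, 0.85, ...)`.
#' @param ... Passed to [make_rotational_params()] for the other states.
#' @return An [rslds_params()] object.
#' @export
make_line_attractor_params <- function(cfg, line_state = min(3L, cfg$n_states),
                                       line_eigs = NULL, ...) {
  stopifnot(inherits(cfg, "sim_config"))
  D <- cfg$n_latent
  if (D < 2) stop("n_latent must be >= 2")
  if (is.null(line_eigs)) line_eigs <- c(0.999, rep(0.85, D - 1))
  stopifnot(length(line_eigs) == D)
  if (sum(abs(line_eigs) >= 0.995) != 1 || any(abs(line_eigs[-which.max(abs(line_eigs))]) > 0.9)) {
    stop("line_eigs must have exactly one magnitude >= 0.995, others <= 0.9")
  }
  p <- make_rotational_params(cfg, ...)
  with_seed(cfg$seed + 1L, {
    M <- matrix(stats::rnorm(D * D), D, D)
    O <- qr.Q(qr(M))  # random orthogonal basis
    p$A[[line_state]] <- O %*% diag(line_eigs, D) %*% t(O)
    p$b[[line_state]] <- rep(0, D)
  })
  p
}
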