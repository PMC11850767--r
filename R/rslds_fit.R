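# Structured mean-field EM for the recurrent switching linear dynamical
# system.  q(x) is a Gaussian Markov chain updated by block-tridiagonal
# message passing (a Kalman smoother in information form, with per-bin
# dynamics averaged under q(z)); q(z) is updated by forward-backward with
# transition logits evaluated at the posterior latent means; M-steps are
# closed-form weighted least squares for dynamics/emissions and a softmax
# regression for the transition parameters.

# ---- Gaussian chain smoother ------------------------------------------

# gamma: T x K soft assignments; seg: integer segment id per bin (dynamics
# factors only act within a segment).  Returns posterior means, marginal
# covariances, lag-1 cross-covariances and log det of the chain precision.
gauss_chain_smoother <- function(Y, gamma, params, seg, prior_var = 100) {
  D <- params$D; K <- params$K
  out <- cpp_chain_smoother(Y, gamma,
                            array(unlist(params$A), c(D, D, K)),
                            vapply(params$b, identity, numeric(D)),
                            array(unlist(params$Q), c(D, D, K)),
                            params$C[[1]], params$d[[1]],
                            diag(params$S[[1]]), as.integer(seg),
                            prior_var)
  if (D == 1) {
    out$mu <- matrix(out$mu, 1)
    dim(out$Sigma) <- c(1, 1, length(seg))
    dim(out$Cross) <- c(1, 1, length(seg))
  }
  out
}

# Expected dynamics quadratic forms, per bin and state: the building block
# of both the z-update potentials and the ELBO dynamics term.
dyn_quad <- function(post, params, seg) {
  D <- params$D; K <- params$K
  cpp_dyn_quad(post$mu, post$Sigma, post$Cross,
               array(unlist(params$A), c(D, D, K)),
               vapply(params$b, identity, numeric(D)),
               array(unlist(params$Q), c(D, D, K)), as.integer(seg))
}

# Transition log-probability cube: ltr[j, k, t] = log p(z_t = k |
# z_{t-1} = j, xbar_{t-1}); NaN slices at segment starts.
trans_logprob <- function(L, Rw, mu, seg) {
  cpp_trans_logprob(L, Rw, mu, as.integer(seg))
}

# Forward-backward over the discrete chain given per-bin log potentials
# and transition cubes; segments are independent chains.
hmm_forward_backward <- function(lphi, ltr, seg) {
  cpp_hmm_fb(lphi, ltr, as.integer(seg))
}

# Softmax-regression M-step for base transition logits L and recurrent
# weights Rw given expected transition counts xi and latent means.
fit_transitions <- function(xi, mu, seg, L0, Rw0, ridge = 1e-6,
                            maxit = 100) {
  K <- nrow(L0); D <- nrow(mu)
  T_ <- ncol(mu)
  ok <- which(c(FALSE, seg[-1] == seg[-T_]))
  Xprev <- t(mu[, ok - 1, drop = FALSE])          # n x D
  # xi is K x K x T; flatten to per-source-state weight matrices
  Wj <- lapply(seq_len(K), function(j) {
    m <- matrix(xi[j, , ok], nrow = K)            # K x n
    t(m)                                          # n x K
  })
  pack <- function(L, Rw) c(as.numeric(L), as.numeric(Rw))
  unpack <- function(th) list(L = matrix(th[seq_len(K * K)], K, K),
                              Rw = matrix(th[-seq_len(K * K)], K, D))
  rowmax <- function(M) do.call(pmax, lapply(seq_len(ncol(M)), function(i) M[, i]))
  nll <- function(th) {
    p <- unpack(th)
    Rx <- Xprev %*% t(p$Rw)                       # n x K
    val <- 0
    for (j in seq_len(K)) {
      Eta <- sweep(Rx, 2, p$L[j, ], "+")
      m <- rowmax(Eta)
      lseK <- m + log(rowSums(exp(Eta - m)))
      W <- Wj[[j]]
      val <- val + sum(W * Eta) - sum(rowSums(W) * lseK)
    }
    -(val - ridge * sum(th^2))
  }
  grad <- function(th) {
    p <- unpack(th)
    Rx <- Xprev %*% t(p$Rw)
    gL <- matrix(0, K, K); gR <- matrix(0, K, D)
    for (j in seq_len(K)) {
      Eta <- sweep(Rx, 2, p$L[j, ], "+")
      m <- rowmax(Eta)
      Pr <- exp(Eta - m); Pr <- Pr / rowSums(Pr)
      Res <- Wj[[j]] - rowSums(Wj[[j]]) * Pr
      gL[j, ] <- colSums(Res)
      gR <- gR + t(Res) %*% Xprev
    }
    -(c(as.numeric(gL), as.numeric(gR)) - 2 * ridge * th)
  }
  opt <- stats::optim(pack(L0, Rw0), nll, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  unpack(opt$par)
}

# ---- main fit ----------------------------------------------------------

#' Fit an rSLDS to binned population rates
#'
#' Structured mean-field EM: the continuous-latent posterior is a
#' Gaussian Markov chain (block-tridiagonal smoother), the discrete
#' posterior comes from forward-backward with recurrent transition
#' logits evaluated at the latent means, and M-steps are closed-form
#' weighted regressions (dynamics, tied diagonal-noise emission) plus a
#' softmax regression for the transition parameters.  Initialization is
#' PCA on the rates for the latents and k-means over local dynamics for
#' the discrete states; the fit is deterministic under `seed`.  States
#' are reordered by descending occupancy after fitting.
#'
#' @param rates N x T matrix of binned firing rates (Gaussian emissions),
#'   or a list of such matrices (trials; truncated to the shortest and
#'   concatenated, with no dynamics factors across trial boundaries).
#' @param K,D Numbers of discrete states and latent dimensions.
#' @param max_iter,tol EM iteration cap and relative ELBO tolerance.
#' @param seed Seed for the k-means initialization.
#' @param verbose Print per-iteration ELBO?
#' @return Object of class `rslds_fit`: `params`, `posterior` (`gamma`,
#'   `z`, `x`, `Sigma`), `elbo_trace`, `converged`, `variance_explained`,
#'   `seg`.
#' @export
fit_rslds <- function(rates, K, D, max_iter = 50, tol = 1e-6, seed = 1,
                      n_init = 3, verbose = FALSE) {
  if (is.list(rates)) {
    Tmin <- min(vapply(rates, ncol, 0L))
    seg <- rep(seq_along(rates), each = Tmin)
    Y <- do.call(cbind, lapply(rates, function(m) m[, seq_len(Tmin), drop = FALSE]))
  } else {
    Y <- as.matrix(rates)
    seg <- rep(1L, ncol(Y))
  }
  if (any(!is.finite(Y))) stop("rates must be finite")
  if (ncol(Y) < 10 * (D + K)) stop("need T >= 10 * (D + K) bins")
  fit <- fit_rslds_seg(Y, seg, K, D, max_iter = max_iter, tol = tol,
                       seed = seed, n_init = n_init, verbose = verbose)
  fit$variance_explained <- variance_explained(fit, Y)
  if (!fit$converged) warning("rSLDS EM reached max_iter without converging")
  fit
}

# Initial parameters: per-state least squares on the PCA latents under
# the k-means segmentation; tied emission from regressing Y on x0.
init_params_from <- function(Y, x0, gamma, K, D, seg) {
  N <- nrow(Y); T_ <- ncol(Y)
  Xaug <- rbind(x0, 1)
  CD <- Y %*% t(Xaug) %*% solve(Xaug %*% t(Xaug) + diag(1e-8, D + 1))
  C <- CD[, seq_len(D), drop = FALSE]; d <- CD[, D + 1]
  resid <- Y - CD %*% Xaug
  S <- diag(pmax(rowMeans(resid^2), 1e-4), N)
  A <- vector("list", K); b <- vector("list", K); Q <- vector("list", K)
  for (k in seq_len(K)) {
    w <- gamma[, k]
    ok <- which(c(FALSE, seg[-1] == seg[-T_]))
    Xp <- rbind(x0[, ok - 1, drop = FALSE], 1)
    Xc <- x0[, ok, drop = FALSE]
    ww <- w[ok]
    Sxx <- (Xp * rep(ww, each = D + 1)) %*% t(Xp) + diag(1e-6, D + 1)
    Syx <- (Xc * rep(ww, each = D)) %*% t(Xp)
    AB <- Syx %*% solve(Sxx)
    A[[k]] <- AB[, seq_len(D), drop = FALSE]
    b[[k]] <- AB[, D + 1]
    r <- Xc - AB %*% Xp
    Q[[k]] <- diag(pmax(colSums(t(r^2) * ww) / max(sum(ww), 1), 1e-4), D)
  }
  P <- if (K == 1) matrix(1, 1, 1) else {
    m <- matrix(0.1 / (K - 1), K, K); diag(m) <- 0.9; m
  }
  rslds_params(K, D, N, P, R = matrix(0, K, D), W = matrix(0, K, 1),
               A, b, V = rep(list(matrix(0, D, 1)), K), Q,
               C = rep(list(C), K), d = rep(list(d), K),
               F_ = rep(list(matrix(0, N, 1)), K),
               S = rep(list(S), K))
}

m_step <- function(Y, post, fb, params, seg) {
  K <- params$K; D <- params$D; N <- params$N; T_ <- ncol(Y)
  mu <- post$mu; gamma <- fb$gamma
  # dynamics, per state
  ss <- cpp_dyn_suffstats(mu, post$Sigma, post$Cross, gamma,
                          as.integer(seg))
  dim(ss$Sxx) <- c(D + 1, D + 1, K)
  dim(ss$Syx) <- c(D, D + 1, K)
  dim(ss$Syy) <- c(D, D, K)
  nk <- as.numeric(ss$nk)
  for (k in seq_len(K)) {
    if (nk[k] < D + 2) next   # starved state: keep previous parameters
    Syxk <- matrix(ss$Syx[, , k], D, D + 1)
    AB <- Syxk %*% solve(ss$Sxx[, , k] + diag(1e-8, D + 1))
    Qk <- (matrix(ss$Syy[, , k], D, D) - AB %*% t(Syxk)) / nk[k]
    Qk <- (Qk + t(Qk)) / 2 + diag(1e-8, D)
    if (all(eigen(Qk, symmetric = TRUE, only.values = TRUE)$values > 0)) {
      params$A[[k]] <- AB[, seq_len(D), drop = FALSE]
      params$b[[k]] <- AB[, D + 1]
      params$Q[[k]] <- Qk
    }
  }
  # tied emission with diagonal noise
  Sig_sum <- rowSums(post$Sigma, dims = 2)
  SxxE <- rbind(cbind(Sig_sum + tcrossprod(mu), rowSums(mu)),
                c(rowSums(mu), T_))
  SyxE <- cbind(Y %*% t(mu), rowSums(Y))
  CD <- SyxE %*% solve(SxxE + diag(1e-8, D + 1))
  svar <- (rowSums(Y^2) - rowSums(CD * SyxE)) / T_
  C <- CD[, seq_len(D), drop = FALSE]; d <- CD[, D + 1]
  S <- diag(pmax(svar, 1e-6), N)
  params$C <- rep(list(C), K); params$d <- rep(list(d), K)
  params$S <- rep(list(S), K)
  # transitions
  if (K > 1) {
    tp <- fit_transitions(fb$xi, mu, seg, log(params$P), params$R)
    params$P <- exp(t(apply(tp$L, 1, log_softmax)))
    params$R <- tp$Rw
  }
  params
}

rslds_elbo <- function(Y, post, fb, lphi, ltr, params, seg) {
  T_ <- ncol(Y); N <- params$N; D <- params$D; K <- params$K
  mu <- post$mu
  C <- params$C[[1]]; d <- params$d[[1]]
  sdiag <- diag(params$S[[1]])
  R <- Y - C %*% mu - d
  Sig_sum <- rowSums(post$Sigma, dims = 2)
  CtSinvC <- t(C / sdiag) %*% C
  ll_em <- -0.5 * sum(sweep(R^2, 1, sdiag, "/")) -
    0.5 * sum(CtSinvC * Sig_sum) -
    0.5 * T_ * (N * log(2 * pi) + sum(log(sdiag)))
  first <- c(TRUE, seg[-1] != seg[-T_])
  ll_dyn <- 0
  ll_tr <- 0
  for (t in 2:T_) {
    if (first[t]) next
    ll_dyn <- ll_dyn + sum(fb$gamma[t, ] * lphi[t, ])
    ll_tr <- ll_tr + sum(fb$xi[, , t] * ltr[, , t])
  }
  prior_var <- 100
  ll_x1 <- 0
  for (t in which(first)) {
    ll_x1 <- ll_x1 - 0.5 * (D * log(2 * pi * prior_var) +
                              (sum(diag(post$Sigma[, , t])) +
                                 sum(mu[, t]^2)) / prior_var)
    ll_tr <- ll_tr - log(K)   # uniform initial state
  }
  H_x <- 0.5 * (T_ * D * (1 + log(2 * pi)) - post$logdetJ)
  ll_em + ll_dyn + ll_tr + ll_x1 + H_x + fb$entropy
}

# Canonical state order: descending occupancy.
reorder_states <- function(fit) {
  occ <- colSums(fit$posterior$gamma)
  ord <- order(occ, decreasing = TRUE)
  if (all(ord == seq_along(ord))) return(fit)
  p <- fit$params
  p$P <- p$P[ord, ord, drop = FALSE]
  p$R <- p$R[ord, , drop = FALSE]
  p$W <- p$W[ord, , drop = FALSE]
  for (f in c("A", "b", "V", "Q", "C", "d", "F_", "S")) p[[f]] <- p[[f]][ord]
  fit$params <- p
  fit$posterior$gamma <- fit$posterior$gamma[, ord, drop = FALSE]
  fit$posterior$z <- match(fit$posterior$z, ord)
  fit
}

#' Fraction of rate variance explained by a fit
#'
#' `1 - SSE / SST` where the reconstruction uses the posterior-mean
#' latents through the fitted emission and SST is about per-unit means;
#' clamped below at 0.
#'
#' @param fit An `rslds_fit`. @param rates The fitted rate matrix.
#' @return Fraction in \[0, 1\].
#' @export
variance_explained <- function(fit, rates) {
  Y <- as.matrix(rates)
  sst <- sum(sweep(Y, 1, rowMeans(Y))^2)
  if (sst == 0) stop("zero-variance rates")
  recon <- fit$params$C[[1]] %*% fit$posterior$x + fit$params$d[[1]]
  sse <- sum((Y - recon)^2)
  max(0, 1 - sse / sst)
}

#' Model selection over (K, D) grids
#'
#' Five-fold cross-validated held-out ELBO (contiguous time folds; the
#' training folds enter as separate trials) and BIC
#' `k ln(n) - 2 ln Lhat` with `k` the free-parameter count and `n` the
#' number of observed scalars.  Returns the grid table and the
#' CV-ELBO argmax.
#'
#' @param rates N x T rate matrix.
#' @param K_grid,D_grid Candidate numbers of states / latent dims.
#' @param folds Number of contiguous folds (default 5).
#' @param max_iter,seed Passed to [fit_rslds()].
#' @return List: `table` (K, D, cv_elbo, bic), `best` (named c(K, D)).
#' @export
select_rslds <- function(rates, K_grid, D_grid, folds = 5, max_iter = 15,
                         seed = 1) {
  if (!length(K_grid) || !length(D_grid)) stop("empty hyperparameter grid")
  Y <- as.matrix(rates)
  T_ <- ncol(Y)
  bnd <- floor(seq(0, T_, length.out = folds + 1))
  if (min(diff(bnd)) < 10) stop("fold too short")
  rows <- list()
  for (K in K_grid) for (D in D_grid) {
    cv <- numeric(folds)
    for (f in seq_len(folds)) {
      test_idx <- (bnd[f] + 1):bnd[f + 1]
      train <- list()
      if (bnd[f] >= 1) train <- c(train, list(Y[, 1:bnd[f], drop = FALSE]))
      if (bnd[f + 1] < T_) train <- c(train, list(Y[, (bnd[f + 1] + 1):T_, drop = FALSE]))
      # trials are truncated to the shortest; for fold evaluation keep
      # blocks separate without truncation instead
      fit <- fit_rslds_blocks(train, K, D, max_iter = max_iter, seed = seed)
      cv[f] <- heldout_elbo(fit$params, Y[, test_idx, drop = FALSE])
    }
    full <- fit_rslds(Y, K, D, max_iter = max_iter, seed = seed)
    n_par <- K * (D^2 + D + D * (D + 1) / 2) + nrow(Y) * (D + 2) +
      K * K + K * D
    bic <- n_par * log(length(Y)) - 2 * max(full$elbo_trace)
    rows[[length(rows) + 1]] <- data.frame(
      K = K, D = D, cv_elbo = mean(cv), bic = bic)
  }
  tab <- do.call(rbind, rows)
  best <- tab[which.max(tab$cv_elbo), ]
  list(table = tab, best = c(K = best$K, D = best$D))
}

# Fit on a list of unequal-length blocks (no truncation): used by CV.
fit_rslds_blocks <- function(blocks, K, D, max_iter = 15, seed = 1) {
  seg <- rep(seq_along(blocks), vapply(blocks, ncol, 0L))
  Y <- do.call(cbind, blocks)
  fit_rslds_seg(Y, seg, K, D, max_iter = max_iter, seed = seed)
}

# Internal: like fit_rslds but with an explicit segment vector.
fit_rslds_seg <- function(Y, seg, K, D, max_iter = 15, tol = 1e-6,
                          seed = 1, n_init = 3, verbose = FALSE) {
  T_ <- ncol(Y)
  pc <- stats::prcomp(t(Y), center = TRUE, rank. = D)
  x0 <- t(pc$x[, seq_len(D), drop = FALSE])
  x0 <- x0 / pmax(apply(x0, 1, stats::sd), 1e-12)
  # AR-HMM initialization: alternate per-state AR fits and forward-
  # backward on the PCA latents (zero-covariance moments), from several
  # k-means starts; keep the segmentation with the best chain likelihood.
  post0 <- list(mu = x0, Sigma = array(0, c(D, D, T_)),
                Cross = array(0, c(D, D, T_)), logdetJ = 0)
  run_em <- function(gamma, params, iters) {
    elbo_trace <- numeric(0)
    post <- NULL; fb <- NULL
    for (it in seq_len(iters)) {
      post <- gauss_chain_smoother(Y, gamma, params, seg)
      lphi <- dyn_quad(post, params, seg)
      ltr <- trans_logprob(log(params$P), params$R, post$mu, seg)
      fb <- hmm_forward_backward(lphi, ltr, seg)
      gamma <- fb$gamma
      params <- m_step(Y, post, fb, params, seg)
      el <- rslds_elbo(Y, post, fb, lphi, ltr, params, seg)
      elbo_trace <- c(elbo_trace, el)
      if (verbose) message(sprintf("iter %d  elbo %.3f", it, el))
      if (it > 1 && abs(el - elbo_trace[it - 1]) < tol * (1 + abs(el))) break
    }
    list(gamma = gamma, params = params, post = post,
         elbo_trace = elbo_trace)
  }
  best <- NULL
  for (r in seq_len(n_init)) {
    gamma <- with_seed(seed + (r - 1) * 1000L, {
      # alternate init flavors: (x, dx) dynamics features, plain latent
      # position, or direction-normalized latents (suited to recurrent
      # partitions of the latent space)
      feat <- switch(1L + (r - 1L) %% 3L,
        t(rbind(x0[, -T_, drop = FALSE],
                x0[, -1, drop = FALSE] - x0[, -T_, drop = FALSE])),
        t(x0[, -T_, drop = FALSE]),
        {
          nrm <- sqrt(colSums(x0^2))
          t(sweep(x0, 2, pmax(nrm, 1e-12), "/")[, -T_, drop = FALSE])
        })
      cl <- stats::kmeans(feat, centers = K, nstart = 5)$cluster
      cl <- c(cl[1], cl)
      g <- matrix(1e-3, T_, K)
      g[cbind(seq_len(T_), cl)] <- 1
      g / rowSums(g)
    })
    params <- init_params_from(Y, x0, gamma, K, D, seg)
    for (i in seq_len(10)) {   # AR-HMM refinement at fixed latents
      lphi <- dyn_quad(post0, params, seg)
      ltr <- trans_logprob(log(params$P), params$R, x0, seg)
      fb <- hmm_forward_backward(lphi, ltr, seg)
      gamma <- fb$gamma
      params <- m_step(Y, post0, fb, params, seg)
    }
    cand <- run_em(gamma, params, max_iter)
    if (is.null(best) ||
        max(cand$elbo_trace) > max(best$elbo_trace)) best <- cand
  }
  fit <- list(params = best$params, posterior = list(
    gamma = best$gamma, z = apply(best$gamma, 1, which.max),
    x = best$post$mu, Sigma = best$post$Sigma),
    elbo_trace = best$elbo_trace,
    converged = length(best$elbo_trace) < max_iter, seg = seg,
    seed = seed)
  fit <- reorder_states(fit)
  class(fit) <- "rslds_fit"
  fit
}

# Held-out ELBO: a few fixed-parameter coordinate updates of q(x), q(z)
# on the held-out block.
heldout_elbo <- function(params, Y, iters = 8) {
  T_ <- ncol(Y); K <- params$K
  seg <- rep(1L, T_)
  gamma <- matrix(1 / K, T_, K)
  el <- NA_real_
  for (i in seq_len(iters)) {
    post <- gauss_chain_smoother(Y, gamma, params, seg)
    lphi <- dyn_quad(post, params, seg)
    ltr <- trans_logprob(log(params$P), params$R, post$mu, seg)
    fb <- hmm_forward_backward(lphi, ltr, seg)
    gamma <- fb$gamma
    el <- rslds_elbo(Y, post, fb, lphi, ltr, params, seg)
  }
  el
}
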