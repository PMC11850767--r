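#' Behavior probabilities from one state's filters
#'
#' Softmax over the four filter responses
#' `P(behavior = i | s) = exp(F_i . s) / sum_j exp(F_j . s)`; the
#' `other` filter is fixed at zero.
#'
#' @param s Cue vector.
#' @param filters 4 x p matrix (rows: other, snatch, chase, retreat).
#' @return Length-4 probability vector.
#' @export
glm_predict_proba <- function(s, filters) {
  if (any(!is.finite(s))) stop("non-finite cue")
  if (ncol(filters) != length(s)) stop("cue/filter length mismatch")
  softmax(as.numeric(filters %*% s))
}

# Penalized negative log-likelihood and gradient for one state's GLM.
# theta packs rows 2..4 of the filter matrix.
state_glm_obj <- function(theta, X, Y, lambda) {
  p <- ncol(X)
  Fm <- rbind(0, matrix(theta, 3, p, byrow = TRUE))
  eta <- X %*% t(Fm)                       # n x 4
  m <- apply(eta, 1, max)
  lse_row <- m + log(rowSums(exp(eta - m)))
  ll <- sum(eta[cbind(seq_len(nrow(X)), Y)] - lse_row)
  pen <- 0
  if (p >= 2) {
    d <- Fm[, -1, drop = FALSE] - Fm[, -p, drop = FALSE]
    pen <- lambda * sum(d^2)
  }
  -(ll - pen)
}

state_glm_grad <- function(theta, X, Y, lambda) {
  p <- ncol(X); n <- nrow(X)
  Fm <- rbind(0, matrix(theta, 3, p, byrow = TRUE))
  eta <- X %*% t(Fm)
  m <- apply(eta, 1, max)
  pr <- exp(eta - m); pr <- pr / rowSums(pr)
  ind <- matrix(0, n, 4); ind[cbind(seq_len(n), Y)] <- 1
  G <- t(ind - pr) %*% X                   # 4 x p likelihood gradient
  Gpen <- matrix(0, 4, p)
  if (p >= 2) {
    d <- Fm[, -1, drop = FALSE] - Fm[, -p, drop = FALSE]
    Gpen[, -1] <- Gpen[, -1, drop = FALSE] + 2 * d
    Gpen[, -p] <- Gpen[, -p, drop = FALSE] - 2 * d
  }
  G <- G - lambda * Gpen
  -as.numeric(t(G[2:4, , drop = FALSE]))
}

#' Fit the state-specific multinomial GLM
#'
#' One multinomial GLM per discrete state, each parameterized by four
#' cue-length filters with the `other` filter pinned at zero.  The
#' penalized log-likelihood (squared differences of adjacent filter
#' coefficients, weight `lambda`) is concave and maximized by BFGS, so
#' the fit is deterministic.  Filters are clamped to +/-20 (with a
#' warning) when a state lacks some behavior classes.
#'
#' @param cues n x p cue matrix (z-scored columns: latent dims, distance,
#'   facing angle).
#' @param behaviors Behavior class per bin (other/snatch/chase/retreat).
#' @param z Discrete state per bin.
#' @param lambda Smoothness penalty weight (default 0.1).
#' @param min_bins Minimum bins required per state (default 20).
#' @return List of class `state_filters`: per state a 4 x p filter
#'   matrix (rows named by class), plus `lambda` and `loglik`.
#' @export
fit_state_glm <- function(cues, behaviors, z, lambda = 0.1, min_bins = 20) {
  X <- as.matrix(cues)
  Y <- as.integer(factor(as.character(behaviors), levels = behavior_classes))
  stopifnot(length(Y) == nrow(X), length(z) == nrow(X))
  states <- sort(unique(z))
  filters <- list()
  ll <- 0
  for (k in states) {
    sel <- z == k
    if (sum(sel) < min_bins) {
      stop("state ", k, " has fewer than ", min_bins, " bins")
    }
    Xi <- X[sel, , drop = FALSE]; Yi <- Y[sel]
    if (length(unique(Yi)) < 2) {
      warning("state ", k, " has a single behavior class; filters clamped")
    }
    p <- ncol(X)
    opt <- stats::optim(rep(0, 3 * p), state_glm_obj, state_glm_grad,
                        X = Xi, Y = Yi, lambda = lambda, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    th <- clamp(opt$par, -20, 20)
    Fm <- rbind(0, matrix(th, 3, p, byrow = TRUE))
    rownames(Fm) <- behavior_classes
    colnames(Fm) <- colnames(X)
    filters[[as.character(k)]] <- Fm
    ll <- ll - state_glm_obj(th, Xi, Yi, lambda = 0)
  }
  structure(list(filters = filters, lambda = lambda, loglik = ll),
            class = "state_filters")
}

#' Chance model of behavior frequencies
#'
#' Constant class probabilities `N_i / N` from the empirical label
#' counts, and the log-likelihood of a (held-out) label sequence under
#' them.
#'
#' @param behaviors Training labels.
#' @param test Labels to score (default the training labels).
#' @return List: `prob` (length-4), `loglik`, `accuracy` (of the argmax
#'   constant prediction on `test`).
#' @export
chance_model <- function(behaviors, test = behaviors) {
  y <- factor(as.character(behaviors), levels = behavior_classes)
  if (!length(y)) stop("need at least one bin")
  pr <- as.numeric(table(y)) / length(y)
  names(pr) <- behavior_classes
  yt <- factor(as.character(test), levels = behavior_classes)
  ll <- sum(log(pmax(pr[as.integer(yt)], 1e-300)))
  top <- behavior_classes[which.max(pr)]
  list(prob = pr, loglik = ll, accuracy = mean(as.character(yt) == top))
}

#' Decode behavior from cues with state-specific filters
#'
#' Argmax class per bin using the active state's filters (ties broken
#' toward the lowest class index: other < snatch < chase < retreat),
#' with accuracy and confusion against provided labels and against the
#' chance model.
#'
#' @param cues n x p cue matrix. @param z State per bin.
#' @param fit A [fit_state_glm()] result.
#' @param behaviors Optional true labels for scoring.
#' @param chance Optional [chance_model()] to compare against.
#' @return List: `predicted`, `prob` (n x 4), `accuracy`, `confusion`,
#'   `chance_accuracy`.
#' @export
decode_behavior <- function(cues, z, fit, behaviors = NULL, chance = NULL) {
  X <- as.matrix(cues)
  pr <- matrix(NA_real_, nrow(X), 4,
               dimnames = list(NULL, behavior_classes))
  for (i in seq_len(nrow(X))) {
    key <- as.character(z[i])
    if (is.null(fit$filters[[key]])) stop("unseen state id: ", key)
    pr[i, ] <- glm_predict_proba(X[i, ], fit$filters[[key]])
  }
  pred_idx <- apply(pr, 1, function(p) which(p == max(p))[1])
  predicted <- factor(behavior_classes[pred_idx], levels = behavior_classes)
  acc <- NA_real_; conf <- NULL; ch_acc <- NA_real_
  if (!is.null(behaviors)) {
    yt <- factor(as.character(behaviors), levels = behavior_classes)
    acc <- mean(predicted == yt, na.rm = TRUE)
    conf <- table(truth = yt, predicted = predicted)
    if (!is.null(chance)) ch_acc <- chance$accuracy
  }
  list(predicted = predicted, prob = pr, accuracy = acc,
       confusion = conf, chance_accuracy = ch_acc)
}

#' Sample a behavior raster from fitted filters
#'
#' Full mode uses each bin's active-state filters; single-state mode
#' applies one state's filters to every bin.  Behaviors are sampled from
#' the predicted probabilities under a fixed seed.
#'
#' @param cues n x p cue matrix. @param z State per bin.
#' @param fit A [fit_state_glm()] result.
#' @param mode `"full"` or a state id to use throughout.
#' @param seed RNG seed.
#' @return Factor of sampled behavior classes.
#' @export
raster_from_filters <- function(cues, z, fit, mode = "full", seed = 1) {
  X <- as.matrix(cues)
  zz <- if (identical(mode, "full")) z else rep(mode, nrow(X))
  with_seed(seed, {
    lab <- vapply(seq_len(nrow(X)), function(i) {
      p <- glm_predict_proba(X[i, ], fit$filters[[as.character(zz[i])]])
      sample(behavior_classes, 1, prob = p)
    }, "")
    factor(lab, levels = behavior_classes)
  })
}
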