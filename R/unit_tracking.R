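#' ISIH mixture parameter vector
#'
#' The eight free parameters of a three-component log-normal ISI mixture:
#' log-means mu1..mu3, log-SDs sigma1..sigma3 and the first two mixing
#' probabilities (the third is implied).
#'
#' @param mu,sigma Length-3 log-means and log-SDs (sigma > 0).
#' @param pi12 First two mixing probabilities (sum in \[0, 1\]).
#' @return Named numeric vector of class `isih_params`.
#' @export
isih_params <- function(mu, sigma, pi12) {
  stopifnot(length(mu) == 3, length(sigma) == 3, length(pi12) == 2,
            all(sigma > 0), sum(pi12) >= 0, sum(pi12) <= 1 + 1e-12)
  out <- c(unname(mu), unname(sigma), unname(pi12))
  names(out) <- c("mu1", "mu2", "mu3", "sigma1", "sigma2", "sigma3",
                  "pi1", "pi2")
  structure(out, class = "isih_params")
}

#' Time-shifted waveform similarity
#'
#' The maximum Pearson correlation between the two average waveforms over
#' integer shifts up to `max_shift`, computed on the overlapping samples.
#' Scale-invariant: identical shapes at any amplitude give w = 1.
#'
#' @param wfA,wfB Equal-rate sampled average waveforms.
#' @param max_shift Maximum shift in samples (default 25% of length).
#' @return List: `w` (max correlation), `shift` (argmax shift).
#' @export
waveform_similarity <- function(wfA, wfB,
                                max_shift = round(0.25 * length(wfA))) {
  nA <- length(wfA); nB <- length(wfB)
  if (stats::sd(wfA) == 0 || stats::sd(wfB) == 0) {
    stop("constant waveform: similarity undefined")
  }
  if (min(nA, nB) - max_shift < 0.5 * min(nA, nB)) {
    stop("max_shift leaves less than 50% overlap")
  }
  best <- -Inf; best_shift <- 0L
  for (s in seq(-max_shift, max_shift)) {
    if (s >= 0) {
      a <- wfA[(1 + s):min(nA, nB + s)]
      b <- wfB[seq_along(a)]
    } else {
      b <- wfB[(1 - s):min(nB, nA - s)]
      a <- wfA[seq_along(b)]
    }
    if (length(a) < 2 || stats::sd(a) == 0 || stats::sd(b) == 0) next
    r <- stats::cor(a, b)
    if (r > best) { best <- r; best_shift <- s }
  }
  list(w = best, shift = best_shift)
}

#' Fit a three-component log-normal mixture to ISIs
#'
#' Maximum likelihood by EM on the log-ISIs (a 1-D Gaussian mixture),
#' initialized by k-means with multiple restarts under a fixed seed, so
#' the fit is deterministic.  Components are ordered by ascending
#' log-mean for identifiability.
#'
#' @param isis Positive ISIs (>= 50).
#' @param seed Seed for the k-means initialization.
#' @param tol Log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap.
#' @return An [isih_params()] vector with attribute `loglik`.
#' @export
fit_isih <- function(isis, seed = 1, tol = 1e-8, max_iter = 500) {
  if (any(isis <= 0)) stop("ISIs must be positive")
  if (length(isis) < 50) stop("need >= 50 ISIs")
  x <- log(isis)
  n <- length(x)
  with_seed(seed, {
    km <- stats::kmeans(x, centers = 3, nstart = 10)
    mu <- as.numeric(km$centers)
    sg <- vapply(1:3, function(k) {
      s <- stats::sd(x[km$cluster == k])
      if (!is.finite(s) || s < 1e-4) 1e-2 else s
    }, 0)
    pi <- as.numeric(table(factor(km$cluster, 1:3))) / n
    pi <- pmax(pi, 1e-6); pi <- pi / sum(pi)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      lg <- vapply(1:3, function(k) {
        log(pi[k]) + stats::dnorm(x, mu[k], sg[k], log = TRUE)
      }, numeric(n))
      m <- apply(lg, 1, max)
      lse_row <- m + log(rowSums(exp(lg - m)))
      ll <- sum(lse_row)
      g <- exp(lg - lse_row)
      nk <- colSums(g)
      mu <- colSums(g * x) / nk
      sg <- sqrt(colSums(g * (x - rep(mu, each = n))^2) / nk)
      sg <- pmax(sg, 1e-4)
      pi <- nk / n
      if (abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    ord <- order(mu)
    out <- isih_params(mu[ord], sg[ord], pi[ord][1:2])
    attr(out, "loglik") <- ll
    out
  })
}

#' ISIH similarity score between two parameter sets
#'
#' `I(A, B) = sqrt(sum_i (A_i - B_i)^2 / sigma_i^2)` over the eight
#' mixture parameters, with `sigma_i` a per-parameter normalization SD
#' (by default the SD of that parameter across the population of fitted
#' units).  `I' = log(I)` (natural log, guarded at 1e-12).
#'
#' @param A,B [isih_params()] vectors (identical parameter ordering).
#' @param norm_sd Length-8 positive normalization SDs.
#' @return List: `I`, `I_prime`.
#' @export
isih_score <- function(A, B, norm_sd) {
  if (!identical(names(A), names(B))) stop("mismatched ISIH parameter ordering")
  if (length(norm_sd) != 8 || any(norm_sd <= 0)) {
    stop("norm_sd must be 8 positive values")
  }
  I <- sqrt(sum((unclass(A) - unclass(B))^2 / norm_sd^2))
  list(I = I, I_prime = log(max(I, 1e-12)))
}

#' Same-unit decision
#'
#' The conjunction of the two thresholds: waveform similarity strictly
#' above 0.81 and log ISIH score strictly below 1.
#'
#' @param w Waveform similarity. @param I_prime Log ISIH score.
#' @param w_threshold,i_threshold The decision thresholds.
#' @return Logical.
#' @export
decide_same_unit <- function(w, I_prime, w_threshold = 0.81,
                             i_threshold = 1) {
  (w > w_threshold) & (I_prime < i_threshold)
}

#' Match units between two days
#'
#' Fits the ISI mixture of every unit, computes all day-A x day-B
#' waveform similarities and ISIH scores (normalized by the population
#' SD of each parameter across all fitted units, or by supplied SDs),
#' and applies the same-unit decision to every pair.
#'
#' @param dayA,dayB Lists of unit records (see [gen_unit_days()]).
#' @param norm_sd Optional length-8 SDs; default population SDs.
#' @param seed Seed for the ISIH fits.
#' @return Data frame: unitA, unitB, w, I, I_prime, same_unit.
#' @export
match_units <- function(dayA, dayB, norm_sd = NULL, seed = 1) {
  fits <- lapply(c(dayA, dayB), function(u) fit_isih(u$isis, seed = seed))
  nA <- length(dayA)
  pm <- do.call(rbind, lapply(fits, unclass))
  if (is.null(norm_sd)) {
    norm_sd <- apply(pm, 2, stats::sd)
    norm_sd[norm_sd <= 0 | !is.finite(norm_sd)] <- 1e-6
  }
  rows <- list()
  for (i in seq_along(dayA)) {
    for (j in seq_along(dayB)) {
      w <- waveform_similarity(dayA[[i]]$waveform, dayB[[j]]$waveform)$w
      sc <- isih_score(fits[[i]], fits[[nA + j]], norm_sd)
      rows[[length(rows) + 1]] <- data.frame(
        unitA = dayA[[i]]$unit, unitB = dayB[[j]]$unit,
        w = w, I = sc$I, I_prime = sc$I_prime,
        same_unit = decide_same_unit(w, sc$I_prime))
    }
  }
  do.call(rbind, rows)
}
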