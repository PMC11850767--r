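#' Lagged cross-correlation of two daily series
#'
#' Sample cross-covariance with 1/T normalization,
#' `c(k) = (1/T) sum_t (y1_t - m1)(y2_{t+k} - m2)`, divided by the
#' product of the two series' (population) SDs.  `r(0) = 1` for identical
#' series; `r(k)` for y1 vs y2 equals `r(-k)` for y2 vs y1.
#'
#' @param y1,y2 Equal-length series (length >= 3), 1-day spacing.
#' @param max_lag Largest |k| (default `floor(T/2)`).
#' @return Data frame `lag`, `r`.
#' @export
cross_correlation <- function(y1, y2, max_lag = floor(length(y1) / 2)) {
  T_ <- min(length(y1), length(y2))
  if (T_ < 3) stop("need series of length >= 3")
  y1 <- y1[seq_len(T_)]; y2 <- y2[seq_len(T_)]
  m1 <- mean(y1); m2 <- mean(y2)
  s1 <- sqrt(mean((y1 - m1)^2)); s2 <- sqrt(mean((y2 - m2)^2))
  if (s1 == 0 || s2 == 0) stop("zero-variance series")
  lags <- seq(-max_lag, max_lag)
  r <- vapply(lags, function(k) {
    if (k >= 0) {
      t <- seq_len(T_ - k)
      sum((y1[t] - m1) * (y2[t + k] - m2)) / T_
    } else {
      t <- seq_len(T_ + k)
      sum((y2[t] - m2) * (y1[t - k] - m1)) / T_
    }
  }, 0) / (s1 * s2)
  data.frame(lag = lags, r = r)
}

#' Optimal lag of a cross-correlation series
#'
#' The lag with the greatest correlation (signed maximum).  Ties go to
#' the smallest |k|; a +/-k magnitude tie resolves to the negative lag.
#'
#' @param cc Data frame from [cross_correlation()].
#' @return Integer lag.
#' @export
optimal_lag <- function(cc) {
  best <- cc[cc$r == max(cc$r), , drop = FALSE]
  best <- best[order(abs(best$lag), best$lag), , drop = FALSE]
  best$lag[1]
}

#' Permutation test for lagged cross-correlation
#'
#' The observed statistic is `max_k |r(k)|`.  The null is built by
#' independently permuting one series `n` times; the p-value uses the
#' add-one correction.
#'
#' @param y1,y2 The two series. @param n Number of permutations.
#' @param max_lag Passed to [cross_correlation()].
#' @param seed RNG seed.
#' @return List: `p`, `observed`, `null` (vector of null statistics).
#' @export
xcorr_permutation_test <- function(y1, y2, n = 1000,
                                   max_lag = floor(length(y1) / 2),
                                   seed = 1) {
  obs <- max(abs(cross_correlation(y1, y2, max_lag)$r))
  with_seed(seed, {
    null <- vapply(seq_len(n), function(i) {
      max(abs(cross_correlation(y1, sample(y2), max_lag)$r))
    }, 0)
    list(p = (1 + sum(null >= obs)) / (n + 1), observed = obs, null = null)
  })
}
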