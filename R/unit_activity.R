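# Gaussian smoothing of a regularly binned series (kernel SD in bins).
gauss_smooth <- function(x, sd_bins) {
  if (sd_bins <= 0) return(x)
  half <- ceiling(4 * sd_bins)
  k <- stats::dnorm(seq(-half, half), sd = sd_bins)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + n)]
}

#' Peri-event z-scored response of one unit
#'
#' Bins the unit's spikes (50 ms bins by default), smooths with a
#' Gaussian kernel (SD 100 ms), and z-scores the peri-event rate against
#' the pooled baseline-window mean and SD.  A Wilcoxon signed-rank test
#' compares per-event mean rates in the 3 s baseline and response
#' windows; the unit is responsive when the test is significant and the
#' mean response-window z exceeds 1.5 (or is at most -1).  Units with
#' mean rate below 0.1 Hz are excluded before testing, as are units with
#' zero baseline SD.
#'
#' @param spikes Spike times (s) of one unit.
#' @param events Event onset times (>= 5).
#' @param t_max Session length (s).
#' @param bin_s,smooth_sd_s Binning and smoothing parameters.
#' @param baseline Baseline window relative to onset (default `c(-4, -1)`,
#'   i.e. 3 s ending 1 s before onset).
#' @param response Response window (default `c(0, 3)`).
#' @param min_rate Exclusion threshold in Hz (default 0.1).
#' @param alpha Significance level of the signed-rank test.
#' @return List of class `response_profile`: `z` (peri-event z series
#'   over \[baseline start, response end)), `t` (bin centres relative to
#'   onset), `mean_z`, `p`, `responsive`, `excluded`, `flag`.
#' @export
peri_event_z <- function(spikes, events, t_max, bin_s = 0.05,
                         smooth_sd_s = 0.1, baseline = c(-4, -1),
                         response = c(0, 3), min_rate = 0.1,
                         alpha = 0.05) {
  if (length(events) < 5) stop("need >= 5 events for the paired test")
  mean_rate <- length(spikes) / t_max
  if (mean_rate < min_rate) {
    return(structure(list(excluded = TRUE, reason = "low_rate",
                          mean_rate = mean_rate), class = "response_profile"))
  }
  edges <- seq(0, t_max, by = bin_s)
  rate <- graphics::hist(spikes[spikes >= 0 & spikes < t_max],
                         breaks = edges, plot = FALSE)$counts / bin_s
  sm <- gauss_smooth(rate, smooth_sd_s / bin_s)
  rel <- seq(baseline[1], response[2] - bin_s, by = bin_s) + bin_s / 2
  n_rel <- length(rel)
  peri <- matrix(NA_real_, length(events), n_rel)
  base_pool <- c()
  for (e in seq_along(events)) {
    idx <- floor((events[e] + rel - bin_s / 2) / bin_s) + 1L
    ok <- idx >= 1 & idx <= length(sm)
    peri[e, ok] <- sm[idx[ok]]
    bsel <- rel >= baseline[1] & rel < baseline[2]
    base_pool <- c(base_pool, peri[e, bsel & ok])
  }
  bm <- mean(base_pool, na.rm = TRUE)
  bs <- stats::sd(base_pool, na.rm = TRUE)
  if (!is.finite(bs) || bs == 0) {
    return(structure(list(excluded = TRUE, reason = "zero_baseline_sd",
                          mean_rate = mean_rate), class = "response_profile"))
  }
  zmat <- (peri - bm) / bs
  z <- colMeans(zmat, na.rm = TRUE)
  rsel <- rel >= response[1] & rel < response[2]
  mean_z <- mean(z[rsel], na.rm = TRUE)
  # paired test on raw (unsmoothed) per-event window means
  win_mean <- function(onset, win) {
    lo <- onset + win[1]; hi <- onset + win[2]
    sum(spikes >= lo & spikes < hi) / (hi - lo)
  }
  b <- vapply(events, win_mean, 0, win = baseline)
  r <- vapply(events, win_mean, 0, win = response)
  p <- if (all(b == r)) 1 else {
    suppressWarnings(stats::wilcox.test(r, b, paired = TRUE,
                                        exact = length(events) <= 25)$p.value)
  }
  responsive <- (p < alpha) && (mean_z > 1.5 || mean_z <= -1)
  structure(list(z = z, t = rel, mean_z = mean_z, p = p,
                 responsive = responsive, excluded = FALSE,
                 mean_rate = mean_rate), class = "response_profile")
}

#' Functional clustering of event-aligned units
#'
#' Agglomerative clustering (Euclidean distance) of the units'
#' event-aligned z series, cut at `cut` -- by default interpreted as a
#' fraction of the maximum linkage height (`mode = "relative"`); an
#' absolute-height cut is available.  Non-responsive units are collected
#' into a residual cluster labelled 0.
#'
#' @param z_matrix Units x time matrix of z series (e.g. snatch and
#'   retreat windows concatenated).
#' @param responsive Logical per unit; FALSE rows go to the residual
#'   cluster (default all TRUE).
#' @param cut Cut parameter (default 0.4).
#' @param mode `"relative"` (0.4 x max height) or `"absolute"`.
#' @param linkage hclust method.
#' @return List: `labels` (0 = residual), `hclust` (on responsive rows).
#' @export
cluster_units <- function(z_matrix, responsive = rep(TRUE, nrow(z_matrix)),
                          cut = 0.4, mode = c("relative", "absolute"),
                          linkage = "ward.D2") {
  mode <- match.arg(mode)
  if (nrow(z_matrix) < 2) stop("need >= 2 units")
  labels <- integer(nrow(z_matrix))
  resp <- which(responsive)
  if (length(resp) >= 2) {
    hc <- stats::hclust(stats::dist(z_matrix[resp, , drop = FALSE]),
                        method = linkage)
    h <- if (mode == "relative") cut * max(hc$height) else cut
    labels[resp] <- stats::cutree(hc, h = h)
  } else if (length(resp) == 1) {
    labels[resp] <- 1L
    hc <- NULL
  } else {
    hc <- NULL
  }
  list(labels = labels, hclust = if (length(resp) >= 2) hc else NULL)
}

#' Rank-sum comparison of response magnitudes between groups
#'
#' Two-sided Wilcoxon rank-sum test on per-unit mean response-window
#' z-scores.
#'
#' @param groupA,groupB Nonempty numeric vectors.
#' @return List: `statistic`, `p`.
#' @export
response_magnitude_compare <- function(groupA, groupB) {
  if (!length(groupA) || !length(groupB)) stop("both groups must be nonempty")
  wt <- suppressWarnings(stats::wilcox.test(groupA, groupB,
                                            alternative = "two.sided"))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1   # degenerate all-tied comparison
  list(statistic = unname(wt$statistic), p = p)
}

#' Firing-rate variance distributions and KS comparison
#'
#' Per-unit firing-rate variance over the session, Gaussian-kernel
#' density estimates, and the two-sample Kolmogorov-Smirnov test between
#' groups.
#'
#' @param ratesA,ratesB Units x time rate matrices (>= 2 units each).
#' @return List: `varA`, `varB`, `densityA`, `densityB`, `D`, `p`.
#' @export
rate_variance_distribution <- function(ratesA, ratesB) {
  vA <- apply(as.matrix(ratesA), 1, stats::var)
  vB <- apply(as.matrix(ratesB), 1, stats::var)
  ks <- suppressWarnings(stats::ks.test(vA, vB))
  list(varA = vA, varB = vB,
       densityA = stats::density(vA, kernel = "gaussian"),
       densityB = stats::density(vB, kernel = "gaussian"),
       D = unname(ks$statistic), p = ks$p.value)
}

#' Cross-day functional-cluster realignment
#'
#' For units tracked across days, the percentage of day-0 cluster members
#' landing in each day-N cluster; rows sum to 100.
#'
#' @param labels0,labelsN Named cluster labels (names = unit ids).
#' @param map Data frame `unit0`, `unitN` pairing tracked units.
#' @return Matrix of percentages (day-0 clusters x day-N clusters).
#' @export
cluster_realignment <- function(labels0, labelsN, map) {
  if (!nrow(map)) stop("empty identity map")
  l0 <- labels0[as.character(map$unit0)]
  lN <- labelsN[as.character(map$unitN)]
  tab <- table(day0 = l0, dayN = lN)
  pct <- 100 * tab / rowSums(tab)
  as.matrix(pct)
}
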