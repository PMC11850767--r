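gauss_deriv <- function(s, centre, width) {
  z <- (s - centre) / width
  -z * exp(-0.5 * z^2)
}

# Random spike-waveform template: a sum of 2-3 Gaussian-derivative lobes,
# peak-normalized to 1.
waveform_template <- function(n_samples = 64) {
  s <- seq(-1, 1, length.out = n_samples)
  n_lobes <- sample(2:3, 1)
  w <- rep(0, n_samples)
  for (j in seq_len(n_lobes)) {
    w <- w + stats::runif(1, 0.5, 1.5) * sample(c(-1, 1), 1) *
      gauss_deriv(s, stats::runif(1, -0.5, 0.5), stats::runif(1, 0.06, 0.25))
  }
  w / max(abs(w))
}

# Smooth random perturbation of unit amplitude `sd`, used for waveform drift.
smooth_noise <- function(n, sd, bw = 4) {
  if (sd == 0) return(rep(0, n))
  x <- stats::rnorm(n + 6 * bw)
  k <- stats::dnorm(seq(-3 * bw, 3 * bw), sd = bw)
  sm <- stats::filter(x, k / sum(k), sides = 2)
  sm <- sm[(3 * bw + 1):(3 * bw + n)]
  as.numeric(sd * sm / stats::sd(sm))
}

#' Simulate drifting units across recording days
#'
#' Every tracked unit has a fixed waveform template (sum of
#' Gaussian-derivative lobes, peak amplitude 1) and fixed three-component
#' log-normal ISI mixture parameters.  Each day the waveform receives an
#' independent smooth perturbation of SD `drift_sd` (in units of peak
#' amplitude) and fresh ISI samples are drawn.  Unrelated distractor
#' units are added on each day after the first.
#'
#' @param n_units Number of tracked units.
#' @param n_days Number of days (>= 1).
#' @param drift_sd Waveform drift SD relative to peak amplitude (>= 0).
#' @param seed RNG seed.
#' @param n_distractors Extra unmatched units per later day.
#' @param n_isi ISI samples per unit per day.
#' @param n_samples Waveform samples.
#' @return List: `days` (list per day of unit records: `unit`, `day`,
#'   `true_id`, `waveform`, `isis`, `spike_times`, `mean_rate`,
#'   `isih_true`), `identity_map` (data frame day/unit/true_id).
#' @export
gen_unit_days <- function(n_units, n_days, drift_sd, seed = 1,
                          n_distractors = max(2L, round(0.2 * n_units)),
                          n_isi = 5000, n_samples = 64) {
  stopifnot(drift_sd >= 0, n_units >= 1, n_days >= 1)
  with_seed(seed, {
    make_isih <- function() {
      # well-separated burst / regular / pause modes, as in cortical ISIHs
      mu <- sort(log(c(stats::runif(1, 0.002, 0.008),
                       stats::runif(1, 0.03, 0.1),
                       stats::runif(1, 0.4, 1.2))))
      sigma <- stats::runif(3, 0.2, 0.4)
      g <- stats::rgamma(3, 2)
      pi <- 0.1 + 0.7 * g / sum(g)   # keep every mode populated
      pi <- pi / sum(pi)
      isih_params(mu, sigma, pi[1:2])
    }
    templates <- replicate(n_units, waveform_template(n_samples),
                           simplify = FALSE)
    isih <- replicate(n_units, make_isih(), simplify = FALSE)
    next_id <- n_units + 1L
    days <- vector("list", n_days)
    id_rows <- list()
    for (d in seq_len(n_days)) {
      recs <- list()
      ids_today <- seq_len(n_units)
      extra <- if (d > 1) seq(next_id, length.out = n_distractors) else integer()
      for (uid in ids_today) {
        wf <- templates[[uid]] + smooth_noise(n_samples, drift_sd)
        p <- isih[[uid]]
        isis <- sample_isih(p, n_isi)
        recs[[length(recs) + 1]] <- list(
          unit = length(recs) + 1L, day = d, true_id = uid,
          waveform = wf, isis = isis, spike_times = cumsum(isis),
          mean_rate = length(isis) / sum(isis), isih_true = p)
        id_rows[[length(id_rows) + 1]] <- data.frame(
          day = d, unit = length(recs), true_id = uid)
      }
      for (uid in extra) {
        wf <- waveform_template(n_samples)
        p <- make_isih()
        isis <- sample_isih(p, n_isi)
        recs[[length(recs) + 1]] <- list(
          unit = length(recs) + 1L, day = d, true_id = uid,
          waveform = wf, isis = isis, spike_times = cumsum(isis),
          mean_rate = length(isis) / sum(isis), isih_true = p)
        id_rows[[length(id_rows) + 1]] <- data.frame(
          day = d, unit = length(recs), true_id = uid)
      }
      if (d > 1) next_id <- next_id + n_distractors
      days[[d]] <- recs
    }
    list(days = days, identity_map = do.call(rbind, id_rows))
  })
}

#' Sample interspike intervals from a log-normal mixture
#'
#' @param params An [isih_params()] vector.
#' @param n Number of ISIs.
#' @return Positive numeric vector of ISIs (seconds).
#' @export
sample_isih <- function(params, n) {
  pi3 <- c(params[["pi1"]], params[["pi2"]],
           1 - params[["pi1"]] - params[["pi2"]])
  comp <- sample.int(3, n, replace = TRUE, prob = pi3)
  mu <- c(params[["mu1"]], params[["mu2"]], params[["mu3"]])
  sg <- c(params[["sigma1"]], params[["sigma2"]], params[["sigma3"]])
  stats::rlnorm(n, mu[comp], sg[comp])
}
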