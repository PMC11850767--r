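# Shared helpers for the test suite.

# Best label-permutation accuracy between a fitted and a true state series.
best_perm_accuracy <- function(z_fit, z_true, K) {
  perms <- perms_of(seq_len(K))
  max(vapply(perms, function(pm) mean(pm[z_fit] == z_true), 0))
}

perms_of <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms_of(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# A small deterministic two-state filter set for GLM tests.
toy_cues <- function(T_, p = 4, seed = 1) {
  withr::with_seed(seed, matrix(stats::rnorm(T_ * p), T_, p,
                                dimnames = list(NULL, paste0("c", seq_len(p)))))
}

# Sample behavior labels from a known filter matrix (4 x p, row 1 zero).
sample_behaviors <- function(cues, filters, seed = 1) {
  withr::with_seed(seed, {
    cls <- apply(cues, 1, function(s) {
      p <- exp(filters %*% s); p <- p / sum(p)
      sample(c("other", "snatch", "chase", "retreat"), 1, prob = p)
    })
    factor(cls, levels = c("other", "snatch", "chase", "retreat"))
  })
}
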