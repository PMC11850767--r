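# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

log_softmax <- function(x) {
  m <- max(x)
  x - m - log(sum(exp(x - m)))
}

# logsumexp along a vector
lse <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Undirected angle between two direction vectors, in degrees [0, 180].
vector_angle_deg <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  rad2deg(acos(clamp(sum(u * v) / (nu * nv), -1, 1)))
}

# Draw one sample from N(mean, cov) via Cholesky; cov must be PSD.
rmvnorm1 <- function(mean, cov) {
  d <- length(mean)
  if (all(cov == 0)) return(mean)
  ch <- tryCatch(chol(cov), error = function(e) {
    ch <- suppressWarnings(chol(cov + diag(1e-10, d)))
    ch
  })
  as.numeric(mean + t(ch) %*% rnorm(d))
}

is_psd <- function(m, tol = 1e-10) {
  if (!isSymmetric(unname(m), tol = 1e-8)) return(FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev > -tol * max(1, abs(ev[1])))
}

# 2x2 rotation matrix scaled by rho, angle in degrees.
rotation_block <- function(omega_deg, rho = 1) {
  w <- deg2rad(omega_deg)
  rho * matrix(c(cos(w), sin(w), -sin(w), cos(w)), 2, 2)
}
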