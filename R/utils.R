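# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

logit <- function(p) stats::qlogis(p)
invlogit <- function(x) stats::plogis(x)

#' Highest density interval of a sample
#'
#' Shortest interval containing `level` of the draws (empirical HDI).
#'
#' @param x numeric vector of posterior draws.
#' @param level probability mass of the interval (default 0.95).
#' @return named numeric vector `c(lower, upper)`.
#' @export
hdi <- function(x, level = 0.95) {
  stopifnot(level > 0, level < 1)
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0L) return(c(lower = NA_real_, upper = NA_real_))
  m <- max(1L, ceiling(level * n))
  if (m >= n) return(c(lower = x[1L], upper = x[n]))
  width <- x[(m + 1L):n] - x[1:(n - m)]
  i <- which.min(width)
  c(lower = x[i], upper = x[i + m])
}

# Probability of direction: max(P(x>0), P(x<0)); exact ties split so a
# symmetric all-zero sample reports 0.5.
pd_value <- function(x) {
  q <- mean(x > 0) + 0.5 * mean(x == 0)
  max(q, 1 - q)
}

# Multivariate normal draws via Cholesky with a PD jitter fallback.
rmvn <- function(n, mu, sigma) {
  p <- length(mu)
  ch <- tryCatch(chol(sigma), error = function(e) {
    chol(sigma + diag(1e-8 * max(diag(sigma), 1), p))
  })
  matrix(stats::rnorm(n * p), n, p) %*% ch + rep(mu, each = n)
}

# Inverse-CDF draws from a Gaussian truncated to [lo, hi]; exact and stable
# under seeding, degenerates to a point mass when sd == 0.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(clamp(mean, lo, hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  clamp(stats::qnorm(u, mean, sd), lo, hi)
}

# Deterministic per-stage seed derivation from one global seed, so pipeline
# stages are independently reproducible.  Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(seed) * 1009 + h * 7919 + 1) %% 2147483647)
}

stage_stop <- function(stage, ...) {
  stop(sprintf("stage %s: %s", stage, paste0(...)), call. = FALSE)
}
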