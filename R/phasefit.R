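#' Specify a sigmoid phase (change-point) model
#'
#' Growth-phase model for a NEG time series: the mean curve is a sum of
#' `n_phases` zero-anchored sigmoids,
#' `m(t) = sum_i A_i * (F_i(t) - F_i(0)) / (1 - F_i(0))` with
#' `F_i(t) = 1 / (1 + exp(-k_i (t - t0_i)))`, constrained so the total
#' amplitude cannot exceed 100%.  For the dual-phase model the inflexion
#' points are ordered (`t0_1 < t0_2`) by construction, which removes
#' label switching.
#'
#' Two observation families are available.  The default, `"binomial"`,
#' models the *increments* of the visited-segment count as conditionally
#' binomial draws of the still-unvisited segments with the first-visit
#' hazard implied by the mean curve,
#' `K_t - K_s ~ Binomial(n - K_s, (M_t - M_s) / (n - M_s))`:
#' the natural likelihood for a monotone first-visit process, exact under
#' time thinning, bounded by construction, and factorising over
#' increments (convenient for LOO).  `"logit-normal"` instead treats each
#' observation as Gaussian on the logit of the proportion (scale
#' `sigma`), an approximation useful for non-count curve data.
#'
#' Priors (all overridable through `priors`): amplitudes uniform on the
#' admissible range, inflexion points uniform on `[0, duration]`,
#' log-rate Gaussian (`logk_mean`, `logk_sd`), and for the logit-normal
#' family a noise scale uniform on `(0, sigma_max)`.
#'
#' @param n_phases 1 or 2 growth phases.
#' @param duration test duration in seconds (upper bound of the inflexion
#'   priors).
#' @param priors named list overriding `logk_mean`, `logk_sd`,
#'   `sigma_max`.
#' @param noise observation family: `"binomial"` (increment hazard) or
#'   `"logit-normal"`.
#' @param eps proportion clamp for the logit-normal transform.
#' @return a `phase_model_spec` object.
#' @export
phase_model_spec <- function(n_phases = 1, duration = 300, priors = list(),
                             noise = c("binomial", "logit-normal"),
                             eps = 1e-4) {
  if (!n_phases %in% c(1, 2)) stop("n_phases must be 1 or 2")
  noise <- match.arg(noise)
  p <- list(logk_mean = log(0.05), logk_sd = 1.6, sigma_max = 5)
  p[names(priors)] <- priors
  structure(list(n_phases = as.integer(n_phases), duration = duration,
                 priors = p, noise = noise, eps = eps),
            class = "phase_model_spec")
}

#' @export
print.phase_model_spec <- function(x, ...) {
  cat(sprintf("%d-phase sigmoid growth model (duration %g s, %s observations)\n",
              x$n_phases, x$duration, x$noise))
  cat(sprintf("  priors: log k ~ N(%.2f, %.2f); t0 ~ U(0, %g)\n",
              x$priors$logk_mean, x$priors$logk_sd, x$duration))
  invisible(x)
}

jags_model_string <- function(n_phases, noise) {
  mean1 <- "
  F0 <- ilogit(-k * t0)
  A ~ dunif(0, 100)
  logk ~ dnorm(logk_mean, pow(logk_sd, -2))
  k <- exp(logk)
  t0 ~ dunif(0, dur)"
  mean2 <- "
  F01 <- ilogit(-k1 * t01)
  F02 <- ilogit(-k2 * t02)
  A1 ~ dunif(0, 100)
  u2 ~ dunif(0, 1)
  A2 <- u2 * (100 - A1)
  logk1 ~ dnorm(logk_mean, pow(logk_sd, -2))
  logk2 ~ dnorm(logk_mean, pow(logk_sd, -2))
  k1 <- exp(logk1)
  k2 <- exp(logk2)
  t01 ~ dunif(0, dur)
  d2 ~ dunif(0, dur - t01)
  t02 <- t01 + d2            # ordered inflexions: no label switching
  sigma ~ dunif(0, sigma_max)"
  mu1 <- "A * (ilogit(k * (%s - t0)) - F0) / (1 - F0)"
  mu2 <- paste0("A1 * (ilogit(k1 * (%s - t01)) - F01) / (1 - F01) + ",
                "A2 * (ilogit(k2 * (%s - t02)) - F02) / (1 - F02)")
  mu_at <- function(v) {
    if (n_phases == 1L) sprintf(mu1, v) else sprintf(mu2, v, v)
  }
  if (noise == "binomial") {
    sprintf("
model {
  for (i in 1:N) {
    m[i]  <- %s
    mp[i] <- %s
    q[i] <- max(min((m[i] - mp[i]) / max(100 - mp[i], 0.001), 0.999999), 1.0E-9)
    dk[i] ~ dbin(q[i], size[i])
  }%s
}", mu_at("t[i]"), mu_at("tp[i]"),
    if (n_phases == 1L) mean1 else sub("\n  sigma ~ dunif\\(0, sigma_max\\)", "", mean2))
  } else {
    sprintf("
model {
  for (i in 1:N) {
    mu[i] <- %s
    pm[i] <- max(min(mu[i] / 100, 1 - eps), eps)
    z[i] ~ dnorm(logit(pm[i]), tau)
  }%s
  sigma0 ~ dunif(0, sigma_max)
  tau <- pow(sigma, -2)
  sigma <- %s
}", mu_at("t[i]"),
    if (n_phases == 1L) mean1 else sub("\n  sigma ~ dunif\\(0, sigma_max\\)", "", mean2),
    "sigma0")
  }
}

phase_mean_curve <- function(t, pars, n_phases) {
  if (n_phases == 1L)
    sigmoid_mean(t, pars[["k"]], pars[["t0"]], pars[["A"]])
  else
    sigmoid_mean(t, pars[["k1"]], pars[["t01"]], pars[["A1"]]) +
      sigmoid_mean(t, pars[["k2"]], pars[["t02"]], pars[["A2"]])
}

# Per-increment first-visit hazard implied by the mean curve (percent
# scale): probability that a segment unvisited at time s is visited by t.
hazard_q <- function(mu_t, mu_s) {
  clamp((mu_t - mu_s) / pmax(100 - mu_s, 1e-3), 1e-9, 1 - 1e-6)
}

# Restructure a (possibly stacked multi-subject) series into increment
# records: per subject, consecutive kept observations with the previous
# time/count, dropping saturated records that carry no information.
increment_data <- function(series, n_scope) {
  sub <- if (!is.null(series$subject)) as.character(series$subject) else
    rep("s1", nrow(series))
  out <- lapply(split(seq_len(nrow(series)), sub), function(idx) {
    idx <- idx[order(series$time[idx])]
    tt <- series$time[idx]
    K <- round(series$neg[idx] / 100 * n_scope)
    tp <- c(0, tt[-length(tt)])
    Kp <- c(0, K[-length(K)])
    keep <- (n_scope - Kp) > 0 & tt > tp
    data.frame(t = tt[keep], tp = tp[keep], dk = (K - Kp)[keep],
               size = (n_scope - Kp)[keep], subject = sub[idx][keep])
  })
  do.call(rbind, out)
}

#' Fit a Bayesian sigmoid phase model to a NEG series
#'
#' MCMC fit (JAGS) of a [phase_model_spec()] to a single-subject or
#' group-pooled (stacked) NEG time series.  The pointwise log-likelihood
#' matrix is retained for PSIS-LOO model comparison, and the per-chain
#' draws for convergence diagnostics.
#'
#' @param series a `neg_series` (columns `time`, `neg`, optionally
#'   `subject` for stacked group data) from [compute_neg()], [pool_neg()]
#'   or built by hand.  Must be monotone non-decreasing within each
#'   subject and bounded in \[0, 100\].
#' @param spec a [phase_model_spec()]; defaults to a single phase over
#'   the series' time range.
#' @param chains,warmup,iter MCMC settings (post-warmup draws per chain =
#'   `iter`).
#' @param thin keep every `thin`-th time point (time thinning is exact
#'   under the binomial increment model).
#' @param seed integer seed (drives all chains' RNGs).
#' @param n_scope segments in the series' scope (defaults to the series'
#'   `n_scope` attribute, or 100); sets the count denominator of the
#'   binomial family.
#' @param quiet suppress JAGS progress output.
#' @return a `neg_phasefit` object with posterior draws, per-chain
#'   samples, the pointwise log-likelihood matrix and the model data.
#' @export
fit_phase_model <- function(series, spec = NULL, chains = 4, warmup = 1000,
                            iter = 1000, thin = 1, seed = 1, n_scope = NULL,
                            quiet = TRUE) {
  stopifnot(all(c("time", "neg") %in% names(series)))
  if (any(series$neg < -1e-9 | series$neg > 100 + 1e-9))
    stop("NEG values must lie within [0, 100]")
  # monotone non-decreasing within each subject (stacked group series are
  # only monotone per subject)
  mono_ok <- if (!is.null(series$subject)) {
    all(vapply(split(series[c("time", "neg")], series$subject), function(d)
      all(diff(d$neg[order(d$time)]) >= -1e-6), logical(1)))
  } else all(diff(series$neg) >= -1e-6)
  if (!mono_ok) stop("NEG series must be monotone non-decreasing")
  spec <- spec %||% phase_model_spec(1, duration = max(series$time))
  n_scope <- n_scope %||% attr(series, "n_scope") %||% 100L
  if (is.na(n_scope)) n_scope <- 100L
  if (thin > 1L) {
    if (!is.null(series$subject)) {
      series <- series[series$time %% thin == 0, , drop = FALSE]
    } else series <- series[seq(1L, nrow(series), by = thin), , drop = FALSE]
  }

  binom <- spec$noise == "binomial"
  if (binom) {
    inc <- increment_data(series, n_scope)
    if (!nrow(inc)) stop("series carries no usable increments")
    dat <- list(dk = inc$dk, size = inc$size,
                t = inc$t, tp = inc$tp, N = nrow(inc), dur = spec$duration,
                logk_mean = spec$priors$logk_mean,
                logk_sd = spec$priors$logk_sd)
    obs_t <- inc$t
  } else {
    tt <- series$time
    y <- series$neg
    z <- logit(clamp(y / 100, spec$eps, 1 - spec$eps))
    dat <- list(z = z, t = tt, N = length(tt), dur = spec$duration,
                eps = spec$eps, logk_mean = spec$priors$logk_mean,
                logk_sd = spec$priors$logk_sd,
                sigma_max = spec$priors$sigma_max)
    obs_t <- tt
  }

  inits <- lapply(seq_len(chains), function(ch) {
    ini <- if (spec$n_phases == 1L)
      list(A = 90, logk = spec$priors$logk_mean,
           t0 = spec$duration * (0.2 + 0.15 * ch))
    else
      list(A1 = 45, u2 = 0.5, logk1 = spec$priors$logk_mean,
           logk2 = spec$priors$logk_mean,
           t01 = spec$duration * (0.05 + 0.05 * ch),
           d2 = spec$duration * 0.4)
    if (!binom) ini$sigma0 <- 0.5
    c(ini, list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = as.integer((as.numeric(seed) * 100 + ch) %% 2147483647)))
  })
  vars <- if (spec$n_phases == 1L) c("A", "k", "t0")
          else c("A1", "A2", "k1", "k2", "t01", "t02")
  if (!binom) vars <- c(vars, "sigma")
  run <- function() {
    jm <- rjags::jags.model(textConnection(jags_model_string(spec$n_phases, spec$noise)),
                            data = dat, inits = inits, n.chains = chains,
                            n.adapt = max(100L, warmup %/% 2L), quiet = TRUE)
    stats::update(jm, max(0L, warmup - warmup %/% 2L),
                  progress.bar = "none")
    rjags::coda.samples(jm, vars, n.iter = iter, progress.bar = "none")
  }
  samples <- if (quiet) suppressWarnings(run()) else run()
  draws <- as.matrix(samples)

  # pointwise log-likelihood, draws x observations
  loglik <- matrix(NA_real_, nrow(draws), length(obs_t))
  for (s in seq_len(nrow(draws))) {
    if (binom) {
      mu_t <- phase_mean_curve(dat$t, draws[s, ], spec$n_phases)
      mu_p <- phase_mean_curve(dat$tp, draws[s, ], spec$n_phases)
      loglik[s, ] <- stats::dbinom(dat$dk, dat$size,
                                   hazard_q(mu_t, mu_p), log = TRUE)
    } else {
      mu <- phase_mean_curve(dat$t, draws[s, ], spec$n_phases)
      zm <- logit(clamp(mu / 100, spec$eps, 1 - spec$eps))
      loglik[s, ] <- stats::dnorm(dat$z, zm, draws[s, "sigma"], log = TRUE)
    }
  }
  data_out <- list(time = series$time, neg = series$neg,
                   subject = series$subject, n_scope = n_scope)
  if (binom) data_out$increments <- inc else data_out$z <- dat$z
  structure(list(spec = spec, samples = samples, draws = draws,
                 loglik = loglik, data = data_out,
                 chains = chains, iter = iter, warmup = warmup, seed = seed,
                 n_params = length(vars)),
            class = "neg_phasefit")
}

#' @export
print.neg_phasefit <- function(x, ...) {
  cat(sprintf("Bayesian %d-phase sigmoid growth fit (%s family; %d chains x %d draws, %d obs)\n",
              x$spec$n_phases, x$spec$noise, x$chains, x$iter, ncol(x$loglik)))
  print(round(coef(x), 3))
  invisible(x)
}

#' @export
coef.neg_phasefit <- function(object, ...) {
  apply(object$draws, 2, stats::median)
}

#' @export
summary.neg_phasefit <- function(object, ...) {
  qs <- t(apply(object$draws, 2, stats::quantile, c(0.5, 0.025, 0.975)))
  colnames(qs) <- c("median", "q2.5", "q97.5")
  d <- diagnostics(object)
  cbind(as.data.frame(qs), rhat = d$rhat[rownames(qs)],
        ess = d$ess[rownames(qs)])
}

#' Posterior mean curve of a phase fit
#'
#' @param object a `neg_phasefit`.
#' @param times evaluation times (defaults to the fitted times).
#' @param level credible-band mass.
#' @param draws return the full draw matrix instead of summaries.
#' @param ... unused.
#' @return data frame `time`, `est`, `lower`, `upper` (posterior median
#'   and HDI of the mean curve), or a times x draws matrix.
#' @export
predict.neg_phasefit <- function(object, times = NULL, level = 0.95,
                                 draws = FALSE, ...) {
  times <- times %||% sort(unique(object$data$time))
  M <- apply(object$draws, 1, function(p)
    phase_mean_curve(times, p, object$spec$n_phases))
  M <- matrix(M, nrow = length(times))
  if (draws) return(M)
  h <- apply(M, 1, hdi, level = level)
  data.frame(time = times, est = apply(M, 1, stats::median),
             lower = h[1, ], upper = h[2, ])
}

#' @export
residuals.neg_phasefit <- function(object, ...) {
  med <- coef(object)
  if (object$spec$noise == "binomial") {
    inc <- object$data$increments
    q <- hazard_q(phase_mean_curve(inc$t, med, object$spec$n_phases),
                  phase_mean_curve(inc$tp, med, object$spec$n_phases))
    (inc$dk - inc$size * q) / sqrt(pmax(inc$size * q * (1 - q), 1e-12))
  } else {
    mu <- phase_mean_curve(object$data$time, med, object$spec$n_phases)
    object$data$z - logit(clamp(mu / 100, object$spec$eps, 1 - object$spec$eps))
  }
}

#' Posterior predictive NEG series
#'
#' Draws replicated series from the fitted observation model: for the
#' binomial family, first-visit hazard paths over each subject's time
#' grid; for the logit-normal family, Gaussian noise around the mean
#' curve on the logit scale.
#'
#' @param object a `neg_phasefit`.
#' @param nsim number of replicated series.
#' @param seed optional seed.
#' @param ... unused.
#' @return matrix of replicated NEG values (percent), one row per
#'   observation of the fitted series.
#' @export
simulate.neg_phasefit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(object$draws), nsim, replace = TRUE)
  tt <- object$data$time
  n <- object$data$n_scope
  sub <- object$data$subject %||% rep("s1", length(tt))
  blocks <- split(seq_along(tt), as.character(sub))
  out <- vapply(idx, function(s) {
    p <- object$draws[s, ]
    rep_y <- numeric(length(tt))
    for (b in blocks) {
      b <- b[order(tt[b])]
      mu <- phase_mean_curve(tt[b], p, object$spec$n_phases)
      if (object$spec$noise == "binomial") {
        mup <- c(0, mu[-length(mu)])
        K <- 0
        for (j in seq_along(b)) {
          q <- hazard_q(mu[j], mup[j])
          K <- K + stats::rbinom(1L, max(0L, n - K), q)
          rep_y[b[j]] <- 100 * K / n
        }
      } else {
        zm <- logit(clamp(mu / 100, object$spec$eps, 1 - object$spec$eps))
        rep_y[b] <- 100 * invlogit(stats::rnorm(length(b), zm, p[["sigma"]]))
      }
    }
    rep_y
  }, numeric(length(tt)))
  matrix(out, nrow = length(tt))
}

#' @export
plot.neg_phasefit <- function(x, ...) {
  pr <- predict(x)
  graphics::plot(x$data$time, x$data$neg, pch = 16, cex = 0.5,
                 xlab = "time (s)", ylab = "NEG (%)", ylim = c(0, 100), ...)
  graphics::polygon(c(pr$time, rev(pr$time)), c(pr$lower, rev(pr$upper)),
                    col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  graphics::lines(pr$time, pr$est, col = "steelblue", lwd = 2)
  invisible(x)
}

#' Convergence and fit diagnostics for a phase fit
#'
#' Pass requires every parameter's Rhat within `rhat_range` (the
#' tolerance used throughout this workflow is \[0.9, 1.1\]), every
#' effective sample size above `min_ess` (1000), and the posterior
#' predictive interval covering at least `min_coverage` of the observed
#' series.
#'
#' @param fit a `neg_phasefit`.
#' @param rhat_range admissible Rhat interval.
#' @param min_ess minimum effective sample size.
#' @param min_coverage minimum fraction of observations inside the 95%
#'   posterior predictive interval.
#' @param level predictive-interval mass.
#' @return a `neg_diagnostics` list: `pass`, per-parameter `rhat` and
#'   `ess`, `coverage`, `failures`.
#' @export
diagnostics <- function(fit, rhat_range = c(0.9, 1.1), min_ess = 1000,
                        min_coverage = 0.8, level = 0.95) {
  stopifnot(inherits(fit, "neg_phasefit"))
  rhat <- tryCatch(
    coda::gelman.diag(fit$samples, autoburnin = FALSE,
                      multivariate = FALSE)$psrf[, 1],
    error = function(e) {
      r <- rep(NA_real_, ncol(fit$draws)); names(r) <- colnames(fit$draws); r
    })
  ess <- tryCatch(coda::effectiveSize(fit$samples),
                  error = function(e) {
                    r <- rep(0, ncol(fit$draws)); names(r) <- colnames(fit$draws); r
                  })
  # near-constant parameters (e.g. amplitude pinned at a bound) can return
  # NaN Rhat; treat as converged-by-degeneracy
  rhat_ok <- is.na(rhat) | (rhat >= rhat_range[1] & rhat <= rhat_range[2])
  ess_ok <- ess > min_ess

  alpha <- (1 - level) / 2
  rep_mat <- simulate(fit, nsim = 200, seed = fit$seed + 1L)
  lo <- apply(rep_mat, 1, stats::quantile, alpha)
  hi <- apply(rep_mat, 1, stats::quantile, 1 - alpha)
  coverage <- mean(fit$data$neg >= lo - 1e-9 & fit$data$neg <= hi + 1e-9)

  failures <- character(0)
  if (!all(rhat_ok)) failures <- c(failures, paste0(
    "Rhat outside [", rhat_range[1], ", ", rhat_range[2], "]: ",
    paste(names(rhat)[!rhat_ok], collapse = ", ")))
  if (!all(ess_ok)) failures <- c(failures, paste0(
    "ESS <= ", min_ess, ": ", paste(names(ess)[!ess_ok], collapse = ", ")))
  if (coverage < min_coverage) failures <- c(failures, sprintf(
    "posterior predictive coverage %.2f below %.2f", coverage, min_coverage))
  structure(list(pass = length(failures) == 0L, rhat = rhat, ess = ess,
                 coverage = coverage, failures = failures),
            class = "neg_diagnostics")
}

#' @export
print.neg_diagnostics <- function(x, ...) {
  cat(sprintf("Diagnostics: %s\n", if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  Rhat: %s; ESS: %s; predictive coverage: %.2f\n",
              paste(sprintf("%.3f", x$rhat), collapse = " "),
              paste(sprintf("%.0f", x$ess), collapse = " "), x$coverage))
  for (f in x$failures) cat("  - ", f, "\n", sep = "")
  invisible(x)
}

#' Prior and posterior predictive checks
#'
#' Prior mode (`x` is a [phase_model_spec()]): draws parameter sets from
#' the priors, generates mean curves and reports the fraction that are
#' scientifically plausible - bounded in \[0, 100\], monotone, and with a
#' 10-to-90% rise time of at least 2 s (an absurdly fast rate yields a
#' step function no animal can produce).  Posterior mode (`x` is a
#' `neg_phasefit`): reports the posterior predictive envelope coverage of
#' the observed series.
#'
#' @param x a `phase_model_spec` or a `neg_phasefit`.
#' @param series observed series (posterior mode; defaults to the fitted
#'   data).
#' @param n_draws prior draws.
#' @param seed seed for the prior draws.
#' @return a `predictive_check` list with `mode`, `frac_plausible` or
#'   `coverage`, and `ok`.
#' @export
predictive_check <- function(x, series = NULL, n_draws = 500, seed = 1) {
  if (inherits(x, "phase_model_spec")) {
    set.seed(seed)
    tt <- seq(0, x$duration, length.out = 101)
    plausible <- logical(n_draws)
    inside <- logical(n_draws)
    for (s in seq_len(n_draws)) {
      np <- x$n_phases
      if (np == 1L) {
        k <- exp(stats::rnorm(1, x$priors$logk_mean, x$priors$logk_sd))
        kmax <- k
        curves <- sigmoid_mean(tt, k, stats::runif(1, 0, x$duration),
                               stats::runif(1, 0, 100))
      } else {
        A1 <- stats::runif(1, 0, 100); A2 <- stats::runif(1) * (100 - A1)
        k1 <- exp(stats::rnorm(1, x$priors$logk_mean, x$priors$logk_sd))
        k2 <- exp(stats::rnorm(1, x$priors$logk_mean, x$priors$logk_sd))
        kmax <- max(k1, k2)
        t01 <- stats::runif(1, 0, x$duration)
        t02 <- t01 + stats::runif(1, 0, x$duration - t01)
        curves <- sigmoid_mean(tt, k1, t01, A1) + sigmoid_mean(tt, k2, t02, A2)
      }
      inside[s] <- all(curves >= -1e-9 & curves <= 100 + 1e-9)
      mono <- all(diff(curves) >= -1e-9)
      # 10% -> 90% rise of a logistic phase takes ~4.39/k seconds
      plausible[s] <- inside[s] && mono && (4.39 / kmax) >= 2
    }
    out <- list(mode = "prior", frac_inside = mean(inside),
                frac_plausible = mean(plausible),
                ok = mean(plausible) >= 0.9 && mean(inside) >= 0.99)
  } else if (inherits(x, "neg_phasefit")) {
    rep_mat <- simulate(x, nsim = 200, seed = seed)
    obs <- (series %||% x$data)$neg
    lo <- apply(rep_mat, 1, stats::quantile, 0.025)
    hi <- apply(rep_mat, 1, stats::quantile, 0.975)
    cov <- mean(obs >= lo - 1e-9 & obs <= hi + 1e-9)
    out <- list(mode = "posterior", coverage = cov, ok = cov >= 0.8)
  } else stop("x must be a phase_model_spec or neg_phasefit")
  structure(out, class = "predictive_check")
}

#' @export
print.predictive_check <- function(x, ...) {
  if (x$mode == "prior")
    cat(sprintf("Prior predictive check: %.1f%% in bounds, %.1f%% plausible -> %s\n",
                100 * x$frac_inside, 100 * x$frac_plausible,
                if (x$ok) "OK" else "FLAGGED"))
  else
    cat(sprintf("Posterior predictive check: coverage %.2f -> %s\n",
                x$coverage, if (x$ok) "OK" else "FLAGGED"))
  invisible(x)
}

#' Compare phase models by PSIS-LOO
#'
#' Computes elpd_loo per candidate fit and applies the selection rule:
#' the model with the higher elpd_loo is preferred; when elpd_loo values
#' are equivalent, the most parsimonious model is selected.  Equivalence
#' follows the standard LOO guidance: an absolute difference below 4
#' elpd units is negligible, and a larger one is only meaningful when it
#' exceeds twice its standard error (computed from the pointwise
#' differences).  Only fits passing [diagnostics()] are eligible.
#'
#' @param fits named list of `neg_phasefit` objects fitted to the same
#'   series.
#' @param check require diagnostics to pass for eligibility.
#' @param ... forwarded to [diagnostics()].
#' @return a `neg_model_comparison`: per-model table, the selected model
#'   name and the selection rationale.
#' @export
compare_models <- function(fits, check = TRUE, ...) {
  stopifnot(length(fits) >= 2L, all(vapply(fits, inherits, logical(1), "neg_phasefit")))
  if (is.null(names(fits)))
    names(fits) <- paste0("phase", vapply(fits, function(f) f$spec$n_phases, integer(1)))
  eligible <- rep(TRUE, length(fits))
  if (check)
    eligible <- vapply(fits, function(f) diagnostics(f, ...)$pass, logical(1))
  if (!any(eligible)) stop("no candidate model passed the diagnostics")
  loos <- lapply(fits, function(f) psis_loo(f$loglik))
  tab <- data.frame(
    model = names(fits),
    n_phases = vapply(fits, function(f) f$spec$n_phases, integer(1)),
    n_params = vapply(fits, function(f) f$n_params, integer(1)),
    elpd_loo = vapply(loos, function(l) l$elpd_loo, numeric(1)),
    se = vapply(loos, function(l) l$se, numeric(1)),
    p_loo = vapply(loos, function(l) l$p_loo, numeric(1)),
    max_pareto_k = vapply(loos, function(l) max(l$pareto_k, na.rm = TRUE), numeric(1)),
    eligible = eligible)
  el <- which(eligible)
  best <- el[which.max(tab$elpd_loo[el])]
  # equivalence: |delta elpd| <= max(4, 2 SE(delta)), the usual LOO rule
  equiv <- vapply(el, function(i) {
    if (i == best) return(TRUE)
    d <- loos[[best]]$pointwise - loos[[i]]$pointwise
    abs(sum(d)) <= max(4, 2 * sqrt(length(d) * stats::var(d)))
  }, logical(1))
  cand <- el[equiv]
  selected <- cand[which.min(tab$n_params[cand])]
  rationale <- if (length(cand) > 1L)
    sprintf("elpd_loo equivalent (|diff| <= max(4, 2 SE)); most parsimonious model '%s' selected",
            tab$model[selected])
  else
    sprintf("'%s' has a decisively higher elpd_loo", tab$model[selected])
  structure(list(table = tab, selected = tab$model[selected],
                 selected_n_phases = tab$n_phases[selected],
                 rationale = rationale, loos = loos),
            class = "neg_model_comparison")
}

#' @export
print.neg_model_comparison <- function(x, ...) {
  cat("Phase-model comparison (PSIS-LOO)\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat("selected:", x$selected, "-", x$rationale, "\n")
  invisible(x)
}
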