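#' Assemble effect-model data from simulated or computed NEG series
#'
#' Restructures a long NEG table into the counts-out-of-segments format
#' used by [fit_neg_effects()]: one row per subject and second with the
#' visited-segment count, the scope size, and the grouping factor
#' (phenotype by default, or arm type for within-phenotype contrasts).
#'
#' @param sim a `neg_sim` data frame from [simulate_neg()] (rows from
#'   several phenotypes may be concatenated with `rbind`), or any long
#'   data frame with `subject`, `time`, `scope`, `neg` and either `count`
#'   + `n` columns or an `n_scope` attribute.
#' @param scope which scope to model (ignored when `group = "scope"`).
#' @param group grouping variable: `"phenotype"` or `"scope"` (arm-type
#'   contrasts use the open and closed scopes as groups).
#' @return data frame with `subject`, `group`, `time`, `visited`, `n`.
#' @export
neg_effects_data <- function(sim, scope = c("total", "open", "closed"),
                             group = c("phenotype", "scope")) {
  group <- match.arg(group)
  scope <- match.arg(scope)
  d <- if (group == "phenotype") sim[sim$scope == scope, , drop = FALSE]
       else sim[sim$scope %in% c("open", "closed"), , drop = FALSE]
  if (!nrow(d)) stop("no rows for the requested scope")
  if (is.null(d$count) || is.null(d$n)) {
    n <- attr(sim, "n_scope") %||% stop("need count/n columns or an n_scope attribute")
    d$n <- n
    d$count <- round(d$neg / 100 * n)
  }
  out <- data.frame(subject = factor(d$subject),
                    group = factor(d[[group]]),
                    time = d$time,
                    visited = round(d$count), n = d$n)
  attr(out, "group_var") <- group
  out
}

#' Fit a Bayesian effect model for NEG over time
#'
#' Models visited-segment counts out of the scope total with a binomial
#' (logit) likelihood.  When the change-point stage selected single-phase
#' growth for every series, the mean structure is a generalised linear
#' mixed model with a group-by-time interaction (a single logistic growth
#' phase is linear on the logit scale).  When any series is multiphase,
#' a generalised additive structure with one thin-plate smooth of time
#' per group is used instead.  Both include subject-level random
#' intercepts.  Fitted with `mgcv::gam` under a quasibinomial family (the
#' cumulative counts are overdispersed relative to pure binomial
#' sampling); posterior draws of all coefficients come from the Gaussian
#' approximation N(coefficients, Vp), the Bayesian view of the penalised
#' fit.
#'
#' @param data a data frame from [neg_effects_data()].
#' @param structure `"multiphase"` (GAM, default) or `"single-phase"`
#'   (GLMM), normally taken from [compare_models()]'s selection.
#' @param basis thin-plate basis size per group smooth.
#' @param seed stored and used for posterior draws downstream.
#' @return a `neg_effects` object wrapping the fitted `gam`.
#' @export
fit_neg_effects <- function(data, structure = c("multiphase", "single-phase"),
                            basis = 10, seed = 1) {
  structure <- match.arg(structure)
  stopifnot(all(c("subject", "group", "time", "visited", "n") %in% names(data)))
  data$group <- droplevels(factor(data$group))
  data$subject <- droplevels(factor(data$subject))
  if (nlevels(data$group) < 2L)
    stop("at least two groups are required to estimate a contrast")
  # Haldane-Anscombe continuity correction: groups that never (or always)
  # explore a scope otherwise give divergent logits with unbounded
  # variance under the Gaussian coefficient posterior
  data$succ <- data$visited + 0.5
  data$fail <- data$n - data$visited + 0.5
  form <- if (structure == "multiphase")
    cbind(succ, fail) ~ group + s(time, by = group, k = basis, bs = "tp") +
      s(subject, bs = "re")
  else
    cbind(succ, fail) ~ group * time + s(subject, bs = "re")
  fit <- mgcv::gam(form, data = data, family = stats::quasibinomial(),
                   method = "REML")
  structure(list(gam = fit, structure = structure, basis = basis,
                 groups = levels(data$group), seed = seed,
                 group_var = attr(data, "group_var") %||% "group",
                 n_scope = data$n[1L], data = data),
            class = "neg_effects")
}

#' @export
print.neg_effects <- function(x, ...) {
  cat(sprintf("NEG effect model (%s; quasibinomial, %d groups: %s)\n",
              x$structure, length(x$groups), paste(x$groups, collapse = ", ")))
  cat(sprintf("  %d observations, scope size %d, subject random intercepts\n",
              nrow(x$data), x$n_scope))
  invisible(x)
}

#' @export
summary.neg_effects <- function(object, ...) summary(object$gam, ...)

#' @export
coef.neg_effects <- function(object, ...) stats::coef(object$gam)

#' Posterior fitted proportions per group over time
#'
#' @param object a `neg_effects` model.
#' @param times evaluation grid (seconds).
#' @param n_draws posterior coefficient draws.
#' @param seed seed for the draws (defaults to the model's).
#' @param ... unused.
#' @return list with `times`, `groups`, and `prop`: a named list of
#'   times x draws matrices of fitted scope proportions, marginal over
#'   subjects (random intercepts excluded).
#' @export
predict.neg_effects <- function(object, times = NULL, n_draws = 4000,
                                seed = NULL, ...) {
  times <- times %||% sort(unique(object$data$time))
  set.seed(seed %||% object$seed)
  g <- object$gam
  B <- rmvn(n_draws, stats::coef(g), g$Vp)
  re_cols <- grep("^s\\(subject\\)", names(stats::coef(g)))
  prop <- lapply(object$groups, function(lev) {
    nd <- data.frame(time = times, group = factor(lev, levels = object$groups),
                     subject = object$data$subject[1L])
    X <- stats::predict(g, newdata = nd, type = "lpmatrix")
    X[, re_cols] <- 0  # population-level curve
    invlogit(X %*% t(B))
  })
  names(prop) <- object$groups
  list(times = times, groups = object$groups, prop = prop, n_draws = n_draws)
}

#' Posterior contrast between two groups over time
#'
#' Difference of the groups' fitted NEG curves on the percent scale
#' (inverse-linked before differencing), with the full posterior draw
#' matrix retained for SeXiT summaries.
#'
#' @param model a `neg_effects` model.
#' @param contrast character vector `c(A, B)`: the effect is A - B.
#' @param times evaluation grid in seconds (default 1-s steps over the
#'   data range).
#' @param n_draws posterior draws.
#' @param seed seed for the coefficient draws.
#' @return a `neg_effect_series`: `times`, percent-scale draw matrix
#'   (times x draws), and the two groups' fitted proportion draws.
#' @export
contrast_over_time <- function(model, contrast, times = NULL, n_draws = 4000,
                               seed = NULL) {
  stopifnot(inherits(model, "neg_effects"), length(contrast) == 2L)
  missing_g <- setdiff(contrast, model$groups)
  if (length(missing_g))
    stop("unknown group label(s): ", paste(missing_g, collapse = ", "))
  pr <- predict(model, times = times, n_draws = n_draws, seed = seed)
  pA <- pr$prop[[contrast[1L]]]
  pB <- pr$prop[[contrast[2L]]]
  structure(list(times = pr$times, contrast = contrast,
                 label = paste(contrast, collapse = " - "),
                 draws = 100 * (pA - pB), pA = pA, pB = pB,
                 n_scope = model$n_scope),
            class = "neg_effect_series")
}

#' @export
print.neg_effect_series <- function(x, ...) {
  cat(sprintf("Effect series %s: %d timepoints x %d draws (percent NEG)\n",
              x$label, length(x$times), ncol(x$draws)))
  invisible(x)
}

#' Region of practical equivalence
#'
#' For conventional (Gaussian-linear) outcomes the ROPE is
#' `[-0.1 SD_y, 0.1 SD_y]` on the response scale.  For growth (binomial
#' logistic) models it is `[-0.18, 0.18]`, applied by default on the
#' proportion response scale - i.e. an effect within +/-18 NEG percentage
#' points is practically equivalent to zero; a logit-scale variant is
#' available.
#'
#' @param family `"growth"` or `"linear"`.
#' @param sd_y response standard deviation (required for `"linear"`).
#' @param scale for growth models: `"proportion"` (default) or `"logit"`.
#' @return a `rope_interval`: `low`, `high`, `scale`.
#' @export
build_rope <- function(family = c("growth", "linear"), sd_y = NULL,
                       scale = c("proportion", "logit")) {
  family <- match.arg(family)
  if (family == "linear") {
    if (is.null(sd_y)) stop("the linear ROPE requires sd_y")
    if (sd_y <= 0) stop("sd_y must be positive")
    out <- list(low = -0.1 * sd_y, high = 0.1 * sd_y, scale = "linear")
  } else {
    out <- list(low = -0.18, high = 0.18, scale = match.arg(scale))
  }
  structure(out, class = "rope_interval")
}

#' @export
print.rope_interval <- function(x, ...) {
  cat(sprintf("ROPE [%g, %g] on the %s scale\n", x$low, x$high, x$scale))
  invisible(x)
}

# One-timepoint SeXiT summary from a draw vector (d on the decision scale,
# x on the reporting scale).
sexit_row <- function(x, d, rope, hdi_level) {
  h <- hdi(x, hdi_level)
  frac <- mean(d >= rope$low & d <= rope$high)
  decision <- if (frac > 0.975) "equivalent"
              else if (frac < 0.025) "not-equivalent" else "undecided"
  data.frame(median = stats::median(x), hdi_low = h[[1L]], hdi_high = h[[2L]],
             pd = pd_value(d), rope_frac = frac, decision = decision)
}

#' SeXiT effect summary with ROPE equivalence decisions
#'
#' Sequential effect existence and significance testing: per timepoint the
#' posterior median, 95% HDI, probability of direction, the fraction of
#' the posterior inside the ROPE, and the three-way decision - equivalent
#' when more than 97.5% of the posterior lies inside the ROPE,
#' not-equivalent when less than 2.5% does, undecided otherwise.  The
#' effect is mapped onto the ROPE's scale before comparison (percent
#' draws / 100 for a proportion ROPE; difference of clamped logits for a
#' logit ROPE).
#'
#' @param series a `neg_effect_series` from [contrast_over_time()], or a
#'   plain numeric vector / one-row matrix of draws for a static effect.
#' @param rope a [build_rope()] interval.
#' @param hdi_level HDI mass (default 0.95).
#' @param eps proportion clamp for the logit mapping (default: half of
#'   one grid segment, the smallest resolvable exploration difference).
#' @return a `neg_decisions` data frame: `time`, `median`, `hdi_low`,
#'   `hdi_high`, `pd`, `rope_frac`, `decision`.
#' @export
sexit <- function(series, rope, hdi_level = 0.95, eps = NULL) {
  stopifnot(inherits(rope, "rope_interval"))
  if (is.numeric(series) && is.null(dim(series)))
    series <- list(times = NA_real_, draws = matrix(series, nrow = 1L))
  if (inherits(series, "neg_effect_series") || is.list(series)) {
    times <- series$times
    draws <- series$draws
    rows <- lapply(seq_along(times), function(i) {
      x <- draws[i, ]
      d <- switch(rope$scale,
        proportion = x / 100,
        logit = {
          e <- eps %||% (0.5 / (series$n_scope %||% 100))
          logit(clamp(series$pA[i, ], e, 1 - e)) -
            logit(clamp(series$pB[i, ], e, 1 - e))
        },
        linear = x)
      sexit_row(x, d, rope, hdi_level)
    })
    out <- cbind(data.frame(time = times), do.call(rbind, rows))
  } else stop("series must be a neg_effect_series or a vector of draws")
  attr(out, "rope") <- rope
  attr(out, "label") <- series$label %||% NA_character_
  class(out) <- c("neg_decisions", "data.frame")
  out
}

#' Landmark times of an equivalence-decision series
#'
#' @param dec a `neg_decisions` data frame from [sexit()].
#' @return a `neg_landmarks` list: `onset_not_equivalent` (earliest time
#'   the effect is declared not practically equivalent; NA if never),
#'   `return_to_equivalent` (earliest time the decision returns to
#'   equivalent after a not-equivalent spell; NA if never), and
#'   `durations`, the total time spent in each decision state.
#' @export
decision_landmarks <- function(dec) {
  stopifnot(inherits(dec, "neg_decisions"))
  dec <- dec[order(dec$time), ]
  dt <- if (nrow(dec) > 1L) stats::median(diff(dec$time)) else 1
  onset_i <- which(dec$decision == "not-equivalent")[1L]
  onset <- if (is.na(onset_i)) NA_real_ else dec$time[onset_i]
  ret <- NA_real_
  if (!is.na(onset_i)) {
    after <- which(dec$decision == "equivalent" & seq_len(nrow(dec)) > onset_i)
    if (length(after)) ret <- dec$time[after[1L]]
  }
  durations <- vapply(c("equivalent", "not-equivalent", "undecided"),
                      function(s) sum(dec$decision == s) * dt, numeric(1))
  structure(list(onset_not_equivalent = onset, return_to_equivalent = ret,
                 durations = durations),
            class = "neg_landmarks")
}

#' @export
print.neg_landmarks <- function(x, ...) {
  cat(sprintf("significance onset: %s s; return to equivalence: %s s\n",
              format(x$onset_not_equivalent), format(x$return_to_equivalent)))
  cat("time per state (s): ",
      paste(names(x$durations), round(x$durations, 1), sep = " = ",
            collapse = "; "), "\n")
  invisible(x)
}

#' Plot an effect series with its ROPE band
#'
#' Ribbon of the effect posterior over time with the ROPE band and the
#' per-timepoint decision colouring.
#'
#' @param x a `neg_decisions` data frame.
#' @param ... passed to [graphics::plot()].
#' @export
plot.neg_decisions <- function(x, ...) {
  rope <- attr(x, "rope")
  band <- if (rope$scale == "proportion") c(rope$low, rope$high) * 100
          else c(rope$low, rope$high)
  graphics::plot(x$time, x$median, type = "n",
                 ylim = range(c(x$hdi_low, x$hdi_high, band)),
                 xlab = "time (s)", ylab = "effect (NEG %)", ...)
  graphics::polygon(c(x$time, rev(x$time)), c(x$hdi_low, rev(x$hdi_high)),
                    col = grDevices::adjustcolor("grey60", 0.4), border = NA)
  graphics::abline(h = band, lty = 2)
  cols <- c(equivalent = "grey30", undecided = "goldenrod",
            `not-equivalent` = "firebrick")
  graphics::points(x$time, x$median, col = cols[x$decision], pch = 16, cex = 0.4)
  invisible(x)
}

#' Bayesian linear regression of conventional measures on phenotype
#'
#' Fits, per measure, a linear model with phenotype as the predictor
#' (conjugate normal-inverse-chi-squared posterior under the reference
#' prior) and summarises every pairwise phenotype contrast with [sexit()]
#' against the linear ROPE `[-0.1 SD_y, 0.1 SD_y]`.
#'
#' @param draws data frame from [simulate_conventional()] (or measured
#'   data) with `phenotype` and the three measure columns.
#' @param measures columns to analyse.
#' @param n_draws posterior draws per model.
#' @param seed integer seed.
#' @return a `neg_conventional_decisions` data frame: one row per measure
#'   and phenotype pair with the SeXiT summary and decision.
#' @export
fit_conventional_effects <- function(draws,
                                     measures = c("latency_open", "entries_open", "time_open"),
                                     n_draws = 4000, seed = 1) {
  stopifnot("phenotype" %in% names(draws))
  draws$phenotype <- factor(draws$phenotype)
  if (nlevels(draws$phenotype) < 2L) stop("need at least two phenotypes")
  set.seed(seed)
  levs <- levels(draws$phenotype)
  pairs <- utils::combn(levs, 2L, simplify = FALSE)
  out <- list()
  for (m in measures) {
    y <- draws[[m]]
    X <- stats::model.matrix(~ phenotype, draws)
    fit <- stats::lm.fit(X, y)
    n <- length(y); p <- ncol(X)
    s2 <- sum(fit$residuals^2) / (n - p)
    XtXi <- chol2inv(chol(crossprod(X)))
    sig2 <- (n - p) * s2 / stats::rchisq(n_draws, n - p)
    Z <- matrix(stats::rnorm(n_draws * p), n_draws, p) %*% chol(XtXi)
    beta <- rep(fit$coefficients, each = n_draws) + Z * sqrt(sig2)
    colnames(beta) <- colnames(X)
    # group means per draw
    L <- stats::model.matrix(~ phenotype, data.frame(phenotype = factor(levs, levels = levs)))
    mu <- beta %*% t(L)  # n_draws x groups
    colnames(mu) <- levs
    rope <- build_rope("linear", sd_y = stats::sd(y))
    for (pr in pairs) {
      d <- mu[, pr[1L]] - mu[, pr[2L]]
      row <- sexit_row(d, d, rope, 0.95)
      out[[length(out) + 1L]] <- cbind(
        data.frame(measure = m, contrast = paste(pr, collapse = " - ")), row)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("neg_conventional_decisions", "data.frame")
  out
}
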