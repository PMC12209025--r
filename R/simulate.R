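#' Anchored sigmoid mean curve
#'
#' Expected cumulative exploration (percent of scope) at time `t` for one
#' arm type: a logistic growth curve with rate `k` (1/s) and inflexion
#' `t0` (s), shifted and rescaled so the curve is exactly 0 at `t = 0`
#' (a raw sigmoid is positive at test onset, but nothing has been explored
#' yet) and approaches the asymptote `A`.
#'
#' @param t times in seconds.
#' @param k growth rate (1/s); `k = 0` (or `A = 0`) gives a flat zero
#'   curve, the avoidant open-arm case.
#' @param t0 inflexion time (s).
#' @param A asymptote in percent (default 100).
#' @return numeric vector of expected NEG percentages.
#' @export
sigmoid_mean <- function(t, k, t0, A = 100) {
  if (k <= 0 || A <= 0) return(rep(0, length(t)))
  F <- function(u) 1 / (1 + exp(-k * (u - t0)))
  F0 <- F(0)
  A * (F(t) - F0) / (1 - F0)
}

#' Default phenotype simulation parameters
#'
#' Per-arm-type sigmoid growth parameters for the three behavioural
#' phenotypes, used as the generating model of the simulation study:
#' \describe{
#'   \item{exploratory}{arm-agnostic: open and closed arms share the same
#'     rate and inflexion (k = 0.1/s, t0 = 30 s).}
#'   \item{delayed}{closed arms first (t0 = 30 s); open-arm exploration in
#'     a later phase with its inflexion at the test mid-point
#'     (t0 = 150 s for a 300-s test).}
#'   \item{avoidant}{no open-arm exploration: open growth rate and
#'     inflexion are 0 (flat zero curve).}
#' }
#' Between-subject variability draws each subject's rate and inflexion
#' from truncated Gaussians around these values (sd 0.02/s and 15 s).
#'
#' @param phenotype `"exploratory"`, `"delayed"` or `"avoidant"`.
#' @param duration test duration in seconds (default 300).
#' @param k_open,k_closed,t0_open,t0_closed,A_open,A_closed overrides of
#'   the per-arm sigmoid parameters.
#' @param sd_k,sd_t0 between-subject standard deviations of rate and
#'   inflexion.
#' @param noise draw visited-segment counts stochastically (binomial
#'   first-visit hazard); `FALSE` returns the mean curves.
#' @return a `phenotype_params` object.
#' @export
phenotype_params <- function(phenotype = c("exploratory", "delayed", "avoidant"),
                             duration = 300,
                             k_open = NULL, k_closed = NULL,
                             t0_open = NULL, t0_closed = NULL,
                             A_open = NULL, A_closed = NULL,
                             sd_k = 0.02, sd_t0 = 15, noise = TRUE) {
  phenotype <- match.arg(phenotype)
  def <- switch(phenotype,
    exploratory = list(k_open = 0.1, k_closed = 0.1, t0_open = 30, t0_closed = 30,
                       A_open = 100, A_closed = 100),
    delayed     = list(k_open = 0.1, k_closed = 0.1,
                       t0_open = duration / 2, t0_closed = 30,
                       A_open = 100, A_closed = 100),
    avoidant    = list(k_open = 0, k_closed = 0.1, t0_open = 0, t0_closed = 30,
                       A_open = 0, A_closed = 100))
  p <- list(phenotype = phenotype, duration = duration,
            open = list(k = k_open %||% def$k_open, t0 = t0_open %||% def$t0_open,
                        A = A_open %||% def$A_open),
            closed = list(k = k_closed %||% def$k_closed,
                          t0 = t0_closed %||% def$t0_closed,
                          A = A_closed %||% def$A_closed),
            sd_k = sd_k, sd_t0 = sd_t0, noise = noise)
  if (p$open$k < 0 || p$closed$k < 0) stop("growth rates must be non-negative")
  if (p$closed$t0 < 0 || p$closed$t0 > duration ||
      p$open$t0 < 0 || p$open$t0 > duration)
    stop("inflexion points must lie within [0, duration]")
  structure(p, class = "phenotype_params")
}

#' @rdname phenotype_params
#' @export
default_params <- phenotype_params

#' @export
print.phenotype_params <- function(x, ...) {
  cat(sprintf("Phenotype '%s' (%g s test)\n", x$phenotype, x$duration))
  cat(sprintf("  open:   k = %g /s, t0 = %g s, A = %g%%\n",
              x$open$k, x$open$t0, x$open$A))
  cat(sprintf("  closed: k = %g /s, t0 = %g s, A = %g%%\n",
              x$closed$k, x$closed$t0, x$closed$A))
  cat(sprintf("  between-subject sd: k %g, t0 %g; noise %s\n",
              x$sd_k, x$sd_t0, if (x$noise) "on" else "off"))
  invisible(x)
}

# First-visit count path with mean exactly mu(t): each still-unvisited
# segment is first visited during second t with hazard
#   q_t = (mu_t - mu_{t-1}) / (n - mu_{t-1}),
# so K_t = K_{t-1} + Binomial(n - K_{t-1}, q_t).  Monotone by construction
# and E[K_t] = mu_t for every t.
sim_first_visit_counts <- function(mu_pct, n) {
  mu <- mu_pct / 100 * n
  K <- numeric(length(mu))
  prev_mu <- 0; prev_K <- 0
  for (i in seq_along(mu)) {
    denom <- n - prev_mu
    q <- if (denom <= 1e-12) 1 else clamp((mu[i] - prev_mu) / denom, 0, 1)
    K[i] <- prev_K + stats::rbinom(1L, max(0L, as.integer(n - prev_K)), q)
    prev_mu <- mu[i]; prev_K <- K[i]
  }
  K
}

#' Simulate per-subject NEG series for a phenotype
#'
#' Each subject receives arm-type sigmoid parameters drawn around the
#' phenotype's values (truncated Gaussians; the avoidant open-arm curve
#' stays exactly zero), an expected curve per arm type, and - when noise is
#' on - a monotone visited-segment count path whose mean equals the
#' expected curve (binomial first-visit hazard model).  The total-maze
#' series is derived from the two arm-type series through the composite
#' identity (total counts = open counts + closed counts).
#'
#' @param params a [phenotype_params()] object.
#' @param geometry an [epm_geometry()].
#' @param n_subjects number of subjects.
#' @param seed integer seed; identical inputs and seed give identical
#'   output.
#' @param subject_prefix label prefix for subject ids.
#' @return a long data frame (class `neg_sim`) with columns `subject`,
#'   `phenotype`, `scope`, `time`, `count`, `n`, `neg`.
#' @export
simulate_neg <- function(params, geometry = epm_geometry(), n_subjects = 10,
                         seed = 1, subject_prefix = NULL) {
  stopifnot(inherits(params, "phenotype_params"), n_subjects >= 1)
  set.seed(seed)
  n_arm <- n_segments(geometry, "open")  # per arm type (== closed)
  tt <- 0:params$duration
  prefix <- subject_prefix %||% substr(params$phenotype, 1, 3)
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    draw_arm <- function(arm) {
      if (arm$k <= 0 || arm$A <= 0) return(list(k = 0, t0 = 0, A = 0))
      list(k = rtruncnorm(1, arm$k, params$sd_k, 1e-3, Inf),
           t0 = rtruncnorm(1, arm$t0, params$sd_t0, 0, params$duration),
           A = arm$A)
    }
    po <- draw_arm(params$open); pc <- draw_arm(params$closed)
    mu_o <- sigmoid_mean(tt, po$k, po$t0, po$A)
    mu_c <- sigmoid_mean(tt, pc$k, pc$t0, pc$A)
    if (params$noise) {
      ko <- sim_first_visit_counts(mu_o, n_arm)
      kc <- sim_first_visit_counts(mu_c, n_arm)
    } else {
      ko <- mu_o / 100 * n_arm
      kc <- mu_c / 100 * n_arm
    }
    sid <- sprintf("%s%02d", prefix, s)
    out[[s]] <- data.frame(
      subject = sid, phenotype = params$phenotype,
      scope = rep(c("open", "closed", "total"), each = length(tt)),
      time = rep(tt, 3L),
      count = c(ko, kc, ko + kc),
      n = rep(c(n_arm, n_arm, 2L * n_arm), each = length(tt)))
  }
  out <- do.call(rbind, out)
  out$neg <- 100 * out$count / out$n
  attr(out, "params") <- params
  attr(out, "n_arm") <- n_arm
  class(out) <- c("neg_sim", "data.frame")
  out
}

#' Pool a simulated cohort into one group-level NEG series
#'
#' Group-pooled input for the change-point models.  The default
#' (`method = "stack"`) keeps every subject's observations, so the
#' observation noise absorbs between-subject variability and the phase
#' comparison judges the group's phase structure rather than chasing the
#' shape of an averaged curve (the mean of sigmoids with spread
#' inflexions is not itself a sigmoid).  `method = "mean"` returns the
#' across-subject mean NEG at each second.
#'
#' @param sim a `neg_sim` data frame from [simulate_neg()], or any long
#'   data frame with `subject`, `scope`, `time`, `neg`.
#' @param scope which scope to pool.
#' @param method `"stack"` (all subject observations) or `"mean"`.
#' @return a `neg_series` data frame (stacked series keep a `subject`
#'   column; monotonicity holds within each subject).
#' @export
pool_neg <- function(sim, scope = c("total", "open", "closed"),
                     method = c("stack", "mean")) {
  scope <- match.arg(scope)
  method <- match.arg(method)
  d <- sim[sim$scope == scope, , drop = FALSE]
  if (!nrow(d)) stop("no rows for scope ", scope)
  if (method == "mean") {
    agg <- stats::aggregate(neg ~ time, data = d, FUN = mean)
    agg <- agg[order(agg$time), ]
    out <- data.frame(time = agg$time, neg = agg$neg)
  } else {
    out <- data.frame(subject = d$subject, time = d$time, neg = d$neg)
    out <- out[order(out$subject, out$time), ]
    rownames(out) <- NULL
  }
  attr(out, "scope") <- scope
  attr(out, "n_scope") <- if (!is.null(d$n)) d$n[1L] else NA_integer_
  attr(out, "subject_id") <- "pooled"
  class(out) <- c("neg_series", "data.frame")
  out
}

# Default truncated-Gaussian parameters (mean, sd) of the conventional
# open-arm measures per phenotype.  Exploratory and delayed share the
# entries and time distributions and differ only in latency; the avoidant
# phenotype never enters (latency pinned at the full test duration,
# entries and time identically zero).
conventional_defaults <- function(duration = 300) {
  list(
    exploratory = list(latency_open = c(30, 20), entries_open = c(8, 3),
                       time_open = c(90, 30)),
    delayed     = list(latency_open = c(duration / 2 + 10, 30),
                       entries_open = c(8, 3), time_open = c(90, 30)),
    avoidant    = list(latency_open = c(duration, 0), entries_open = c(0, 0),
                       time_open = c(0, 0)))
}

#' Simulate conventional open-arm measures
#'
#' Draws the three conventional measures per phenotype from Gaussians
#' truncated to \[0, duration\] (inverse-CDF sampling), replicating the
#' simulation study's 1000-repetition design.  All draws are bounded in
#' \[0, duration\]; avoidant entries and open-arm time are identically 0
#' and its latency equals the test duration.
#'
#' @param n_reps draws per phenotype (default 1000).
#' @param duration test duration in seconds.
#' @param config optional override: a list per phenotype of
#'   `list(latency_open = c(mean, sd), entries_open = ..., time_open = ...)`.
#' @param seed integer seed.
#' @return data frame with columns `phenotype`, `rep`, `latency_open`,
#'   `entries_open`, `time_open`.
#' @export
simulate_conventional <- function(n_reps = 1000, duration = 300,
                                  config = NULL, seed = 1) {
  stopifnot(n_reps >= 1)
  cfg <- config %||% conventional_defaults(duration)
  bad <- vapply(cfg, function(ph) any(vapply(ph, function(v)
    v[1] < 0 || v[1] > duration || v[2] < 0, logical(1))), logical(1))
  if (any(bad)) stop("means must lie in [0, duration] and sds be non-negative")
  set.seed(seed)
  out <- lapply(names(cfg), function(ph) {
    m <- cfg[[ph]]
    data.frame(phenotype = ph, rep = seq_len(n_reps),
               latency_open = rtruncnorm(n_reps, m$latency_open[1], m$latency_open[2], 0, duration),
               entries_open = rtruncnorm(n_reps, m$entries_open[1], m$entries_open[2], 0, duration),
               time_open = rtruncnorm(n_reps, m$time_open[1], m$time_open[2], 0, duration))
  })
  out <- do.call(rbind, out)
  attr(out, "duration") <- duration
  out
}

#' Generate a coordinate trajectory realising given NEG curves
#'
#' Builds a maze-frame path whose discretisation reproduces the input
#' per-arm-type NEG curves.  Exploration runs in arm-type blocks ordered
#' by curve onset; within a block the animal enters arm 1, moves outward
#' reaching each new segment on the curve's schedule (idling at the
#' frontier between scheduled visits), then - following the
#' full-exploration-then-exit heuristic - crosses through the centre into
#' arm 2 and completes it, so a fully explored open-arm pair yields
#' exactly two open-arm entries.  Movement is hold-then-dash at constant
#' `speed` regardless of arm type; the arm-1 schedule is advanced by half
#' the arm-to-arm transit time so the crossing lag is balanced around the
#' schedule.
#'
#' A single animal cannot grow two arm-type curves at literally the same
#' instant, so blocks whose schedules overlap (the exploratory phenotype)
#' are serialised; round-trip fidelity holds for curves whose arm-type
#' phases are separated or single.
#'
#' @param neg_open,neg_closed `neg_series` (or data frames with `time`,
#'   `neg`) for the open and closed arm types of one subject.
#' @param geometry an [epm_geometry()].
#' @param speed locomotion speed in cm/s (> 0).
#' @param frame_rate output sampling rate in Hz (25 recommended).
#' @param max_lag generation error if the realised first-visit time of any
#'   segment falls more than this many seconds behind schedule (the curve
#'   then requires a speed above the configured one).
#' @param policy `"follow"` reproduces the curves' schedule and errors when
#'   infeasible; `"heuristic"` reproduces only the conventional-measure
#'   heuristic (enter each arm-type block at its onset, full exploration
#'   at constant speed, immediate exit) and never errors on schedule slip
#'   - the mode used to study latency/entries/time rather than curve
#'   shape.
#' @return a [tracking_series()] spanning the curves' time range.
#' @export
simulate_trajectory <- function(neg_open, neg_closed, geometry = epm_geometry(),
                                speed = 20, frame_rate = 25, max_lag = 10,
                                policy = c("follow", "heuristic")) {
  policy <- match.arg(policy)
  if (policy == "heuristic") max_lag <- Inf
  if (speed <= 0) stop("speed must be positive")
  res <- geometry$resolution
  n <- geometry$n_per_arm
  half <- geometry$centre_size / 2
  duration <- max(neg_open$time, neg_closed$time)

  sched <- function(series, n_type) {
    cnt <- round(series$neg / 100 * n_type)
    cnt <- cummax(clamp(cnt, 0, n_type))
    vapply(seq_len(max(cnt)), function(j) min(series$time[cnt >= j]),
           numeric(1))
  }
  s_open <- if (max(neg_open$neg) > 0) sched(neg_open, 2L * n) else numeric(0)
  s_closed <- if (max(neg_closed$neg) > 0) sched(neg_closed, 2L * n) else numeric(0)

  blocks <- list()
  if (length(s_closed)) blocks <- c(blocks, list(list(type = "closed", s = s_closed)))
  if (length(s_open)) blocks <- c(blocks, list(list(type = "open", s = s_open)))
  if (length(blocks) == 2L && min(s_open) < min(s_closed)) blocks <- rev(blocks)

  # unit direction of arm (type, index); open axis default x
  arm_dir <- function(type, index) {
    sgn <- if (index == 1L) 1 else -1
    on_x <- (type == "open") == (geometry$open_axis == "x")
    if (on_x) c(sgn, 0) else c(0, sgn)
  }
  pos_at <- function(type, index, depth_cm) arm_dir(type, index) * (half + depth_cm)

  wp_t <- 0; wp_x <- 0; wp_y <- 0  # start at the maze centre
  t_cur <- 0; p_cur <- c(0, 0)
  push <- function(t, p) {
    wp_t <<- c(wp_t, t); wp_x <<- c(wp_x, p[1]); wp_y <<- c(wp_y, p[2])
    t_cur <<- t; p_cur <<- p
  }
  # hold at current position, then dash at `speed` to p, arriving at t_target
  # (or as soon as possible); returns the arrival time
  move_to <- function(p, t_target) {
    d <- sqrt(sum((p - p_cur)^2))
    if (d < 1e-9) {
      if (t_target > t_cur) push(t_target, p_cur)
      return(t_cur)
    }
    t_dep <- max(t_cur, t_target - d / speed)
    arrive <- t_dep + d / speed
    if (t_dep > t_cur) push(t_dep, p_cur)
    push(arrive, p)
    arrive
  }

  worst_lag <- 0
  for (b in blocks) {
    s <- b$s
    n1 <- min(length(s), n)              # segments reached in arm 1
    need2 <- length(s) > n
    tau <- if (need2) (n1 * res + 2 * half + res / 2) / speed else 0
    shift <- tau / 2                     # balance the crossing lag
    heur <- policy == "heuristic"
    for (j in seq_len(n1)) {
      target <- if (heur && j > 1L) 0    # full exploration at speed
        else max(s[j] - 0.5 - (if (need2) shift else 0), 0)
      arrive <- move_to(pos_at(b$type, 1L, (j - 0.5) * res), target)
      worst_lag <- max(worst_lag, arrive - s[j])
    }
    if (need2) {
      move_to(c(0, 0), t_cur)            # exit through the centre
      for (j in seq_len(length(s) - n)) {
        target <- if (heur) 0 else s[n + j] - 0.5
        arrive <- move_to(pos_at(b$type, 2L, (j - 0.5) * res), target)
        worst_lag <- max(worst_lag, arrive - s[n + j])
      }
    }
    move_to(c(0, 0), t_cur)              # immediate exit after the block
  }
  if (worst_lag > max_lag)
    stop(sprintf(
      "infeasible NEG curve: schedule slips %.1f s behind at %g cm/s; increase speed",
      worst_lag, speed))
  if (t_cur < duration) push(duration, p_cur)
  keep <- !duplicated(wp_t)
  wp_t <- wp_t[keep]; wp_x <- wp_x[keep]; wp_y <- wp_y[keep]

  ft <- seq(0, duration, by = 1 / frame_rate)
  fx <- stats::approx(wp_t, wp_x, xout = pmin(ft, t_cur), rule = 2)$y
  fy <- stats::approx(wp_t, wp_y, xout = pmin(ft, t_cur), rule = 2)$y
  tracking_series(ft, fx, fy, subject_id = "sim",  frame_rate = frame_rate)
}
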