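#' Discretise a tracking series into per-second occupancy
#'
#' Frames are binned into 1-s windows starting at the first sample (the
#' clock starts when tracking starts).  Each window records the set of
#' grid segments occupied or traversed during that second.  When
#' `interpolate` is `TRUE` (default), consecutive samples further apart
#' than one grid unit are joined by a straight line and the segments along
#' it are added to the window, mitigating under-sampling at high speed.
#' Per-sample speed is computed and samples faster than `speed_warn` cm/s
#' are flagged with a warning.
#'
#' @param track a [tracking_series()].
#' @param geometry an [epm_geometry()].
#' @param interpolate add segments crossed between consecutive samples.
#' @param speed_warn speed threshold (cm/s) above which samples are
#'   flagged; position is poorly resolved beyond ~25 cm/s at typical frame
#'   rates.
#' @return an `occupancy_seq` object: per-second segment sets plus
#'   frame-level zone codes, speeds and flags.
#' @export
discretize <- function(track, geometry, interpolate = TRUE, speed_warn = 25) {
  if (!inherits(track, "tracking_series")) {
    if (is.data.frame(track) && all(c("t", "x", "y") %in% names(track)))
      track <- tracking_series(track$t, track$x, track$y)
    else stop("track must be a tracking_series or a data frame with t, x, y")
  }
  if (nrow(track) == 0L) stop("empty track")
  t0 <- track$t[1L]
  tt <- track$t - t0
  duration <- max(1L, as.integer(ceiling(max(tt))))
  zone <- assign_segment(track$x, track$y, geometry)
  sec <- pmin(as.integer(floor(tt)), duration - 1L) + 1L  # 1-based window index

  dt <- diff(track$t)
  step <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  speed <- c(0, step / dt)
  fast <- which(speed > speed_warn)
  if (length(fast))
    warning(sprintf(
      "%d of %d samples exceed %g cm/s; grid occupancy may be under-resolved",
      length(fast), nrow(track), speed_warn), call. = FALSE)

  records <- vector("list", duration)
  for (k in seq_len(duration)) records[[k]] <- integer(0)
  add <- function(k, ids) {
    ids <- ids[ids > 0L]
    if (length(ids)) records[[k]] <<- union(records[[k]], ids)
    invisible(NULL)
  }
  for (i in seq_along(sec)) add(sec[i], zone[i])

  if (interpolate && nrow(track) > 1L) {
    res <- geometry$resolution
    jump <- which(step > res)
    for (i in jump) {
      m <- ceiling(step[i] / (res / 2))  # sub-resolution sampling of the line
      f <- seq_len(m - 1L) / m
      xi <- track$x[i] + f * (track$x[i + 1L] - track$x[i])
      yi <- track$y[i] + f * (track$y[i + 1L] - track$y[i])
      ti <- tt[i] + f * (tt[i + 1L] - tt[i])
      zi <- assign_segment(xi, yi, geometry)
      ki <- pmin(as.integer(floor(ti)), duration - 1L) + 1L
      for (k in unique(ki)) add(k, zi[ki == k])
    }
  }

  structure(
    list(records = records, zone = zone, sec = sec, speed = speed,
         duration = duration, subject_id = attr(track, "subject_id") %||% "s1",
         n_centre = sum(zone == ZONE_CENTRE), n_off = sum(zone == ZONE_OFF),
         fast_samples = fast, interpolate = interpolate,
         n_total = n_segments(geometry)),
    class = "occupancy_seq")
}

#' @export
print.occupancy_seq <- function(x, ...) {
  cat(sprintf("Occupancy sequence: subject %s, %d s, %d frames\n",
              x$subject_id, x$duration, length(x$zone)))
  cat(sprintf("  centre-zone frames: %d; off-maze frames: %d; fast samples: %d\n",
              x$n_centre, x$n_off, length(x$fast_samples)))
  invisible(x)
}

#' Novel exploration growth from an occupancy sequence
#'
#' NEG(t) is 100 times the number of scope segments first visited by the
#' end of second `t`, divided by the number of segments in the scope.
#' Centre-zone and off-maze samples contribute nothing.  The series is
#' non-decreasing and bounded in \[0, 100\] by construction; the time grid
#' covers 0..duration at 1-s steps (time 0 carries the placement sample).
#'
#' @param occ an `occupancy_seq` from [discretize()], or a list of
#'   per-second integer segment-id vectors.
#' @param geometry an [epm_geometry()].
#' @param scope `"total"`, `"open"` or `"closed"`.
#' @return a `neg_series` data frame with columns `time`, `neg`.
#' @export
compute_neg <- function(occ, geometry, scope = c("total", "open", "closed")) {
  scope <- match.arg(scope)
  records <- if (inherits(occ, "occupancy_seq")) occ$records else occ
  ids <- scope_segments(geometry, scope)
  n <- length(ids)
  if (inherits(occ, "occupancy_seq") && occ$n_total != n_segments(geometry))
    stop("occupancy sequence was built for a different geometry")
  placement <- if (inherits(occ, "occupancy_seq")) {
    z0 <- occ$zone[1L]
    if (z0 > 0L && z0 %in% ids) z0 else integer(0)
  } else integer(0)
  seen <- logical(n_segments(geometry))
  if (length(placement)) seen[placement] <- TRUE
  in_scope <- logical(n_segments(geometry)); in_scope[ids] <- TRUE
  neg <- numeric(length(records) + 1L)
  neg[1L] <- 100 * sum(seen & in_scope) / n
  for (k in seq_along(records)) {
    r <- records[[k]]
    if (length(r)) seen[r] <- TRUE
    neg[k + 1L] <- 100 * sum(seen & in_scope) / n
  }
  out <- data.frame(time = 0:length(records), neg = neg)
  attr(out, "scope") <- scope
  attr(out, "n_scope") <- n
  attr(out, "subject_id") <- if (inherits(occ, "occupancy_seq")) occ$subject_id else "s1"
  class(out) <- c("neg_series", "data.frame")
  out
}

#' Conventional open-arm measures
#'
#' The three standard elevated-plus-maze outcomes, computed from the same
#' occupancy sequence as NEG:
#' \describe{
#'   \item{latency_open}{first second whose occupancy contains an open-arm
#'     segment; the full test duration if the open arms are never entered.}
#'   \item{entries_open}{number of frame-level ingresses into open-arm
#'     segments from any non-open zone (centre or closed); entering each
#'     open arm through the centre counts separately.}
#'   \item{time_open}{number of seconds whose dominant (modal) frame zone
#'     is open; ties are broken toward the previous second's zone.}
#' }
#'
#' @param occ an `occupancy_seq` from [discretize()].
#' @param geometry an [epm_geometry()].
#' @return a `conventional_measures` list with the three fields.
#' @export
compute_conventional <- function(occ, geometry) {
  stopifnot(inherits(occ, "occupancy_seq"))
  open_ids <- scope_segments(geometry, "open")
  is_open_id <- function(id) id %in% open_ids
  duration <- occ$duration

  lat <- duration
  for (k in seq_along(occ$records)) {
    if (any(occ$records[[k]] %in% open_ids)) { lat <- k - 1L; break }
  }
  # placement directly in an open arm counts as latency 0
  if (occ$zone[1L] %in% open_ids) lat <- 0L

  # frame zone classes: open / closed / centre / off
  cls <- ifelse(occ$zone %in% open_ids, "open",
                ifelse(occ$zone > 0L, "closed",
                       ifelse(occ$zone == ZONE_CENTRE, "centre", "off")))
  r <- rle(cls)
  v <- r$values
  entries <- sum(v == "open" & c("start", v[-length(v)]) != "open")

  # dominant zone per second, ties toward the previous second's zone
  time_open <- 0L
  prev <- "centre"
  for (k in seq_len(duration)) {
    f <- cls[occ$sec == k]
    if (!length(f)) { next }
    tab <- table(f)
    top <- names(tab)[tab == max(tab)]
    dom <- if (prev %in% top) prev else top[1L]
    if (dom == "open") time_open <- time_open + 1L
    prev <- dom
  }
  structure(list(latency_open = as.numeric(lat),
                 entries_open = as.integer(entries),
                 time_open = as.numeric(time_open),
                 duration = as.numeric(duration)),
            class = "conventional_measures")
}

#' @export
print.conventional_measures <- function(x, ...) {
  cat(sprintf("latency to open arms: %g s; open-arm entries: %d; time in open arms: %g s\n",
              x$latency_open, x$entries_open, x$time_open))
  invisible(x)
}
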