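#' Construct a tracking series
#'
#' A tracking series is the per-frame centre-of-mass position of one
#' animal in maze-frame coordinates (cm, origin at the maze centre).
#'
#' @param t numeric vector of sample times in seconds, strictly increasing.
#' @param x,y numeric coordinate vectors in cm.
#' @param subject_id subject label.
#' @param frame_rate nominal sampling rate in Hz (informational).
#' @return a `tracking_series` data frame with columns `t`, `x`, `y`.
#' @export
tracking_series <- function(t, x, y, subject_id = "s1", frame_rate = NULL) {
  if (length(t) == 0L) stop("empty track: no samples")
  if (length(t) != length(x) || length(t) != length(y))
    stop("t, x and y must have equal length")
  if (any(!is.finite(t)) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("tracking samples must be finite")
  if (any(diff(t) <= 0)) stop("sample times must be strictly increasing")
  out <- data.frame(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y))
  attr(out, "subject_id") <- as.character(subject_id)
  attr(out, "frame_rate") <- frame_rate %||%
    if (length(t) > 1L) 1 / stats::median(diff(t)) else NA_real_
  class(out) <- c("tracking_series", "data.frame")
  out
}

# Column presets for common tracker exports.  Wide per-frame x,y tables;
# "frames" means no time column, times are frame_index / frame_rate.
tracker_presets <- list(
  generic   = list(time = "t", x = "x", y = "y"),
  ethovision = list(time = "Trial time", x = "X center", y = "Y center"),
  anymaze   = list(time = "Time", x = "Centre position X", y = "Centre position Y"),
  xy_frames = list(time = NULL, x = "x", y = "y")
)

#' Read a tracking export
#'
#' Reads delimited text with configurable column names and units.  Time may
#' be an explicit seconds column or, when `time_col` is `NULL`, derived
#' from the row (frame) index and `frame_rate`.
#'
#' @param path file path (CSV by default; `sep` follows the extension:
#'   `.tsv`/`.txt` are tab-delimited).
#' @param preset one of `"generic"`, `"ethovision"`, `"anymaze"`,
#'   `"xy_frames"`; sets default column names.
#' @param time_col,x_col,y_col column name overrides.
#' @param units coordinate units in the file; `"m"` is converted to cm.
#' @param frame_rate required when no time column is present.
#' @param subject_id subject label (defaults to the file name).
#' @param sep field separator override.
#' @return a [tracking_series()].
#' @export
read_tracking <- function(path, preset = "generic", time_col = NULL,
                          x_col = NULL, y_col = NULL, units = c("cm", "m"),
                          frame_rate = NULL, subject_id = NULL, sep = NULL) {
  units <- match.arg(units)
  if (!preset %in% names(tracker_presets))
    stop("unknown preset: ", preset)
  cols <- tracker_presets[[preset]]
  if (!missing(time_col)) cols$time <- time_col else if (!is.null(time_col)) cols$time <- time_col
  cols$x <- x_col %||% cols$x
  cols$y <- y_col %||% cols$y
  sep <- sep %||% if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c(cols$x, cols$y, cols$time)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("tracking file ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "))
  scale <- if (units == "m") 100 else 1
  tt <- if (is.null(cols$time)) {
    if (is.null(frame_rate)) stop("frame_rate is required when no time column is present")
    (seq_len(nrow(df)) - 1) / frame_rate
  } else as.numeric(df[[cols$time]])
  tracking_series(tt, df[[cols$x]] * scale, df[[cols$y]] * scale,
                  subject_id = subject_id %||% sub("\\.[^.]*$", "", basename(path)),
                  frame_rate = frame_rate)
}

#' Write NEG series in tidy long format
#'
#' Columns: `subject_id`, `scope`, `time_s`, `neg_pct`.
#'
#' @param x a `neg_series` (from [compute_neg()]) or a long data frame of
#'   simulated series (from [simulate_neg()]).
#' @param path output file; delimiter follows the extension.
#' @export
write_neg <- function(x, path) {
  if (inherits(x, "neg_series")) {
    out <- data.frame(subject_id = attr(x, "subject_id"),
                      scope = attr(x, "scope"),
                      time_s = x$time, neg_pct = x$neg)
  } else {
    stopifnot(all(c("subject", "scope", "time", "neg") %in% names(x)))
    out <- data.frame(subject_id = x$subject, scope = x$scope,
                      time_s = x$time, neg_pct = x$neg)
  }
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(out)
}
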