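#' Elevated plus maze geometry and segment grid
#'
#' Constructs the unidimensional first-visit grid for a plus maze: each arm
#' is divided along its length into segments of `grid_resolution` cm that
#' span the full arm width.  Segments carry a unique identifier with arm
#' type (open/closed), arm index (1 or 2) and a depth index counted outward
#' from the centre-zone boundary.  The square centre zone contains no
#' segments and is excluded from every NEG calculation.
#'
#' Coordinates are maze-frame centimetres with the origin at the maze
#' centre.  By default the open arms lie on the x axis (arm 1 towards +x,
#' arm 2 towards -x) and the closed arms on the y axis.
#'
#' @param arm_length arm length in cm (from the centre-zone boundary to the
#'   arm tip).
#' @param arm_width arm width in cm.
#' @param centre_size side of the square centre zone in cm.
#' @param grid_resolution segment depth in cm (default 1); must divide
#'   `arm_length` exactly.
#' @param open_axis `"x"` or `"y"`: the axis carrying the open-arm pair.
#' @return an object of class `epm_geometry`.
#' @examples
#' geom <- epm_geometry()
#' n_segments(geom)            # 200
#' n_segments(geom, "open")    # 100
#' @export
epm_geometry <- function(arm_length = 50, arm_width = 10, centre_size = 10,
                         grid_resolution = 1, open_axis = c("x", "y")) {
  open_axis <- match.arg(open_axis)
  if (arm_length <= 0 || arm_width <= 0 || centre_size <= 0 || grid_resolution <= 0)
    stop("maze dimensions and grid resolution must be positive")
  n_per_arm <- arm_length / grid_resolution
  if (abs(n_per_arm - round(n_per_arm)) > 1e-8)
    stop("grid_resolution must divide arm_length exactly (",
         arm_length, " / ", grid_resolution, " is not an integer)")
  n_per_arm <- as.integer(round(n_per_arm))
  segments <- data.frame(
    id = seq_len(4L * n_per_arm),
    arm_type = rep(c("open", "closed"), each = 2L * n_per_arm),
    arm_index = rep(rep(1:2, each = n_per_arm), times = 2L),
    depth = rep(seq_len(n_per_arm), times = 4L)
  )
  structure(
    list(arm_length = arm_length, arm_width = arm_width,
         centre_size = centre_size, resolution = grid_resolution,
         n_per_arm = n_per_arm, open_axis = open_axis, segments = segments),
    class = "epm_geometry")
}

#' @export
print.epm_geometry <- function(x, ...) {
  cat("Elevated plus maze geometry\n")
  cat(sprintf("  arms: %g cm long, %g cm wide; centre zone %g x %g cm\n",
              x$arm_length, x$arm_width, x$centre_size, x$centre_size))
  cat(sprintf("  grid: %g cm resolution -> %d segments/arm, %d per arm type, %d total\n",
              x$resolution, x$n_per_arm, 2L * x$n_per_arm, 4L * x$n_per_arm))
  cat(sprintf("  open arms on the %s axis\n", x$open_axis))
  invisible(x)
}

#' Number of grid segments in a scope
#'
#' @param geometry an [epm_geometry()] object.
#' @param scope `"total"`, `"open"` or `"closed"`.
#' @return integer segment count.
#' @export
n_segments <- function(geometry, scope = c("total", "open", "closed")) {
  scope <- match.arg(scope)
  stopifnot(inherits(geometry, "epm_geometry"))
  if (scope == "total") 4L * geometry$n_per_arm else 2L * geometry$n_per_arm
}

#' Segment identifiers belonging to a scope
#'
#' @inheritParams n_segments
#' @return integer vector of segment ids.
#' @export
scope_segments <- function(geometry, scope = c("total", "open", "closed")) {
  scope <- match.arg(scope)
  seg <- geometry$segments
  if (scope == "total") seg$id else seg$id[seg$arm_type == scope]
}

#' Zone constants used by [assign_segment()]
#'
#' `ZONE_CENTRE` (0) marks samples inside the centre square; `ZONE_OFF`
#' (-1) marks samples outside the maze footprint.  Positive values are
#' segment ids.
#'
#' @name zones
#' @export
ZONE_CENTRE <- 0L

#' @rdname zones
#' @export
ZONE_OFF <- -1L

#' Map maze-frame coordinates to grid segments
#'
#' Total function: every point maps to a segment id, `ZONE_CENTRE`, or
#' `ZONE_OFF`.  The centre square takes precedence.  Depth intervals are
#' half-open `[d, d + resolution)` with the final interval closed at the
#' arm tip, so assignment is unambiguous along the whole arm.
#'
#' @param x,y numeric vectors of coordinates in cm (origin at maze centre).
#' @param geometry an [epm_geometry()] object.
#' @return integer vector: segment id (> 0), `ZONE_CENTRE` or `ZONE_OFF`.
#' @export
assign_segment <- function(x, y, geometry) {
  stopifnot(inherits(geometry, "epm_geometry"), length(x) == length(y))
  half <- geometry$centre_size / 2
  hw <- geometry$arm_width / 2
  res <- geometry$resolution
  n <- geometry$n_per_arm
  L <- geometry$arm_length
  out <- rep(ZONE_OFF, length(x))
  centre <- abs(x) <= half & abs(y) <= half
  out[centre] <- ZONE_CENTRE

  # axis "x" arms use x for depth and y for width, and vice versa
  seg_along <- function(a, b) {
    # a: along-arm coordinate, b: across-arm coordinate
    d <- abs(a) - half
    ok <- !centre & abs(b) <= hw & d >= 0 & d <= L
    depth <- pmin(floor(d / res) + 1L, n)  # closes the final interval
    arm <- ifelse(a >= 0, 1L, 2L)
    list(ok = ok, depth = as.integer(depth), arm = arm)
  }
  ox <- if (geometry$open_axis == "x") seg_along(x, y) else seg_along(y, x)
  cx <- if (geometry$open_axis == "x") seg_along(y, x) else seg_along(x, y)
  # open ids: (arm-1)*n + depth; closed ids offset by 2n
  out[ox$ok] <- (ox$arm[ox$ok] - 1L) * n + ox$depth[ox$ok]
  out[cx$ok] <- 2L * n + (cx$arm[cx$ok] - 1L) * n + cx$depth[cx$ok]
  out
}
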