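# Segment geometry: irregular MLC aperture area, equivalent-square field
# (EQIF) size, EQIF binning, and resampling of a VMAT arc into fixed-width
# gantry sectors. All lengths are cm at the isocenter plane (DICOM mm are
# converted once, on read).

#' Nominal EQIF bin sizes
#'
#' The 11 nominal equivalent-square field sizes (side length, cm) into which
#' segment apertures are binned: 3, 4, 5, 6, 8, 10, 12, 14, 16, 18, 20.
#'
#' @return Numeric vector of length 11.
#' @export
eqif_bin_sizes <- function() c(3, 4, 5, 6, 8, 10, 12, 14, 16, 18, 20)

#' Irregular aperture area from MLC and jaw positions
#'
#' Computes the open area of an MLC-shaped field, optionally clipped by the
#' X and Y jaws. Each leaf pair contributes the x-overlap of its open
#' interval with the X-jaw window, times the y-overlap of the pair's width
#' interval with the Y-jaw window. Closed or crossed pairs (right <= left)
#' contribute nothing.
#'
#' @param mlc_left,mlc_right Numeric vectors of per-pair leaf tip positions
#'   (cm at isocenter); `mlc_left` is bank A (negative-x side).
#' @param leaf_widths Per-pair leaf widths (cm). The bank is assumed centered
#'   on y = 0 unless `leaf_boundaries` is given.
#' @param jaw_x,jaw_y Length-2 `c(lo, hi)` jaw windows (cm). `NULL` means no
#'   clipping on that axis.
#' @param leaf_boundaries Optional `length(leaf_widths) + 1` vector of leaf
#'   edge y-coordinates (cm), overriding the centered-bank assumption.
#' @return Aperture area in cm^2 (>= 0).
#' @export
aperture_area <- function(mlc_left, mlc_right, leaf_widths,
                          jaw_x = NULL, jaw_y = NULL,
                          leaf_boundaries = NULL) {
  n <- length(leaf_widths)
  if (length(mlc_left) != n || length(mlc_right) != n)
    stop("mlc_left, mlc_right and leaf_widths must have equal length")
  if (any(leaf_widths <= 0)) stop("leaf widths must be positive")
  if (is.null(leaf_boundaries)) {
    leaf_boundaries <- cumsum(c(0, leaf_widths)) - sum(leaf_widths) / 2
  } else if (length(leaf_boundaries) != n + 1L) {
    stop("leaf_boundaries must have length(leaf_widths) + 1 elements")
  }
  xlo <- if (is.null(jaw_x)) -Inf else jaw_x[1L]
  xhi <- if (is.null(jaw_x)) Inf else jaw_x[2L]
  ylo <- if (is.null(jaw_y)) -Inf else jaw_y[1L]
  yhi <- if (is.null(jaw_y)) Inf else jaw_y[2L]
  dx <- pmax(0, pmin(mlc_right, xhi) - pmax(mlc_left, xlo))
  dy <- pmax(0, pmin(leaf_boundaries[-1L], yhi) -
                pmax(leaf_boundaries[-(n + 1L)], ylo))
  sum(dx * dy)
}

#' Equivalent-square field side length
#'
#' Side of the square with the same area as the irregular aperture,
#' `sqrt(area)`. The Sterling `4A/P` equivalent square is available via
#' `method = "sterling"` (requires the field perimeter) for sensitivity
#' checks; the equal-area square is the default and the definition used
#' throughout the pipeline.
#'
#' @param area Aperture area, cm^2.
#' @param method `"sqrt"` (equal-area, default) or `"sterling"`.
#' @param perimeter Field perimeter (cm), needed for `"sterling"`.
#' @return Side length in cm; 0 iff `area == 0`.
#' @export
eqif_side <- function(area, method = c("sqrt", "sterling"),
                      perimeter = NULL) {
  method <- match.arg(method)
  if (any(area < 0)) stop("area must be non-negative")
  if (method == "sqrt") return(sqrt(area))
  if (is.null(perimeter)) stop("sterling method needs the field perimeter")
  ifelse(area == 0, 0, 4 * area / perimeter)
}

#' Assign an EQIF side length to its nominal bin
#'
#' Nearest size on the 11-point nominal grid; ties go to the smaller size.
#' Sides beyond the grid clamp to the end bins; a zero side (zero-area
#' aperture) gets `NA` and is excluded from dose accumulation.
#'
#' @param side EQIF side length(s), cm.
#' @return Numeric vector of nominal bin sizes (or `NA` for zero sides).
#' @export
assign_eqif_bin <- function(side) {
  if (any(side < 0, na.rm = TRUE)) stop("side must be non-negative")
  sizes <- eqif_bin_sizes()
  vapply(side, function(s) {
    if (is.na(s) || s == 0) return(NA_real_)
    d <- abs(sizes - s)
    sizes[which.min(d)]  # which.min takes the first = smaller size on ties
  }, numeric(1))
}

#' Resample a VMAT arc into fixed-width gantry sectors
#'
#' Splits a beam's gantry sweep into `delta`-degree sectors (the last sector
#' is truncated if the span is not a multiple of `delta`). The aperture of a
#' sector is the control-point geometry linearly interpolated at the sector's
#' angular midpoint; its meterset fraction is the increment of the cumulative
#' meterset weight across the sector, so fractions sum to 1 over the beam.
#'
#' @param beam An `rt_beam` (see [read_rtplan()]).
#' @param delta Sector width in degrees (default 4, giving 90 segments for a
#'   full 360-degree arc).
#' @param clip_jaws Clip the MLC aperture by the jaws (default `TRUE`).
#' @return A data.frame of class `rt_segments` with one row per sector:
#'   `gantry_center`, `area` (cm^2), `eqif_side` (cm), `eqif_bin` (nominal
#'   size or `NA`), `meterset_fraction`.
#' @export
resample_arc <- function(beam, delta = 4, clip_jaws = TRUE) {
  stopifnot(inherits(beam, "rt_beam"))
  stopifnot_scalar_pos(delta, "delta")
  ang <- beam$gantry
  cw <- beam$cum_weight
  if (length(ang) < 2L) stop("beam needs at least 2 control points")
  d <- diff(ang)
  if (any(d < 0)) stop("non-monotonic gantry sweep")
  span <- ang[length(ang)] - ang[1L]
  if (span == 0) {  # static beam: a single segment at the fixed angle
    warning("static (non-arc) beam treated as a single segment")
    bounds <- c(ang[1L], ang[1L])
    mids <- ang[1L]
    n_seg <- 1L
    frac <- cw[length(cw)] - cw[1L]
  } else {
    n_seg <- as.integer(ceiling(span / delta - 1e-9))
    bounds <- pmin(ang[1L] + delta * (0:n_seg), ang[length(ang)])
    mids <- (bounds[-1L] + bounds[-(n_seg + 1L)]) / 2
    cw_at <- stats::approx(ang, cw, xout = bounds, ties = "ordered")$y
    frac <- diff(cw_at)
  }
  interp <- function(mat) {
    apply(mat, 2L, function(col)
      stats::approx(ang, col, xout = mids, ties = "ordered")$y)
  }
  ml <- matrix(interp(beam$mlc_left), nrow = n_seg)
  mr <- matrix(interp(beam$mlc_right), nrow = n_seg)
  jx <- matrix(interp(beam$jaw_x), nrow = n_seg)
  jy <- matrix(interp(beam$jaw_y), nrow = n_seg)
  area <- vapply(seq_len(n_seg), function(i) {
    aperture_area(ml[i, ], mr[i, ], beam$leaf_widths,
                  jaw_x = if (clip_jaws) jx[i, ] else NULL,
                  jaw_y = if (clip_jaws) jy[i, ] else NULL,
                  leaf_boundaries = beam$leaf_boundaries)
  }, numeric(1))
  side <- eqif_side(area)
  seg <- data.frame(
    gantry_center = mids %% 360,
    area = area,
    eqif_side = side,
    eqif_bin = assign_eqif_bin(side),
    meterset_fraction = frac
  )
  class(seg) <- c("rt_segments", "data.frame")
  seg
}
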