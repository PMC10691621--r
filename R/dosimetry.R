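# Per-segment dose, contour volumes and mean structure dose from the grid.

#' Dose delivered in each arc segment
#'
#' A segment's dose is the beam's per-fraction dose times the segment's
#' meterset fraction; with `course_total = TRUE` it is additionally
#' multiplied by the number of fractions. Segment doses over a beam sum
#' exactly to the beam dose (times fractions).
#'
#' @param beam An `rt_beam`.
#' @param segments `rt_segments` from [resample_arc()].
#' @param n_fractions Number of fractions (used when `course_total`).
#' @param course_total Accumulate over the whole course (default `FALSE`:
#'   per-fraction doses, the scale on which bin-dose features are reported).
#' @return Numeric vector of per-segment doses (Gy).
#' @export
segment_dose <- function(beam, segments, n_fractions = 1L,
                         course_total = FALSE) {
  stopifnot(inherits(beam, "rt_beam"))
  d <- beam$beam_dose * segments$meterset_fraction
  if (course_total) d <- d * n_fractions
  d
}

# Shoelace area of one planar polygon (vertices need not repeat the first).
.polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3L) stop("contour with fewer than 3 vertices")
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

#' Structure volume from planar contours
#'
#' Sum over slices of shoelace polygon area times slice spacing; multiple
#' contours on one slice add (holes are not modelled). Spacing is inferred
#' from the distinct contour z-coordinates unless given.
#'
#' @param contours List of contours, each `list(x, y, z)` in cm.
#' @param slice_spacing Slice thickness (cm); required when all contours lie
#'   on a single plane.
#' @return Volume in cm^3.
#' @export
structure_volume <- function(contours, slice_spacing = NULL) {
  if (length(contours) == 0L) stop("no contours")
  areas <- vapply(contours, function(ct) .polygon_area(ct$x, ct$y), numeric(1))
  if (is.null(slice_spacing)) {
    z <- sort(unique(vapply(contours, `[[`, numeric(1), "z")))
    if (length(z) < 2L)
      stop("slice_spacing must be given for single-slice structures")
    slice_spacing <- stats::median(diff(z))
  }
  sum(areas) * slice_spacing
}

# Vectorized even-odd (ray crossing) point-in-polygon test.
.points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Mean dose within a contoured structure
#'
#' Slice-wise voxel-center sampling: each contour is matched to the nearest
#' dose-grid z-plane; voxels whose centers fall inside the (union of)
#' contours on that plane contribute. No partial-volume weighting, matching
#' the behaviour of typical DVH engines at planning-grid resolution.
#'
#' @param dose An `rt_dose_grid` from [read_rtdose()].
#' @param contours List of contours (`list(x, y, z)`, cm).
#' @return Mean dose in Gy.
#' @export
mean_structure_dose <- function(dose, contours) {
  stopifnot(inherits(dose, "rt_dose_grid"))
  dims <- dim(dose$values)
  gx <- dose$origin[1L] + (seq_len(dims[1L]) - 1L) * dose$spacing[1L]
  gy <- dose$origin[2L] + (seq_len(dims[2L]) - 1L) * dose$spacing[2L]
  gz <- dose$origin[3L] +
    (seq_len(dims[3L]) - 1L) * (dose$spacing[3L] %||% 0)
  px <- rep(gx, times = dims[2L])
  py <- rep(gy, each = dims[1L])
  total <- 0; count <- 0L
  cz <- vapply(contours, `[[`, numeric(1), "z")
  plane_of <- vapply(cz, function(z) which.min(abs(gz - z)), integer(1))
  for (plane in unique(plane_of)) {
    mask <- rep(FALSE, dims[1L] * dims[2L])
    for (ct in contours[plane_of == plane]) {
      mask <- xor(mask, .points_in_polygon(px, py, ct$x, ct$y))
    }
    slab <- dose$values[, , plane]
    total <- total + sum(slab[mask])
    count <- count + sum(mask)
  }
  if (count == 0L) stop("structure below grid resolution: no voxel centers inside")
  total / count
}

#' CTV volume normalized by body mass index
#'
#' @param volume CTV volume, cm^3.
#' @param bmi Body mass index, kg/m^2.
#' @return `volume / bmi` in cm^3 m^2 / kg.
#' @export
ctv_per_bmi <- function(volume, bmi) {
  if (any(bmi <= 0)) stop("bmi must be positive")
  volume / bmi
}
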