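# Readers for DICOM RT Plan / Structure Set / Dose and for the plain-text
# cohort metadata and feature tables. All geometry is converted mm -> cm at
# read time; doses are Gy internally.

## ---- model constructors ---------------------------------------------------

#' @rdname read_rtplan
#' @param beam_mu Beam meterset (MU).
#' @param beam_dose Per-fraction dose attributable to the beam (Gy).
#' @param gantry Unwrapped, non-decreasing gantry angles (degrees), one per
#'   control point.
#' @param cum_weight Cumulative meterset weight per control point, normalized
#'   to end at 1.
#' @param mlc_left,mlc_right Control-point-by-leaf-pair matrices (cm).
#' @param jaw_x,jaw_y Control-point-by-2 matrices `c(lo, hi)` (cm).
#' @param leaf_boundaries Leaf edge y-coordinates, length pairs + 1 (cm).
#' @export
rt_beam <- function(beam_mu, beam_dose, gantry, cum_weight,
                    mlc_left, mlc_right, jaw_x, jaw_y, leaf_boundaries) {
  n <- length(gantry)
  if (n < 2L) stop("a beam needs at least 2 control points")
  if (length(cum_weight) != n) stop("cum_weight length mismatch")
  if (any(diff(cum_weight) < -1e-9))
    stop("cumulative meterset weights must be non-decreasing")
  mlc_left <- as.matrix(mlc_left); mlc_right <- as.matrix(mlc_right)
  if (nrow(mlc_left) != n || nrow(mlc_right) != n)
    stop("MLC matrices must have one row per control point")
  arc_span <- gantry[n] - gantry[1L]
  structure(list(
    beam_mu = beam_mu, beam_dose = beam_dose, gantry = gantry,
    cum_weight = cum_weight, mlc_left = mlc_left, mlc_right = mlc_right,
    jaw_x = as.matrix(jaw_x), jaw_y = as.matrix(jaw_y),
    leaf_boundaries = leaf_boundaries,
    leaf_widths = diff(leaf_boundaries),
    arc_span = arc_span
  ), class = "rt_beam")
}

#' @rdname read_rtplan
#' @param plan_id Plan label.
#' @param beams List of `rt_beam` objects.
#' @param fraction_dose Prescribed dose per fraction (Gy).
#' @param n_fractions Number of planned fractions.
#' @export
rt_plan <- function(plan_id, beams, fraction_dose, n_fractions) {
  total_mu <- sum(vapply(beams, `[[`, numeric(1), "beam_mu"))
  if (total_mu <= 0) stop("total MU must be positive")
  stopifnot_scalar_pos(fraction_dose, "fraction_dose")
  structure(list(
    plan_id = plan_id, beams = beams, total_mu = total_mu,
    fraction_dose = fraction_dose, n_fractions = as.integer(n_fractions)
  ), class = "rt_plan")
}

#' @export
print.rt_plan <- function(x, ...) {
  cat(sprintf(
    "<rt_plan %s>  beams: %d  total MU: %.1f  %.2f Gy x %d fractions\n",
    x$plan_id, length(x$beams), x$total_mu, x$fraction_dose, x$n_fractions))
  invisible(x)
}

## ---- RT Plan --------------------------------------------------------------

#' Read DICOM RT objects into the internal model
#'
#' `read_rtplan()` parses a DICOM RTPLAN (explicit VR little endian) into an
#' `rt_plan`: per-beam control points (gantry angle, cumulative meterset
#' weight, MLC leaf positions, jaw windows), beam metersets and per-fraction
#' beam doses. Gantry angles are unwrapped modulo 360 into a monotone sweep;
#' geometry is converted to cm. A beam without gantry motion is accepted with
#' a warning and later treated as a single segment. Per-fraction beam dose
#' falls back to `fraction_dose * beam_mu / total_mu` when the plan does not
#' record per-beam doses.
#'
#' @param path Path to the DICOM file.
#' @return `read_rtplan()`: an `rt_plan`; `read_rtstruct()`: an
#'   `rt_structure_set` (named list of ROIs, each a list of planar contours
#'   with `x`, `y` (cm) and scalar `z`); `read_rtdose()`: an `rt_dose_grid`
#'   with `values` (Gy, dims x-y-z), `origin`, `spacing` (cm).
#' @export
read_rtplan <- function(path) {
  ds <- dcm_read_file(path)
  if (!identical(dcm_get(ds, "00080060"), "RTPLAN"))
    stop("not an RTPLAN object: ", path)
  beam_items <- ds[["300a00b0"]]
  if (is.null(beam_items) || length(beam_items) == 0L)
    stop("unsupported plan: no BeamSequence")

  # meterset / per-beam dose from the fraction group
  fg <- ds[["300a0070"]]
  n_fractions <- 1L
  meterset <- list(); beamdose <- list()
  if (!is.null(fg) && length(fg) > 0L) {
    n_fractions <- as.integer(dcm_get(fg[[1L]], "300a0078", 1L))
    for (rb in fg[[1L]][["300c0004"]] %||% list()) {
      num <- as.character(dcm_require(rb, "300c0006", "ReferencedBeamNumber"))
      meterset[[num]] <- dcm_get(rb, "300a0086")
      beamdose[[num]] <- dcm_get(rb, "300a0084")
    }
  }

  beams <- lapply(beam_items, function(bi) {
    num <- as.character(dcm_get(bi, "300a00c0", NA))
    final_w <- dcm_get(bi, "300a010e", 1)
    # leaf boundaries from the MLCX beam limiting device (mm -> cm)
    bld <- bi[["300a00b6"]] %||% list()
    boundaries <- NULL
    for (dev in bld) {
      if (identical(dcm_get(dev, "300a00b8"), "MLCX"))
        boundaries <- dcm_get(dev, "300a00be") / 10
    }
    if (is.null(boundaries))
      stop("unsupported plan: beam ", num, " has no MLC leaf boundaries")
    n_pairs <- length(boundaries) - 1L
    cps <- bi[["300a0111"]] %||% list()
    if (length(cps) < 2L) stop("beam ", num, " has fewer than 2 control points")
    ncp <- length(cps)
    gantry_raw <- numeric(ncp); cw <- numeric(ncp)
    ml <- matrix(NA_real_, ncp, n_pairs); mr <- ml
    jx <- matrix(NA_real_, ncp, 2L); jy <- jx
    last <- list(ml = NULL, mr = NULL, jx = NULL, jy = NULL)
    for (i in seq_len(ncp)) {
      cp <- cps[[i]]
      g <- dcm_get(cp, "300a011e")
      gantry_raw[i] <- if (is.null(g) && i > 1L) gantry_raw[i - 1L] else g
      cw[i] <- dcm_require(cp, "300a0134", "CumulativeMetersetWeight")
      for (dev in cp[["300a011a"]] %||% list()) {
        kind <- dcm_get(dev, "300a00b8")
        pos <- dcm_get(dev, "300a011c") / 10
        if (identical(kind, "MLCX")) {
          last$ml <- pos[seq_len(n_pairs)]
          last$mr <- pos[n_pairs + seq_len(n_pairs)]
        } else if (identical(kind, "X") || identical(kind, "ASYMX")) {
          last$jx <- pos
        } else if (identical(kind, "Y") || identical(kind, "ASYMY")) {
          last$jy <- pos
        }
      }
      if (is.null(last$ml)) stop("unsupported plan: control point without ",
                                 "MLC positions before any MLC snapshot")
      ml[i, ] <- last$ml; mr[i, ] <- last$mr
      jx[i, ] <- last$jx %||% c(-Inf, Inf)
      jy[i, ] <- last$jy %||% c(-Inf, Inf)
    }
    # unwrap gantry modulo 360 into a monotone sweep (clockwise convention)
    steps <- diff(gantry_raw) %% 360
    if (any(steps >= 180))
      stop("non-monotonic gantry sweep in beam ", num)
    gantry <- gantry_raw[1L] + cumsum(c(0, steps))
    if (gantry[ncp] - gantry[1L] == 0 && ncp > 1L)
      warning("static (non-arc) beam ", num, ": treated as a single segment")
    mu <- meterset[[num]] %||% NA_real_
    bd <- beamdose[[num]] %||% NA_real_
    rt_beam(beam_mu = mu, beam_dose = bd,
            gantry = gantry, cum_weight = cw / final_w,
            mlc_left = ml, mlc_right = mr, jaw_x = jx, jaw_y = jy,
            leaf_boundaries = boundaries)
  })

  mus <- vapply(beams, `[[`, numeric(1), "beam_mu")
  if (anyNA(mus)) stop("unsupported plan: beam meterset missing")
  doses <- vapply(beams, `[[`, numeric(1), "beam_dose")
  fraction_dose <- if (anyNA(doses)) 2 else sum(doses)
  if (anyNA(doses)) {  # proportional-MU split when per-beam dose is absent
    for (i in seq_along(beams))
      beams[[i]]$beam_dose <- fraction_dose * mus[i] / sum(mus)
  }
  rt_plan(plan_id = dcm_get(ds, "300a0002", basename(path)),
          beams = beams, fraction_dose = fraction_dose,
          n_fractions = n_fractions)
}

## ---- RT Structure Set -----------------------------------------------------

#' @rdname read_rtplan
#' @export
read_rtstruct <- function(path) {
  ds <- dcm_read_file(path)
  if (!identical(dcm_get(ds, "00080060"), "RTSTRUCT"))
    stop("not an RTSTRUCT object: ", path)
  roi_names <- list()
  for (item in ds[["30060020"]] %||% list()) {
    num <- as.character(dcm_require(item, "30060022", "ROINumber"))
    roi_names[[num]] <- dcm_require(item, "30060026", "ROIName")
  }
  rois <- list()
  for (item in ds[["30060039"]] %||% list()) {
    num <- as.character(dcm_require(item, "30060084", "ReferencedROINumber"))
    name <- roi_names[[num]] %||% paste0("ROI_", num)
    contours <- lapply(item[["30060040"]] %||% list(), function(ci) {
      xyz <- dcm_require(ci, "30060050", "ContourData") / 10  # mm -> cm
      m <- matrix(xyz, ncol = 3L, byrow = TRUE)
      if (nrow(m) < 3L) stop("contour with fewer than 3 vertices in ", name)
      list(x = m[, 1L], y = m[, 2L], z = m[1L, 3L])
    })
    rois[[name]] <- contours
  }
  structure(list(rois = rois), class = "rt_structure_set")
}

## ---- RT Dose --------------------------------------------------------------

#' @rdname read_rtplan
#' @export
read_rtdose <- function(path) {
  ds <- dcm_read_file(path)
  if (!identical(dcm_get(ds, "00080060"), "RTDOSE"))
    stop("not an RTDOSE object: ", path)
  units <- dcm_get(ds, "30040002", "GY")
  if (!identical(toupper(units), "GY"))
    stop("unknown dose units: ", units)
  rows <- dcm_require(ds, "00280010", "Rows")
  cols <- dcm_require(ds, "00280011", "Columns")
  frames <- as.integer(dcm_get(ds, "00280008", 1L))
  bits <- dcm_get(ds, "00280100", 32L)
  scaling <- dcm_require(ds, "3004000e", "DoseGridScaling")
  origin <- dcm_require(ds, "00200032", "ImagePositionPatient") / 10
  px <- dcm_require(ds, "00280030", "PixelSpacing") / 10  # row-spacing, col-spacing
  offsets <- dcm_get(ds, "3004000c", 0) / 10
  pix <- dcm_require(ds, "7fe00010", "PixelData")
  ints <- if (bits < 32L) {
    readBin(pix, "integer", n = rows * cols * frames, size = bits / 8L,
            signed = FALSE, endian = "little")
  } else {
    readBin(pix, "integer", n = rows * cols * frames, size = 4L,
            endian = "little")
  }
  if (any(ints < 0)) ints <- ints + ifelse(ints < 0, 2^bits, 0)
  values <- array(ints * scaling, dim = c(cols, rows, frames))
  dz <- if (length(offsets) > 1L) stats::median(diff(offsets)) else NA_real_
  structure(list(
    values = values,
    origin = origin,                 # (x, y, z) of first voxel center, cm
    spacing = c(px[2L], px[1L], dz), # (dx, dy, dz), cm
    units = "Gy"
  ), class = "rt_dose_grid")
}

## ---- cohort metadata and feature tables -----------------------------------

#' Read the cohort metadata table
#'
#' A delimited text table with columns `patient_id`, `bmi`, `art_label`
#' (labels `"ART"` / `"non-ART"`, or the numeric codes `+1` / `-1`). BMI is
#' carried here because it is not reliably present in DICOM.
#'
#' @param path CSV path.
#' @return data.frame with `patient_id` (character), `bmi` (kg/m^2) and
#'   `label` (+1 = ART, -1 = non-ART).
#' @export
read_cohort_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "bmi", "art_label")
  if (!all(need %in% names(md)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(md$patient_id))
    stop("duplicate patient_id in metadata")
  if (any(!is.finite(md$bmi)) || any(md$bmi <= 0))
    stop("bmi must be positive")
  lab <- as.character(md$art_label)
  label <- ifelse(lab %in% c("ART", "1", "+1"), 1,
                  ifelse(lab %in% c("non-ART", "non_art", "-1"), -1, NA))
  if (anyNA(label))
    stop("art_label values must be 'ART' or 'non-ART' (or +1/-1)")
  data.frame(patient_id = as.character(md$patient_id), bmi = md$bmi,
             label = label, stringsAsFactors = FALSE)
}

#' Write / read a five-dimensional feature table
#'
#' CSV schema: `patient_id`, `eqif_size_cm`, `bin_dose_gy`,
#' `ctv_high_per_bmi`, `total_mu`, `oral_mean_dose_gy`, `label`.
#'
#' @param cohort A `cohort_table` (see [build_cohort_table()]).
#' @param path Output CSV path.
#' @export
write_feature_table <- function(cohort, path) {
  out <- data.frame(
    patient_id = cohort$patient_id,
    eqif_size_cm = cohort$eqif_size,
    bin_dose_gy = cohort$bin_dose,
    ctv_high_per_bmi = cohort$ctv_high_per_bmi,
    total_mu = cohort$total_mu,
    oral_mean_dose_gy = cohort$oral_mean_dose,
    label = cohort$label
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  cohort <- data.frame(
    patient_id = as.character(x$patient_id),
    eqif_size = x$eqif_size_cm,
    bin_dose = x$bin_dose_gy,
    ctv_high_per_bmi = x$ctv_high_per_bmi,
    total_mu = x$total_mu,
    oral_mean_dose = x$oral_mean_dose_gy,
    label = x$label,
    stringsAsFactors = FALSE
  )
  class(cohort) <- c("cohort_table", "data.frame")
  cohort
}
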