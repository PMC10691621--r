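# Assembly of per-patient five-dimensional feature lists: one list per
# nominal EQIF bin, carrying (eqif size, accumulated bin dose, CTV-high/BMI,
# total MU, mean oral-cavity dose) plus the ART label.

#' Accumulate segment doses into the 11 EQIF bins
#'
#' @param eqif_bin Per-segment nominal bin sizes (`NA` = zero-area segment,
#'   excluded).
#' @param dose Per-segment doses (Gy).
#' @return Named numeric vector of length 11 (names = nominal sizes); the sum
#'   equals the total dose of binned segments.
#' @export
accumulate_bin_doses <- function(eqif_bin, dose) {
  if (length(eqif_bin) != length(dose))
    stop("eqif_bin and dose must have equal length")
  sizes <- eqif_bin_sizes()
  out <- stats::setNames(numeric(length(sizes)), sizes)
  keep <- !is.na(eqif_bin)
  if (any(keep)) {
    agg <- tapply(dose[keep], factor(eqif_bin[keep], levels = sizes), sum)
    agg[is.na(agg)] <- 0
    out[] <- agg
  }
  out
}

#' Build the 11 five-dimensional feature lists for one patient
#'
#' Resamples every beam of the plan into `delta`-degree segments, assigns
#' per-segment (per-fraction) doses, accumulates them into the 11 EQIF bins,
#' and attaches the three patient-level features (CTV-high volume / BMI,
#' total MU, mean oral-cavity dose) shared by all 11 lists.
#'
#' @param plan An `rt_plan`.
#' @param structures An `rt_structure_set`.
#' @param dose An `rt_dose_grid` (course-total dose), or `NULL` to skip the
#'   oral dose (then `oral_mean_dose` must be supplied).
#' @param meta One-row data.frame with `patient_id`, `bmi`, `label`.
#' @param roi_map Named list of regexes resolving ROI roles to names,
#'   defaults from [default_config()].
#' @param delta Gantry sector width in degrees.
#' @param course_total_bins Accumulate bin doses over the whole course
#'   instead of per fraction (default `FALSE`, the scale of the per-segment
#'   dose feature).
#' @return A `cohort_table` data.frame with 11 rows.
#' @export
build_feature_lists <- function(plan, structures, dose, meta,
                                roi_map = default_config()$roi_map,
                                delta = 4, course_total_bins = FALSE) {
  stopifnot(inherits(plan, "rt_plan"), inherits(structures, "rt_structure_set"))
  find_roi <- function(role) {
    hits <- grep(roi_map[[role]], names(structures$rois), ignore.case = TRUE,
                 value = TRUE)
    if (length(hits) == 0L)
      stop("no ROI matching role '", role, "' (pattern ", roi_map[[role]],
           ") for patient ", meta$patient_id)
    hits[1L]
  }
  bins <- numeric(11L)
  for (beam in plan$beams) {
    seg <- resample_arc(beam, delta = delta)
    d <- segment_dose(beam, seg, n_fractions = plan$n_fractions,
                      course_total = course_total_bins)
    bins <- bins + accumulate_bin_doses(seg$eqif_bin, d)
  }
  ctv <- structures$rois[[find_roi("ctv_high")]]
  ctv_vol <- structure_volume(ctv)
  oral_dose <- if (!is.null(dose)) {
    mean_structure_dose(dose, structures$rois[[find_roi("oral_cavity")]])
  } else {
    meta$oral_mean_dose
  }
  sizes <- eqif_bin_sizes()
  out <- data.frame(
    patient_id = meta$patient_id,
    eqif_size = sizes,
    bin_dose = as.numeric(bins),
    ctv_high_per_bmi = ctv_per_bmi(ctv_vol, meta$bmi),
    total_mu = plan$total_mu,
    oral_mean_dose = oral_dose,
    label = meta$label,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Combine per-patient feature lists into a cohort table
#'
#' @param patient_tables List of 11-row `cohort_table`s.
#' @return A `cohort_table` ordered by (`patient_id`, `eqif_size`); exactly
#'   11 rows per patient.
#' @export
build_cohort_table <- function(patient_tables) {
  if (length(patient_tables) == 0L) {
    out <- data.frame(patient_id = character(0), eqif_size = numeric(0),
                      bin_dose = numeric(0), ctv_high_per_bmi = numeric(0),
                      total_mu = numeric(0), oral_mean_dose = numeric(0),
                      label = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("cohort_table", "data.frame")
    return(out)
  }
  ids <- vapply(patient_tables, function(t) t$patient_id[1L], character(1))
  if (anyDuplicated(ids)) stop("duplicate patient id: ",
                               ids[duplicated(ids)][1L])
  out <- do.call(rbind, patient_tables)
  out <- out[order(out$patient_id, out$eqif_size), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Extract the full feature table from a directory of DICOM triplets
#'
#' Expects `out_dir/metadata.csv` plus, per patient id,
#' `<id>_rtplan.dcm`, `<id>_rtstruct.dcm`, `<id>_rtdose.dcm` (the layout
#' written by [generate_dicom_cohort()]). Patients whose files are missing
#' or whose ROIs cannot be resolved are skipped with a message; the result
#' always has 11 rows per successfully processed patient.
#'
#' @param dir Cohort directory.
#' @param roi_map,delta See [build_feature_lists()].
#' @param skip_errors Skip failing patients (default `TRUE`) instead of
#'   stopping.
#' @return A `cohort_table`.
#' @export
extract_features <- function(dir, roi_map = default_config()$roi_map,
                             delta = 4, skip_errors = TRUE) {
  md_path <- file.path(dir, "metadata.csv")
  if (!file.exists(md_path)) stop("no metadata.csv found in ", dir)
  md <- read_cohort_metadata(md_path)
  tables <- list()
  for (i in seq_len(nrow(md))) {
    id <- md$patient_id[i]
    res <- tryCatch({
      plan <- read_rtplan(file.path(dir, paste0(id, "_rtplan.dcm")))
      structures <- read_rtstruct(file.path(dir, paste0(id, "_rtstruct.dcm")))
      dose <- read_rtdose(file.path(dir, paste0(id, "_rtdose.dcm")))
      build_feature_lists(plan, structures, dose, md[i, , drop = FALSE],
                          roi_map = roi_map, delta = delta)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (!skip_errors) stop("patient ", id, ": ", conditionMessage(res))
      message("skipping patient ", id, ": ", conditionMessage(res))
    } else {
      tables[[id]] <- res
    }
  }
  build_cohort_table(tables)
}
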