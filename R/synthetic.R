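# Synthetic cohorts and synthetic DICOM RT triplets. The generator's stated
# world is the published cohort: 43 non-ART / 18 ART patients whose group
# means of CTV-high/BMI (3.70 / 6.21 cm^3 m^2/kg), mean oral-cavity dose
# (28.70 / 32.98 Gy), total MU (636 / 644) and per-EQIF-bin dose profiles
# match the study's summary tables. Group SDs are not published, so they are
# back-solved from the published Welch-t p-values under an equal-SD
# assumption.

#' Back-solve a common group SD from a published p-value
#'
#' Given two group means, the group sizes, and the two-sided Welch-t p-value
#' the comparison is reported to have produced, finds the common
#' (equal-across-groups) SD under which the expected Welch statistic
#' reproduces that p-value. With equal SDs the Satterthwaite df do not
#' depend on the SD, so the relation is monotone and is root-found to 1e-6.
#'
#' @param mean_a,mean_b Group means (must differ).
#' @param n_a,n_b Group sizes.
#' @param target_p Two-sided p-value in (0, 1).
#' @return The common SD.
#' @export
calibrate_sds <- function(mean_a, mean_b, n_a, n_b, target_p) {
  if (target_p <= 0 || target_p >= 1) stop("target_p must be in (0, 1)")
  d <- abs(mean_a - mean_b)
  if (d == 0)
    stop("equal means: any SD reproduces p = 1; SD not identifiable")
  q <- 1 / n_a + 1 / n_b
  df <- q^2 / ((1 / n_a)^2 / (n_a - 1) + (1 / n_b)^2 / (n_b - 1))
  p_of <- function(s) 2 * stats::pt(-d / (s * sqrt(q)), df)
  lo <- d * 1e-8; hi <- d * 1e8
  stats::uniroot(function(s) p_of(s) - target_p, c(lo, hi),
                 tol = 1e-6 * d)$root
}

# Draws from a zero-left-truncated normal whose *post-truncation* mean is
# `target_mean` (the location parameter is shifted down to compensate, so
# generated cohorts reproduce the published group means). `sd` is the
# pre-truncation scale. sd = 0 degenerates to the constant.
.rtrunc0_meanmatched <- function(n, target_mean, sd) {
  if (sd == 0) return(rep(target_mean, n))
  if (target_mean <= 0) stop("target mean of a positive quantity must be > 0")
  trunc_mean <- function(mu) {
    a <- -mu / sd
    lambda <- exp(stats::dnorm(a, log = TRUE) -
                  stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
    mu + sd * lambda
  }
  mu <- stats::uniroot(function(m) trunc_mean(m) - target_mean,
                       c(target_mean - 20 * sd, target_mean),
                       tol = 1e-9 * max(1, target_mean))$root
  a <- -mu / sd
  pa <- stats::pnorm(a)
  mu + sd * stats::qnorm(pa + stats::runif(n) * (1 - pa))
}

#' Specification of a calibrated synthetic cohort
#'
#' Defaults encode the published cohort: group sizes 43/18; CTV-high/BMI
#' means 3.70/6.21, mean oral dose 28.70/32.98 Gy, total MU 636/644
#' (non-ART/ART); per-bin per-fraction dose-profile means from the published
#' EQIF comparison table; SDs calibrated from the published p-values via
#' [calibrate_sds()] (bins with identical zero means in both groups get
#' SD 0).
#'
#' @param n_non_art,n_art Group sizes.
#' @param seed Generator seed.
#' @param prob_two_arcs Probability a synthetic patient is planned with two
#'   arcs rather than one.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_non_art = 43L, n_art = 18L, seed = 1L,
                        prob_two_arcs = 0.5) {
  n_a <- 43L; n_b <- 18L  # calibration always uses the published sizes
  shared <- list(
    ctv_high_per_bmi = list(mean_non = 3.70, mean_art = 6.21, p = 0.036),
    oral_mean_dose   = list(mean_non = 28.70, mean_art = 32.98, p = 0.040),
    total_mu         = list(mean_non = 636, mean_art = 644, p = 0.801)
  )
  for (v in names(shared)) {
    sh <- shared[[v]]
    shared[[v]]$sd <- calibrate_sds(sh$mean_art, sh$mean_non, n_b, n_a, sh$p)
  }
  bins <- data.frame(
    eqif_size = eqif_bin_sizes(),
    mean_non = c(0.0469, 0.0113, 0.0142, 0.0703, 0.4138, 0.5957,
                 0.5449, 0.2202, 0.0349, 0, 0),
    mean_art = c(0, 0.0061, 0.0140, 0.0382, 0.3051, 0.5972,
                 0.5844, 0.3440, 0.0653, 0, 0),
    p = c(0.29, 0.60, 0.99, 0.10, 0.04, 0.97, 0.37, 0.03, 0.29, NA, NA)
  )
  bins$sd <- vapply(seq_len(nrow(bins)), function(i) {
    if (bins$mean_non[i] == bins$mean_art[i]) return(0)
    calibrate_sds(bins$mean_art[i], bins$mean_non[i], n_b, n_a, bins$p[i])
  }, numeric(1))
  structure(list(
    n_non_art = as.integer(n_non_art), n_art = as.integer(n_art),
    shared = shared, bins = bins, seed = as.integer(seed),
    prob_two_arcs = prob_two_arcs,
    fraction_dose = 2, n_fractions = 33L,
    bmi_mean = 22, bmi_sd = 3
  ), class = "cohort_spec")
}

#' Generate a calibrated synthetic feature cohort
#'
#' Per patient: CTV-high/BMI, mean oral dose and total MU are drawn from
#' zero-truncated normals whose post-truncation means equal the group means
#' and whose scale is the p-value-calibrated SD; the 11 per-bin doses are
#' drawn from normals around the group bin profile with negatives clipped to
#' zero. Deterministic given `spec$seed`; 11 feature lists per patient.
#'
#' @param spec A `cohort_spec`.
#' @return A `cohort_table` with `11 * (n_non_art + n_art)` rows.
#' @export
generate_cohort_features <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    groups <- list(
      list(n = spec$n_non_art, label = -1, key = "mean_non", tag = "N"),
      list(n = spec$n_art, label = 1, key = "mean_art", tag = "A")
    )
    tables <- list()
    for (g in groups) {
      if (g$n == 0L) next
      ctv <- .rtrunc0_meanmatched(g$n, spec$shared$ctv_high_per_bmi[[g$key]],
                                  spec$shared$ctv_high_per_bmi$sd)
      oral <- .rtrunc0_meanmatched(g$n, spec$shared$oral_mean_dose[[g$key]],
                                   spec$shared$oral_mean_dose$sd)
      mu <- .rtrunc0_meanmatched(g$n, spec$shared$total_mu[[g$key]],
                                 spec$shared$total_mu$sd)
      prof <- matrix(
        pmax(0, stats::rnorm(g$n * 11L,
                             mean = rep(spec$bins[[g$key]], each = g$n),
                             sd = rep(spec$bins$sd, each = g$n))),
        nrow = g$n)
      for (i in seq_len(g$n)) {
        id <- sprintf("pt%s%04d", g$tag, i)
        tab <- data.frame(
          patient_id = id, eqif_size = eqif_bin_sizes(),
          bin_dose = prof[i, ], ctv_high_per_bmi = ctv[i],
          total_mu = mu[i], oral_mean_dose = oral[i], label = g$label,
          stringsAsFactors = FALSE)
        class(tab) <- c("cohort_table", "data.frame")
        tables[[id]] <- tab
      }
    }
    build_cohort_table(tables)
  })
}

## ---- synthetic DICOM ------------------------------------------------------

.synth_uid <- function(...) paste("1.2.826.0.1.3680043.9590", ..., sep = ".")

# MLC bank used by all synthetic plans: 40 pairs of 0.5 cm, centered.
.SYNTH_BOUNDARIES <- seq(-10, 10, by = 0.5)

# Encode a square aperture of side s (cm) as MLC/jaw positions.
.square_aperture <- function(s) {
  nb <- .SYNTH_BOUNDARIES
  n <- length(nb) - 1L
  open <- nb[-length(nb)] >= -s / 2 - 1e-9 & nb[-1L] <= s / 2 + 1e-9
  list(left = ifelse(open, -s / 2, 0), right = ifelse(open, s / 2, 0),
       jaw_x = c(-s / 2, s / 2), jaw_y = c(-s / 2, s / 2))
}

# One full 360-degree arc delivering `profile` (11-vector, Gy) as square
# apertures of the nominal bin sizes: 90 four-degree sectors allocated to
# the active bins proportionally to their dose share, control points every
# 2 degrees with the sector aperture held across each sector.
.synth_arc_elements <- function(beam_number, beam_mu, profile) {
  sizes <- eqif_bin_sizes()
  active <- which(profile > 0)
  if (length(active) == 0L) stop("unsatisfiable profile: no dose in any bin")
  share <- profile[active] / sum(profile)
  # largest-remainder allocation of the 90 sectors, at least one per bin
  n_sec <- pmax(1L, as.integer(floor(share * 90)))
  while (sum(n_sec) > 90L) {
    k <- which.max(n_sec); n_sec[k] <- n_sec[k] - 1L
  }
  while (sum(n_sec) < 90L) {
    k <- which.max(share * 90 - n_sec); n_sec[k] <- n_sec[k] + 1L
  }
  sector_bin <- rep(active, n_sec)              # bin index per sector
  sector_w <- rep(share / n_sec, n_sec)         # meterset fraction per sector
  cum_at_cp <- numeric(181L)
  for (m in 1:180) {
    k <- ceiling(m / 2)                          # sector of this half-step
    cum_at_cp[m + 1L] <- cum_at_cp[m] + sector_w[k] / 2
  }
  cum_at_cp[181L] <- 1                           # exact endpoint

  cps <- vector("list", 181L)
  for (m in 0:180) {
    # odd CPs sit at sector midpoints, even CPs at sector boundaries (they
    # take the aperture of the sector that starts there)
    k <- min(m %/% 2L + 1L, 90L)
    ap <- .square_aperture(sizes[sector_bin[k]])
    pos_sq <- dcm_element(0x300A, 0x011A, "SQ", list(
      dcm_item(dcm_element(0x300A, 0x00B8, "CS", "X"),
               dcm_element(0x300A, 0x011C, "DS", ap$jaw_x * 10)),
      dcm_item(dcm_element(0x300A, 0x00B8, "CS", "Y"),
               dcm_element(0x300A, 0x011C, "DS", ap$jaw_y * 10)),
      dcm_item(dcm_element(0x300A, 0x00B8, "CS", "MLCX"),
               dcm_element(0x300A, 0x011C, "DS",
                           c(ap$left, ap$right) * 10))
    ))
    cps[[m + 1L]] <- dcm_item(
      dcm_element(0x300A, 0x0112, "IS", m),
      pos_sq,
      dcm_element(0x300A, 0x011E, "DS", (2 * m) %% 360),
      dcm_element(0x300A, 0x0134, "DS", cum_at_cp[m + 1L])
    )
  }
  dcm_item(
    dcm_element(0x300A, 0x00B6, "SQ", list(
      dcm_item(dcm_element(0x300A, 0x00B8, "CS", "MLCX"),
               dcm_element(0x300A, 0x00BC, "IS",
                           length(.SYNTH_BOUNDARIES) - 1L),
               dcm_element(0x300A, 0x00BE, "DS", .SYNTH_BOUNDARIES * 10))
    )),
    dcm_element(0x300A, 0x00C0, "IS", beam_number),
    dcm_element(0x300A, 0x010E, "DS", 1),
    dcm_element(0x300A, 0x0111, "SQ", cps)
  )
}

# Write one synthetic RTPLAN delivering `profile` Gy per fraction across
# `n_arcs` full arcs with total meterset `total_mu`.
write_synth_rtplan <- function(path, plan_id, profile, total_mu,
                               n_arcs = 1L, n_fractions = 33L) {
  if (sum(profile) <= 0) stop("unsatisfiable profile: no dose in any bin")
  beam_items <- lapply(seq_len(n_arcs), function(b)
    .synth_arc_elements(b, total_mu / n_arcs, profile))
  ref_beams <- lapply(seq_len(n_arcs), function(b)
    dcm_item(dcm_element(0x300A, 0x0084, "DS", sum(profile) / n_arcs),
             dcm_element(0x300A, 0x0086, "DS", total_mu / n_arcs),
             dcm_element(0x300C, 0x0006, "IS", b)))
  elements <- list(
    dcm_element(0x0008, 0x0060, "CS", "RTPLAN"),
    dcm_element(0x300A, 0x0002, "SH", plan_id),
    dcm_element(0x300A, 0x0070, "SQ", list(dcm_item(
      dcm_element(0x300A, 0x0078, "IS", n_fractions),
      dcm_element(0x300C, 0x0004, "SQ", ref_beams)
    ))),
    dcm_element(0x300A, 0x00B0, "SQ", beam_items)
  )
  dcm_write_file(path, "1.2.840.10008.5.1.4.1.1.481.5",
                 .synth_uid("1", abs(sum(utf8ToInt(plan_id)))), elements)
}

# Square planar contour stack: side `a` cm on `n_slices` planes spaced `dz`.
.square_contours <- function(a, n_slices, dz, z0 = 0, cx = 0, cy = 0) {
  lapply(seq_len(n_slices) - 1L, function(i) {
    h <- a / 2
    list(x = cx + c(-h, h, h, -h), y = cy + c(-h, -h, h, h), z = z0 + i * dz)
  })
}

write_synth_rtstruct <- function(path, struct_id, rois) {
  roi_defs <- lapply(seq_along(rois), function(i)
    dcm_item(dcm_element(0x3006, 0x0022, "IS", i),
             dcm_element(0x3006, 0x0026, "LO", names(rois)[i])))
  roi_contours <- lapply(seq_along(rois), function(i) {
    citems <- lapply(rois[[i]], function(ct) {
      xyz <- as.vector(rbind(ct$x, ct$y, rep(ct$z, length(ct$x)))) * 10
      dcm_item(dcm_element(0x3006, 0x0046, "IS", length(ct$x)),
               dcm_element(0x3006, 0x0050, "DS", xyz))
    })
    dcm_item(dcm_element(0x3006, 0x0040, "SQ", citems),
             dcm_element(0x3006, 0x0084, "IS", i))
  })
  elements <- list(
    dcm_element(0x0008, 0x0060, "CS", "RTSTRUCT"),
    dcm_element(0x3006, 0x0020, "SQ", roi_defs),
    dcm_element(0x3006, 0x0039, "SQ", roi_contours)
  )
  dcm_write_file(path, "1.2.840.10008.5.1.4.1.1.481.3",
                 .synth_uid("2", abs(sum(utf8ToInt(struct_id)))), elements)
}

write_synth_rtdose <- function(path, dose_id, values, origin, spacing,
                               scaling = 1e-4) {
  dims <- dim(values)
  ints <- as.integer(round(as.vector(values) / scaling))
  elements <- list(
    dcm_element(0x0008, 0x0060, "CS", "RTDOSE"),
    dcm_element(0x0020, 0x0032, "DS", origin * 10),
    dcm_element(0x0020, 0x0037, "DS", c(1, 0, 0, 0, 1, 0)),
    dcm_element(0x0028, 0x0008, "IS", dims[3L]),
    dcm_element(0x0028, 0x0010, "US", dims[2L]),        # rows (y)
    dcm_element(0x0028, 0x0011, "US", dims[1L]),        # columns (x)
    dcm_element(0x0028, 0x0030, "DS", c(spacing[2L], spacing[1L]) * 10),
    dcm_element(0x0028, 0x0100, "US", 32L),
    dcm_element(0x0028, 0x0101, "US", 32L),
    dcm_element(0x0028, 0x0103, "US", 0L),
    dcm_element(0x3004, 0x0002, "CS", "GY"),
    dcm_element(0x3004, 0x000C, "DS",
                (seq_len(dims[3L]) - 1L) * spacing[3L] * 10),
    dcm_element(0x3004, 0x000E, "DS", scaling),
    dcm_element(0x7FE0, 0x0010, "OW",
                writeBin(ints, raw(), size = 4L, endian = "little"))
  )
  dcm_write_file(path, "1.2.840.10008.5.1.4.1.1.481.2",
                 .synth_uid("3", abs(sum(utf8ToInt(dose_id)))), elements)
}

#' Generate a synthetic DICOM cohort
#'
#' Draws the feature cohort with [generate_cohort_features()] (same seed,
#' hence identical values) and materializes each patient as a readable DICOM
#' triplet: an RTPLAN with 1-2 full arcs (control points every 2 degrees)
#' whose 4-degree-segment EQIF-bin dose profile reproduces the patient's
#' drawn profile, an RTSTRUCT whose CTV-high volume encodes the drawn
#' CTV/BMI at the patient's BMI, and a uniform RTDOSE grid whose
#' oral-cavity mean equals the drawn oral dose. Also writes `metadata.csv`.
#'
#' @param spec A `cohort_spec`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest data.frame (patient ids, file paths,
#'   arcs, bmi).
#' @export
generate_dicom_cohort <- function(spec, out_dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  features <- generate_cohort_features(spec)
  ids <- unique(features$patient_id)
  aux <- with_seed(spec$seed + 1000003L, list(
    bmi = pmax(15, stats::rnorm(length(ids), spec$bmi_mean, spec$bmi_sd)),
    arcs = 1L + stats::rbinom(length(ids), 1L, spec$prob_two_arcs)
  ))
  manifest <- data.frame(patient_id = ids, bmi = aux$bmi, arcs = aux$arcs,
                         stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    id <- ids[i]
    rows <- features[features$patient_id == id, ]
    profile <- rows$bin_dose[order(rows$eqif_size)]
    write_synth_rtplan(file.path(out_dir, paste0(id, "_rtplan.dcm")),
                       id, profile, total_mu = rows$total_mu[1L],
                       n_arcs = aux$arcs[i], n_fractions = spec$n_fractions)
    ctv_vol <- rows$ctv_high_per_bmi[1L] * aux$bmi[i]
    rois <- list(
      CTV_high = .square_contours(sqrt(ctv_vol / 2), 5L, 0.4),
      CTV_intermediate = .square_contours(sqrt(3.5 * aux$bmi[i] / 2), 5L, 0.4),
      CTV_low = .square_contours(sqrt(1.2 * aux$bmi[i] / 2), 5L, 0.4),
      OralCavity = .square_contours(6, 4L, 1, z0 = 2)
    )
    write_synth_rtstruct(file.path(out_dir, paste0(id, "_rtstruct.dcm")),
                         id, rois)
    dose <- array(rows$oral_mean_dose[1L], dim = c(20L, 20L, 8L))
    write_synth_rtdose(file.path(out_dir, paste0(id, "_rtdose.dcm")),
                       id, dose, origin = c(-9.5, -9.5, 0),
                       spacing = c(1, 1, 1))
  }
  labels <- features$label[match(ids, features$patient_id)]
  utils::write.csv(
    data.frame(patient_id = ids, bmi = aux$bmi,
               art_label = ifelse(labels == 1, "ART", "non-ART")),
    file.path(out_dir, "metadata.csv"), row.names = FALSE)
  invisible(manifest)
}
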