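# Group comparisons between the ART and non-ART cohorts: Welch t, two-sample
# z, normal probability-density summaries, and the per-EQIF-bin dose
# comparison table with relative differences.

#' Two-sample location tests
#'
#' `welch_t_test()` is the two-sided unequal-variance t-test with
#' Satterthwaite degrees of freedom (the safer default for the 43-vs-18
#' group sizes; the pooled-variance variant is available via
#' `var_equal = TRUE`). `two_sample_z_test()` is the large-sample z-test
#' using per-group sample variances with a two-sided normal p-value.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @return List with `statistic`, `p`, and (t-test) `df`.
#' @export
welch_t_test <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    stat <- if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b))
    return(list(statistic = stat, p = if (stat == 0) 1 else 0, df = NA_real_))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(statistic = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' @rdname welch_t_test
#' @export
two_sample_z_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs n >= 2")
  se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
  if (se == 0) {
    stat <- if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b))
    return(list(statistic = stat, p = if (stat == 0) 1 else 0))
  }
  z <- (mean(a) - mean(b)) / se
  list(statistic = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Normal probability-density summary of a sample
#'
#' Mean, SD, and a normal pdf curve evaluated on a regular grid spanning
#' +/- 6 SD (the display used for comparing the ART and non-ART feature
#' distributions). A zero-variance sample is flagged degenerate and gets no
#' curve.
#'
#' @param x Numeric sample.
#' @param n_grid Grid resolution.
#' @return List with `mean`, `sd`, `degenerate`, and (unless degenerate)
#'   `grid`, `density`.
#' @export
density_summary <- function(x, n_grid = 512L) {
  m <- mean(x); s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    return(list(mean = m, sd = s, degenerate = TRUE))
  grid <- seq(m - 6 * s, m + 6 * s, length.out = n_grid)
  list(mean = m, sd = s, degenerate = FALSE,
       grid = grid, density = stats::dnorm(grid, m, s))
}

#' Relative difference of the ART group versus the non-ART group
#'
#' `100 * (art - non_art) / non_art`; undefined (`NA`) when the non-ART
#' reference is zero, rendered as "-" in reports.
#'
#' @param art,non_art Group summary values.
#' @param digits Rounding for report display (`NULL` = no rounding).
#' @return Percent difference (possibly `NA`).
#' @export
relative_difference <- function(art, non_art, digits = 2) {
  r <- ifelse(non_art == 0, NA_real_, 100 * (art - non_art) / non_art)
  if (!is.null(digits)) r <- round(r, digits)
  r
}

#' Per-EQIF-bin dose comparison between the ART and non-ART groups
#'
#' For each of the 11 nominal bins, the group average and median of the
#' per-patient accumulated bin dose, the relative differences (ART vs
#' non-ART, %), and the per-bin Welch t-test p-value. Medians are taken over
#' per-patient values within each group (each patient contributes exactly
#' one bin dose per bin).
#'
#' @param cohort A `cohort_table`.
#' @return data.frame with one row per bin: `eqif_size`, `avg_art`,
#'   `avg_non_art`, `rel_diff_avg`, `med_art`, `med_non_art`,
#'   `rel_diff_med`, `p_welch`.
#' @export
eqif_comparison_table <- function(cohort) {
  if (length(unique(cohort$label)) < 2L)
    stop("both ART and non-ART patients are required")
  sizes <- eqif_bin_sizes()
  rows <- lapply(sizes, function(s) {
    art <- cohort$bin_dose[cohort$eqif_size == s & cohort$label == 1]
    non <- cohort$bin_dose[cohort$eqif_size == s & cohort$label == -1]
    p <- if (stats::sd(art) == 0 && stats::sd(non) == 0) NA_real_
         else welch_t_test(art, non)$p
    data.frame(
      eqif_size = s,
      avg_art = mean(art), avg_non_art = mean(non),
      rel_diff_avg = relative_difference(mean(art), mean(non)),
      med_art = stats::median(art), med_non_art = stats::median(non),
      rel_diff_med = relative_difference(stats::median(art),
                                         stats::median(non)),
      p_welch = p
    )
  })
  do.call(rbind, rows)
}

#' Patient-level group comparison of the shared features
#'
#' One row per patient-level variable (CTV-high/BMI, total MU, mean oral
#' dose) with group means and the Welch-t and z-test p-values, mirroring the
#' cohort summary table. Oral dose is reported in cGy (the reporting unit),
#' internal doses being Gy.
#'
#' @param cohort A `cohort_table`.
#' @return data.frame with `variable`, `mean_non_art`, `mean_art`, `p_t`,
#'   `p_z`.
#' @export
cohort_group_summary <- function(cohort) {
  per_patient <- unique(cohort[, c("patient_id", "ctv_high_per_bmi",
                                   "total_mu", "oral_mean_dose", "label")])
  vars <- list(
    ctv_high_per_bmi = per_patient$ctv_high_per_bmi,
    total_mu = per_patient$total_mu,
    oral_mean_dose_cgy = per_patient$oral_mean_dose * 100
  )
  rows <- lapply(names(vars), function(v) {
    x <- vars[[v]]
    art <- x[per_patient$label == 1]
    non <- x[per_patient$label == -1]
    data.frame(variable = v,
               mean_non_art = mean(non), mean_art = mean(art),
               p_t = welch_t_test(art, non)$p,
               p_z = two_sample_z_test(art, non)$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
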