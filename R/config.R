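# Run configuration: defaults are the study's protocol constants; a JSON
# config file (and, in the CLI, flags) can override them.

#' Default run configuration
#'
#' ROI name-mapping regexes, the 4-degree gantry sector width, the nominal
#' EQIF bins, classifier parameters (RBF SVM gamma 0.05 / c 10, KNN k 5),
#' and the sweep grid (test sizes 0.1-0.9, split seeds 1-100).
#'
#' @return A named list.
#' @export
default_config <- function() {
  list(
    roi_map = list(
      ctv_high = "ctv[_ ]*high|high[_ ]*ctv",
      ctv_intermediate = "ctv[_ ]*int|int.*ctv",
      ctv_low = "ctv[_ ]*low|low[_ ]*ctv",
      oral_cavity = "oral"
    ),
    delta = 4,
    eqif_bins = eqif_bin_sizes(),
    svm = list(gamma = 0.05, c = 10),
    knn = list(k = 5),
    scaling = "zscore",
    split_level = "list",
    sizes = seq(0.1, 0.9, by = 0.1),
    seeds = 1:100
  )
}

#' Load a JSON run configuration
#'
#' Fields present in the file override the defaults; everything else keeps
#' the protocol value. Validated on load.
#'
#' @param path JSON file, or `NULL` for pure defaults.
#' @return A config list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (k in names(user)) {
      if (is.list(cfg[[k]]) && is.list(user[[k]])) {
        for (k2 in names(user[[k]])) cfg[[k]][[k2]] <- user[[k]][[k2]]
      } else {
        cfg[[k]] <- user[[k]]
      }
    }
  }
  if (cfg$delta <= 0) stop("config: delta must be positive")
  if (any(cfg$sizes <= 0 | cfg$sizes >= 1))
    stop("config: test sizes must be in (0, 1)")
  if (!cfg$split_level %in% c("list", "patient"))
    stop("config: split_level must be 'list' or 'patient'")
  cfg
}
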