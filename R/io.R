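#' @name asl_io
#' @title NIfTI input/output for ASL series, masks and label maps
#'
#' @description
#' Series are stored as a 14-frame NIfTI-1 volume (frames along the third
#' dimension in acquisition order: base, noise, then the six interleaved
#' control/label pairs C1, L1, ..., C6, L6) with a JSON sidecar of the same
#' basename (`.json`) carrying `heart_rate`, `n_rr_delay`, `t1_blood` and
#' `pixel_spacing`. Masks and segment label maps are integer NIfTI on the
#' series grid, with a sidecar carrying `lv_center` and
#' `rv_insertion_angle`. Coordinates are 0-based (row, col) array indices;
#' angles are degrees counter-clockwise from the +col axis of the displayed
#' image. All readers and writers are exact inverses on valid inputs.
NULL

.sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", "", path) |> paste0(".json")
}

.write_sidecar <- function(x, path) {
  jsonlite::write_json(x, .sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

.read_sidecar <- function(path) {
  sp <- .sidecar_path(path)
  if (!file.exists(sp)) stop("missing JSON sidecar: ", sp)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write a FAIR-ASL series to NIfTI + JSON sidecar
#'
#' @param series An [asl_series()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "asl_series"))
  d <- dim(series$base_image)
  vol <- array(NA_real_, c(d, 14L))
  vol[, , 1] <- series$base_image
  vol[, , 2] <- series$noise_image
  for (p in 1:6) {
    vol[, , 1 + 2 * p] <- series$pairs[[p]]$control
    vol[, , 2 + 2 * p] <- series$pairs[[p]]$label
  }
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(series$pixel_spacing, series$pixel_spacing, 1)
  RNifti::writeNifti(img, path)
  .write_sidecar(list(heart_rate = series$heart_rate,
                      n_rr_delay = series$n_rr_delay,
                      t1_blood = series$t1_blood,
                      pixel_spacing = series$pixel_spacing,
                      frame_order = "base, noise, C1, L1, ..., C6, L6"),
                 path)
  invisible(path)
}

#' Read a FAIR-ASL series from NIfTI + JSON sidecar
#'
#' Missing optional sidecar fields are filled with the acquisition defaults
#' (`n_rr_delay = 2`, `t1_blood = 1650` ms, `pixel_spacing = 1.5` mm);
#' `heart_rate` has no safe default and must be present.
#'
#' @param path Path to a 14-frame NIfTI volume written by [write_series()].
#' @return An [asl_series()].
#' @export
read_series <- function(path) {
  vol <- as.array(RNifti::readNifti(path))
  if (length(dim(vol)) != 3L || dim(vol)[3] != 14L)
    stop("expected a 14-frame volume (base, noise, C1, L1, ..., C6, L6); got ",
         paste(dim(vol), collapse = "x"))
  meta <- .read_sidecar(path)
  if (is.null(meta$heart_rate))
    stop("sidecar lacks `heart_rate`; the post-labeling delay cannot be ",
         "derived without it")
  pairs <- lapply(1:6, function(p)
    list(control = vol[, , 1 + 2 * p], label = vol[, , 2 + 2 * p]))
  asl_series(vol[, , 1], vol[, , 2], pairs,
             heart_rate = meta$heart_rate,
             n_rr_delay = if (is.null(meta$n_rr_delay)) 2L else meta$n_rr_delay,
             t1_blood = if (is.null(meta$t1_blood)) 1650 else meta$t1_blood,
             pixel_spacing = if (is.null(meta$pixel_spacing)) 1.5
                             else meta$pixel_spacing)
}

#' Write / read a myocardial mask as integer NIfTI + sidecar
#'
#' @param mask A [myocardial_mask()].
#' @param path Output `.nii` path.
#' @return `path` (write) / a [myocardial_mask()] (read).
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "myocardial_mask"))
  m <- mask$mask; storage.mode(m) <- "integer"
  RNifti::writeNifti(RNifti::asNifti(m, datatype = "int16"), path)
  .write_sidecar(list(lv_center = mask$lv_center,
                      rv_insertion_angle = mask$rv_insertion_angle), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- as.array(RNifti::readNifti(path))
  if (length(dim(m)) != 2L) stop("mask must be a single 2-D frame")
  meta <- .read_sidecar(path)
  if (is.null(meta$lv_center) || is.null(meta$rv_insertion_angle))
    stop("mask sidecar must carry `lv_center` and `rv_insertion_angle`")
  myocardial_mask(m != 0, meta$lv_center, meta$rv_insertion_angle)
}

#' Write / read an AHA segment label map as integer NIfTI + sidecar
#'
#' Label values are restricted to 0 (background) and 1-6 (AHA segments).
#'
#' @param labels A `segment_labels` object from [aha6_labels()].
#' @param path Output `.nii` path.
#' @param series_grid Optional grid dims to check against (e.g.
#'   `dim(series$base_image)`).
#' @return `path` (write) / a `segment_labels` (read).
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "segment_labels"))
  lab <- labels$labels
  if (!all(lab %in% 0:6)) stop("label values must be in {0, 1..6}")
  RNifti::writeNifti(RNifti::asNifti(lab, datatype = "int16"), path)
  .write_sidecar(list(lv_center = labels$lv_center,
                      rv_insertion_angle = labels$rv_insertion_angle,
                      segment_names = aha6_segment_names()), path)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path, series_grid = NULL) {
  lab <- as.array(RNifti::readNifti(path))
  if (length(dim(lab)) != 2L) stop("label map must be a single 2-D frame")
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  if (!all(lab %in% 0:6)) stop("label values must be in {0, 1..6}")
  if (!any(lab > 0L)) stop("label map is empty")
  if (!is.null(series_grid) && !identical(dim(lab), as.integer(series_grid)))
    stop("label map grid ", paste(dim(lab), collapse = "x"),
         " does not match series grid ", paste(series_grid, collapse = "x"))
  meta <- .read_sidecar(path)
  structure(list(labels = lab, regions = .region_map,
                 lv_center = as.numeric(meta$lv_center),
                 rv_insertion_angle = meta$rv_insertion_angle),
            class = "segment_labels")
}

#' Write / read the long-format cohort results table
#'
#' One row per (subject, slice, segment, condition, timepoint) with `mbf`,
#' `pn`, `tsnr`, `included` and `region` columns (plus the six per-pair MBF
#' repeats when present). Excluded segments keep their values with
#' `included = FALSE`; exclusion is a flag, never a deletion.
#'
#' @param cohort_table Data frame as produced by [quantify_cohort()].
#' @param path Output `.csv` path.
#' @return `path` (write) / the table (read).
#' @export
write_results <- function(cohort_table, path) {
  need <- c("subject", "slice", "segment", "region", "condition", "timepoint",
            "mbf", "pn", "tsnr", "included")
  miss <- setdiff(need, names(cohort_table))
  if (length(miss)) stop("results table lacks columns: ",
                         paste(miss, collapse = ", "))
  utils::write.csv(cohort_table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$included <- as.logical(tab$included)
  tab
}

#' Read a YAML run configuration
#'
#' A study-run configuration: scenario list with optional parameter
#' overrides, seeds, output paths, per-arm exclusion policy. Unknown keys are
#' kept verbatim so downstream tools can extend the format.
#'
#' @param path YAML file path.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}
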