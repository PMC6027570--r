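#' FAIR-ASL acquisition series for one short-axis slice
#'
#' Container for a single-slice FAIR (flow-sensitive alternating inversion
#' recovery) arterial spin labeling acquisition: one base image (no labeling
#' pulse), one noise image, and six control/label image pairs, together with
#' the per-scan heart rate and timing metadata needed for quantification.
#'
#' @param base_image Numeric matrix, signal without a labeling pulse (a.u.).
#' @param noise_image Numeric matrix on the same grid, pure-noise acquisition.
#' @param pairs List of exactly 6 elements, each a list with components
#'   `control` and `label`, numeric matrices on the same grid. Controls use the
#'   slice-selective inversion, labels the nonselective inversion.
#' @param heart_rate Heart rate during the scan, beats/min. Required: the
#'   post-labeling delay is expressed in cardiac RR intervals.
#' @param n_rr_delay Integer, number of RR intervals between inversion and
#'   image acquisition (post-labeling delay). Default 2.
#' @param t1_blood Longitudinal relaxation time of arterial blood, ms.
#'   Default 1650.
#' @param pixel_spacing In-plane pixel spacing, mm. Default 1.5.
#'
#' @return An object of class `asl_series`.
#' @seealso [read_series()], [write_series()], [quantify_slice()]
#' @export
asl_series <- function(base_image, noise_image, pairs, heart_rate,
                       n_rr_delay = 2L, t1_blood = 1650, pixel_spacing = 1.5) {
  base_image <- as.matrix(base_image)
  noise_image <- as.matrix(noise_image)
  if (!is.list(pairs) || length(pairs) != 6L)
    stop("`pairs` must be a list of exactly 6 control/label pairs, got ",
         length(pairs))
  dims <- dim(base_image)
  check_grid <- function(m, what) {
    m <- as.matrix(m)
    if (!identical(dim(m), dims))
      stop(what, " is on a ", paste(dim(m), collapse = "x"),
           " grid; series grid is ", paste(dims, collapse = "x"))
    m
  }
  noise_image <- check_grid(noise_image, "noise image")
  pairs <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    if (is.null(p$control) || is.null(p$label))
      stop("pair ", i, " must have `control` and `label` components")
    list(control = check_grid(p$control, paste("control", i)),
         label   = check_grid(p$label, paste("label", i)))
  })
  if (is.null(heart_rate) || !is.finite(heart_rate) || heart_rate <= 0)
    stop("`heart_rate` must be a positive number (beats/min)")
  if (t1_blood <= 0) stop("`t1_blood` must be positive (ms)")
  n_rr_delay <- as.integer(n_rr_delay)
  if (n_rr_delay < 1L) stop("`n_rr_delay` must be >= 1")
  structure(
    list(base_image = base_image, noise_image = noise_image, pairs = pairs,
         heart_rate = heart_rate, n_rr_delay = n_rr_delay,
         t1_blood = t1_blood, pixel_spacing = pixel_spacing),
    class = "asl_series")
}

#' @export
print.asl_series <- function(x, ...) {
  cat("<asl_series> ", paste(dim(x$base_image), collapse = "x"),
      " grid, 6 control/label pairs\n", sep = "")
  cat("  heart rate ", x$heart_rate, " bpm, PLD ", x$n_rr_delay,
      " RR (", round(compute_td(x$heart_rate, x$n_rr_delay), 1),
      " ms), T1blood ", x$t1_blood, " ms\n", sep = "")
  invisible(x)
}

#' LV myocardial mask with AHA reference geometry
#'
#' @param mask Logical matrix marking left-ventricular myocardium.
#' @param lv_center Numeric length-2, (row, col) of the LV cavity center in
#'   0-based continuous array coordinates.
#' @param rv_insertion_angle Angle (degrees, counter-clockwise from the +col
#'   axis of the displayed image) from `lv_center` to the anterior
#'   right-ventricular insertion point; anchors the AHA segment boundaries.
#'
#' @return An object of class `myocardial_mask`.
#' @seealso [aha6_labels()]
#' @export
myocardial_mask <- function(mask, lv_center, rv_insertion_angle) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!any(mask)) stop("myocardial mask is empty")
  if (length(lv_center) != 2L || any(!is.finite(lv_center)))
    stop("`lv_center` must be finite (row, col) coordinates")
  ctr <- round(lv_center) + 1  # nearest pixel, 1-based
  if (all(ctr >= 1) && ctr[1] <= nrow(mask) && ctr[2] <= ncol(mask) &&
      isTRUE(mask[ctr[1], ctr[2]]))
    stop("`lv_center` falls inside the mask; it must sit in the blood pool")
  structure(list(mask = mask, lv_center = as.numeric(lv_center),
                 rv_insertion_angle = as.numeric(rv_insertion_angle) %% 360),
            class = "myocardial_mask")
}

#' Post-labeling delay from heart rate
#'
#' The FAIR inversion pulses are applied a fixed number of heartbeats before
#' image acquisition, so the post-labeling delay T_D is `n_rr_delay` RR
#' intervals expressed in milliseconds.
#'
#' @param heart_rate Heart rate, beats/min. Must be positive.
#' @param n_rr_delay Number of RR intervals (default 2).
#' @return Post-labeling delay in ms: `n_rr_delay * 60000 / heart_rate`.
#' @examples
#' compute_td(60, 2)   # 2000 ms
#' compute_td(93, 2)   # ~1290 ms
#' @export
compute_td <- function(heart_rate, n_rr_delay = 2L) {
  if (any(!is.finite(heart_rate)) || any(heart_rate <= 0))
    stop("`heart_rate` must be positive (beats/min)")
  if (any(n_rr_delay < 1)) stop("`n_rr_delay` must be >= 1")
  n_rr_delay * 60000 / heart_rate
}

#' Timing parameters for quantification
#'
#' @param heart_rate Heart rate, beats/min.
#' @param n_rr_delay RR intervals of post-labeling delay (default 2).
#' @param t1_blood Blood T1, ms (default 1650).
#' @return List with `t_d` (ms), `t1_blood`, `n_rr_delay`, `heart_rate`.
#' @export
timing_params <- function(heart_rate, n_rr_delay = 2L, t1_blood = 1650) {
  if (t1_blood <= 0) stop("`t1_blood` must be positive (ms)")
  list(t_d = compute_td(heart_rate, n_rr_delay), t1_blood = t1_blood,
       n_rr_delay = as.integer(n_rr_delay), heart_rate = heart_rate)
}
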