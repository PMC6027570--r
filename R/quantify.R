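#' Myocardial blood flow from one control/label pair
#'
#' Inverts the Buxton general kinetic model for FAIR ASL at a single
#' post-labeling delay:
#' \deqn{F = \frac{C - L}{2 \, B \, T_D \, \exp(-T_D / T_{1blood})}}
#' with C, L and B the (mean myocardial) signal in the control, labeled and
#' base images. Times are in ms; F is returned in ml/g/min (the 60000 ms/min
#' conversion is applied internally; the blood-tissue partition coefficient is
#' absorbed as 1 ml/g). Negative values are possible under noise and are
#' deliberately not clipped.
#'
#' @param control,label,base Signal values (a.u.); vectors recycle.
#' @param t_d Post-labeling delay, ms (> 0). See [compute_td()].
#' @param t1_blood Blood T1, ms (default 1650).
#' @return MBF in ml/g/min.
#' @examples
#' mbf_from_pair(100.1, 99.9, 100, t_d = 1290)
#' @export
mbf_from_pair <- function(control, label, base, t_d, t1_blood = 1650) {
  if (any(!is.finite(base)) || any(base <= 0))
    stop("`base` signal must be positive: normalization undefined")
  if (any(t_d <= 0)) stop("`t_d` must be positive (ms)")
  if (any(t1_blood <= 0)) stop("`t1_blood` must be positive (ms)")
  60000 * (control - label) / (2 * base * t_d * exp(-t_d / t1_blood))
}

#' Per-segment, per-pair MBF repeats
#'
#' For each AHA segment and each of the six control/label pairs, MBF is
#' computed from the segment-mean control, label and base signals (mean over
#' the segment's pixels), using the series' recorded heart rate for the
#' post-labeling delay.
#'
#' @param series An [asl_series()].
#' @param labels A `segment_labels` object on the series grid.
#' @return 6 x 6 numeric matrix, rows = segments 1-6, columns = pairs 1-6.
#' @export
segment_mbf_repeats <- function(series, labels) {
  stopifnot(inherits(series, "asl_series"), inherits(labels, "segment_labels"))
  lab <- labels$labels
  if (!identical(dim(lab), dim(series$base_image)))
    stop("segment labels are not on the series grid")
  idx <- lapply(1:6, function(s) which(lab == s))
  npix <- vapply(idx, length, 0L)
  if (any(npix == 0L))
    stop("segment(s) with zero pixels: ",
         paste(aha6_segment_names()[npix == 0L], collapse = ", "))
  t_d <- compute_td(series$heart_rate, series$n_rr_delay)
  b_bar <- vapply(idx, function(i) mean(series$base_image[i]), 0)
  out <- matrix(NA_real_, 6, 6,
                dimnames = list(aha6_segment_names(), paste0("pair", 1:6)))
  for (p in 1:6) {
    c_bar <- vapply(idx, function(i) mean(series$pairs[[p]]$control[i]), 0)
    l_bar <- vapply(idx, function(i) mean(series$pairs[[p]]$label[i]), 0)
    out[, p] <- mbf_from_pair(c_bar, l_bar, b_bar, t_d, series$t1_blood)
  }
  out
}

#' Physiological noise of a segment
#'
#' Physiological noise (PN) is the intra-scan variability of perfusion:
#' the sample standard deviation (n-1 denominator) of the six repeated MBF
#' measurements obtained from the six control/label pairs.
#'
#' @param mbf_repeats Numeric vector of exactly 6 per-pair MBF values.
#' @return PN in ml/g/min.
#' @export
physiological_noise <- function(mbf_repeats) {
  if (length(mbf_repeats) != 6L)
    stop("physiological noise is defined over exactly 6 MBF repeats, got ",
         length(mbf_repeats))
  stats::sd(mbf_repeats)
}

#' Temporal SNR and quality exclusion of a segment
#'
#' tSNR = mean MBF / PN. Segments with tSNR below the threshold (default 2)
#' are flagged for exclusion; the flag never deletes values. At PN = 0 the
#' ratio is taken as +/-Inf by the sign of the mean (a noiseless positive
#' measurement is always included); tSNR exactly at the threshold is
#' included (only tSNR strictly below the threshold is excluded).
#'
#' @param mbf_mean Segment mean MBF, ml/g/min.
#' @param pn Physiological noise, ml/g/min (>= 0).
#' @param threshold Exclusion threshold (default 2).
#' @return List with `tsnr` and logical `included`.
#' @export
tsnr_and_exclude <- function(mbf_mean, pn, threshold = 2) {
  if (any(pn < 0)) stop("`pn` must be >= 0")
  tsnr <- ifelse(pn > 0, mbf_mean / pn,
                 ifelse(mbf_mean > 0, Inf, ifelse(mbf_mean < 0, -Inf, NaN)))
  included <- !is.nan(tsnr) & tsnr >= threshold
  list(tsnr = tsnr, included = included)
}

#' Pixelwise MBF map
#'
#' Per-pixel MBF from the mean control and mean label signal across the six
#' pairs, after spatial(-temporal) filtering of the control, label and base
#' frames within the myocardium. Normalization uses either the pixel's own
#' base signal (`b_mode = "pixel"`) or the segment-mean base signal
#' (`b_mode = "segment"`, requires `labels`). Background pixels are set to
#' `NA` (0 is a valid flow and is never used as a sentinel).
#'
#' @param series An [asl_series()].
#' @param mask A [myocardial_mask()] (or logical matrix).
#' @param spatial_radius,temporal Filter parameters passed to
#'   [spatial_temporal_filter()]; defaults radius 1, temporal averaging on
#'   (display maps pool all pairs anyway).
#' @param b_mode "pixel" or "segment" base-signal normalization.
#' @param labels `segment_labels`, needed for `b_mode = "segment"`.
#' @return Numeric matrix of MBF (ml/g/min), `NA` outside the mask.
#' @export
mbf_map <- function(series, mask, spatial_radius = 1, temporal = TRUE,
                    b_mode = c("pixel", "segment"), labels = NULL) {
  b_mode <- match.arg(b_mode)
  m <- if (inherits(mask, "myocardial_mask")) mask$mask else as.matrix(mask)
  ctrl <- array(unlist(lapply(series$pairs, `[[`, "control")),
                c(dim(m), 6L))
  labl <- array(unlist(lapply(series$pairs, `[[`, "label")),
                c(dim(m), 6L))
  ctrl <- spatial_temporal_filter(ctrl, m, spatial_radius, temporal)
  labl <- spatial_temporal_filter(labl, m, spatial_radius, temporal)
  base <- spatial_temporal_filter(series$base_image, m, spatial_radius, FALSE)
  cbar <- apply(ctrl, c(1, 2), mean)
  lbar <- apply(labl, c(1, 2), mean)
  t_d <- compute_td(series$heart_rate, series$n_rr_delay)
  map <- matrix(NA_real_, nrow(m), ncol(m))
  if (b_mode == "pixel") {
    map[m] <- mbf_from_pair(cbar[m], lbar[m], base[m], t_d, series$t1_blood)
  } else {
    if (is.null(labels)) stop("`labels` required for segment-mean normalization")
    lab <- labels$labels
    for (s in 1:6) {
      i <- which(lab == s)
      if (!length(i)) next
      map[i] <- mbf_from_pair(cbar[i], lbar[i], mean(base[i]), t_d,
                              series$t1_blood)
    }
  }
  map
}

#' Quantify one slice into per-segment perfusion records
#'
#' Runs the regional pipeline for a single slice: per-segment per-pair MBF
#' from segment-mean signals, segment mean MBF, physiological noise, tSNR and
#' the inclusion flag. With `exclusion_enabled = FALSE` (the policy for
#' post-infarction comparisons, where the infarcted segment is expected to
#' have low tSNR) every segment is flagged included regardless of tSNR.
#'
#' @param series An [asl_series()].
#' @param labels A `segment_labels` on the series grid.
#' @param exclusion_enabled Apply the tSNR < threshold exclusion? Default TRUE.
#' @param tsnr_threshold Exclusion threshold (default 2).
#' @return Data frame with one row per segment: `segment`, `segment_name`,
#'   `region`, `mbf`, `pn`, `tsnr`, `included`, and `pair1`..`pair6` (the six
#'   per-pair MBF repeats).
#' @export
quantify_slice <- function(series, labels, exclusion_enabled = TRUE,
                           tsnr_threshold = 2) {
  reps <- segment_mbf_repeats(series, labels)
  mbf <- rowMeans(reps)
  pn <- apply(reps, 1, physiological_noise)
  q <- tsnr_and_exclude(mbf, pn, tsnr_threshold)
  out <- data.frame(
    segment = 1:6,
    segment_name = aha6_segment_names(),
    region = region_of(1:6),
    mbf = unname(mbf), pn = unname(pn), tsnr = unname(q$tsnr),
    included = if (exclusion_enabled) unname(q$included) else rep(TRUE, 6),
    stringsAsFactors = FALSE)
  colnames(reps) <- paste0("pair", 1:6)
  cbind(out, as.data.frame(reps, row.names = seq_len(6)))
}
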