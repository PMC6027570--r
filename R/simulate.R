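#' Forward ASL difference signal for a given flow
#'
#' Inverse of [mbf_from_pair()]: the control-minus-label difference signal
#' produced by a perfusion F under the single-delay Buxton model,
#' `dM = 2 * B * (F/60000) * T_D * exp(-T_D / T1blood)` (times in ms, F in
#' ml/g/min, signal in the units of B). Splitting dM symmetrically around B
#' (control = B + dM/2, label = B - dM/2) and quantifying recovers F exactly.
#'
#' @param f MBF, ml/g/min (may be negative: the model is linear).
#' @param base Base signal B (a.u.), > 0.
#' @param t_d Post-labeling delay, ms, > 0.
#' @param t1_blood Blood T1, ms (default 1650).
#' @return Difference signal dM in a.u.
#' @export
forward_delta_m <- function(f, base, t_d, t1_blood = 1650) {
  if (any(base <= 0)) stop("`base` must be positive")
  if (any(t_d <= 0)) stop("`t_d` must be positive (ms)")
  if (any(t1_blood <= 0)) stop("`t1_blood` must be positive (ms)")
  2 * base * (f / 60000) * t_d * exp(-t_d / t1_blood)
}

#' Calibrate the generator's flow-fluctuation SD against thermal noise
#'
#' Physiological noise as measured by the pipeline is the repeat-to-repeat SD
#' of per-pair segment MBF, which mixes true flow fluctuation with thermal
#' image noise. Thermal noise with per-pixel SD `B/snr` propagates to the
#' segment-mean difference signal with variance `2 * (B/snr)^2 / n_pixels`
#' and through the Buxton denominator to an MBF SD `sigma_thermal`. The
#' generator therefore draws per-pair flow fluctuations with SD
#' `sqrt(max(0, target_pn^2 - sigma_thermal^2))` so that the total measured
#' PN converges to `target_pn` (clipped at 0 when thermal noise alone
#' exceeds the target).
#'
#' @param target_pn Target physiological noise, ml/g/min (>= 0).
#' @param snr Base-image SNR (may be `Inf` for noise-free simulation).
#' @param base Base signal B, a.u.
#' @param t_d Post-labeling delay, ms.
#' @param t1_blood Blood T1, ms (default 1650).
#' @param n_pixels Pixels in the segment whose mean signal is quantified.
#' @return Flow-fluctuation SD `sigma_flow` in ml/g/min.
#' @export
calibrate_flow_noise <- function(target_pn, snr, base, t_d, t1_blood = 1650,
                                 n_pixels) {
  if (any(target_pn < 0)) stop("`target_pn` must be >= 0")
  denom <- 2 * base * t_d * exp(-t_d / t1_blood) / 60000  # a.u. per ml/g/min
  sigma_thermal <- ifelse(is.finite(snr),
                          sqrt(2 / n_pixels) * (base / snr) / denom, 0)
  sqrt(pmax(0, target_pn^2 - sigma_thermal^2))
}

#' Simulate one FAIR-ASL series from a phantom
#'
#' Builds the acquisition the quantification pipeline inverts: a base image
#' (B0 on the annulus plus Gaussian noise of SD B0/SNR), a pure-noise image,
#' and six control/label pairs. For each pair the per-segment flow is the
#' phantom truth plus an independent fluctuation of SD `sigma_flow`
#' (calibrated per segment so measured PN matches the phantom's target; see
#' [calibrate_flow_noise()]); the difference signal follows
#' [forward_delta_m()] and is split symmetrically around B0, with independent
#' thermal noise added to every frame. Negative difference signals are
#' allowed (control >= label is not enforced). Deterministic given `seed`.
#'
#' @param phantom A `phantom_slice` from [build_phantom()].
#' @param seed Integer seed for the noise realization.
#' @param condition "rest" or "stress" (stress requires a paired phantom).
#' @return List with `series` (an [asl_series()]), `labels` (the exact
#'   `segment_labels` used to paint the segments), and `phantom`.
#' @export
simulate_series <- function(phantom, seed, condition = c("rest", "stress")) {
  condition <- match.arg(condition)
  if (phantom$epi_radius <= phantom$endo_radius || phantom$endo_radius <= 0)
    stop("phantom radii invalid: need epi > endo > 0")
  f_true <- if (condition == "stress") phantom$f_true_stress else phantom$f_true
  hr <- if (condition == "stress") phantom$heart_rate_stress else phantom$heart_rate
  if (is.null(f_true))
    stop("phantom has no stress ground truth; use a paired scenario")
  set.seed(as.integer(seed))
  mask <- phantom_mask(phantom)
  labels <- aha6_labels(mask)
  lab <- labels$labels
  idx <- lapply(1:6, function(s) which(lab == s))
  npix <- vapply(idx, length, 0L)
  t_d <- compute_td(hr, phantom$n_rr_delay)
  sigma_pix <- if (is.finite(phantom$snr)) phantom$b0 / phantom$snr else 0
  sigma_flow <- calibrate_flow_noise(phantom$target_pn, phantom$snr,
                                     phantom$b0, t_d, phantom$t1_blood, npix)
  g <- phantom$grid
  noise <- function() if (sigma_pix > 0)
    matrix(stats::rnorm(prod(g), 0, sigma_pix), g[1], g[2])
  else matrix(0, g[1], g[2])
  clean_base <- matrix(0, g[1], g[2]); clean_base[mask$mask] <- phantom$b0
  base_image <- clean_base + noise()
  noise_image <- noise()
  pairs <- vector("list", 6L)
  for (p in 1:6) {
    f_p <- f_true + stats::rnorm(6, 0, sigma_flow)
    dm <- forward_delta_m(f_p, phantom$b0, t_d, phantom$t1_blood)
    ctrl <- clean_base; labl <- clean_base
    for (s in 1:6) {
      ctrl[idx[[s]]] <- ctrl[idx[[s]]] + dm[s] / 2
      labl[idx[[s]]] <- labl[idx[[s]]] - dm[s] / 2
    }
    pairs[[p]] <- list(control = ctrl + noise(), label = labl + noise())
  }
  series <- asl_series(base_image, noise_image, pairs, heart_rate = hr,
                       n_rr_delay = phantom$n_rr_delay,
                       t1_blood = phantom$t1_blood,
                       pixel_spacing = phantom$pixel_spacing)
  list(series = series, labels = labels, phantom = phantom)
}

#' Simulate a synthetic cohort
#'
#' One slice per configured seed; for the paired scenario each slice yields a
#' rest and a stress acquisition sharing ground-truth geometry and jointly
#' drawn true MBF. Scenario defaults reproduce the study's group structure
#' (41 baseline slices over 24 subjects; 25 paired slices over 13 subjects;
#' 9/8/4 post-AMI slices).
#'
#' @param config A [scenario_config()].
#' @return List of records, each `list(subject, slice, condition, timepoint,
#'   series, labels, phantom)`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  out <- list()
  for (i in seq_len(config$n_slices)) {
    ph <- build_phantom(config, i, config$seeds[i])
    rec <- simulate_series(ph, config$seeds[i], "rest")
    out[[length(out) + 1L]] <- c(list(subject = config$subjects[i], slice = i,
                                      condition = "rest",
                                      timepoint = config$timepoint), rec)
    if (config$paired) {
      rec_s <- simulate_series(ph, config$stress_seeds[i], "stress")
      out[[length(out) + 1L]] <- c(list(subject = config$subjects[i],
                                        slice = i, condition = "stress",
                                        timepoint = config$timepoint), rec_s)
    }
  }
  out
}

#' Quantify a simulated (or loaded) cohort into a long results table
#'
#' Runs [quantify_slice()] on every record and stacks the per-segment results
#' into the long cohort table used by the group statistics: one row per
#' (subject, slice, segment, condition, timepoint).
#'
#' @param cohort List of records as returned by [simulate_cohort()] (each
#'   needs `subject`, `slice`, `condition`, `timepoint`, `series`, `labels`).
#' @param exclusion_enabled Apply tSNR exclusion (default TRUE; disable for
#'   post-AMI comparisons).
#' @param tsnr_threshold Exclusion threshold (default 2).
#' @return Data frame with columns `subject`, `slice`, `segment`,
#'   `segment_name`, `region`, `condition`, `timepoint`, `mbf`, `pn`, `tsnr`,
#'   `included`, `pair1`..`pair6`.
#' @export
quantify_cohort <- function(cohort, exclusion_enabled = TRUE,
                            tsnr_threshold = 2) {
  rows <- lapply(cohort, function(rec) {
    q <- quantify_slice(rec$series, rec$labels, exclusion_enabled,
                        tsnr_threshold)
    cbind(data.frame(subject = rec$subject, slice = rec$slice,
                     condition = rec$condition, timepoint = rec$timepoint,
                     stringsAsFactors = FALSE), q)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab[, c("subject", "slice", "segment", "segment_name", "region",
          "condition", "timepoint", "mbf", "pn", "tsnr", "included",
          paste0("pair", 1:6))]
}
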