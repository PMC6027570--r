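#' Scenario configuration for synthetic FAIR-ASL cohorts
#'
#' Defines the study conditions a synthetic cohort emulates. The shipped
#' defaults reproduce the swine study groups: a 41-slice resting baseline
#' cohort (24 animals), a 25-slice paired rest/stress cohort (13 animals),
#' and post-infarction cohorts at 1-2 days (9), 1-2 weeks (8) and 4 weeks (4)
#' with a low-flow anteroseptal infarct. Segment-level true MBF is drawn from
#' a lognormal distribution with the configured mean and between-segment SD
#' (perfusion is positive and right-skewed); the paired scenario couples rest
#' and stress on the log scale with correlation `log_cor`.
#'
#' @param scenario One of "baseline", "rest_stress", "ami_day1", "ami_week1",
#'   "ami_week4".
#' @param n_slices Cohort size in slices; defaults to the study group size.
#' @param seed Integer seed from which the per-slice seed list is drawn.
#' @param mbf_mean,mbf_sd Mean and between-segment SD of resting true MBF
#'   (ml/g/min).
#' @param stress_mbf_mean,stress_mbf_sd Stress counterparts (paired scenario).
#' @param log_cor Rest/stress correlation on the log scale (paired scenario).
#' @param infarct_mbf_mean,infarct_mbf_sd Anteroseptal true-MBF distribution
#'   for the AMI scenarios. The source study reports no numeric infarct MBF;
#'   these defaults are synthetic stand-ins chosen low enough that tSNR < 2
#'   typically flags the infarcted segment.
#' @param target_pn Target physiological noise: repeat-to-repeat SD of
#'   per-pair segment MBF (ml/g/min).
#' @param snr_mean,snr_sd,snr_range Base-image SNR distribution (truncated
#'   normal).
#' @param hr_mean,hr_sd,stress_hr_mean,stress_hr_sd Heart-rate distributions
#'   (bpm).
#' @param grid,pixel_spacing,endo_radius,epi_radius,rv_insertion_angle,b0
#'   Annulus geometry (pixels / mm / degrees) and base signal level (a.u.).
#' @param n_rr_delay,t1_blood Timing defaults (2 RR; 1650 ms).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("baseline", "rest_stress",
                                         "ami_day1", "ami_week1", "ami_week4"),
                            n_slices = NULL, seed = 1L,
                            mbf_mean = 1.08, mbf_sd = 0.62,
                            stress_mbf_mean = 1.47, stress_mbf_sd = 0.62,
                            log_cor = 0.62,
                            infarct_mbf_mean = NULL, infarct_mbf_sd = 0.10,
                            target_pn = 0.15,
                            snr_mean = 98, snr_sd = 31, snr_range = c(37, 155),
                            hr_mean = 93, hr_sd = 9,
                            stress_hr_mean = 87, stress_hr_sd = 6,
                            grid = c(96L, 96L), pixel_spacing = 1.5,
                            endo_radius = 11, epi_radius = 18,
                            rv_insertion_angle = 120, b0 = 100,
                            n_rr_delay = 2L, t1_blood = 1650) {
  scenario <- match.arg(scenario)
  defaults <- list(baseline = 41L, rest_stress = 25L,
                   ami_day1 = 9L, ami_week1 = 8L, ami_week4 = 4L)
  if (is.null(n_slices)) n_slices <- defaults[[scenario]]
  n_slices <- as.integer(n_slices)
  if (n_slices < 1L) stop("`n_slices` must be >= 1")
  if (epi_radius <= endo_radius || endo_radius <= 0)
    stop("need epi_radius > endo_radius > 0")
  if (target_pn < 0) stop("`target_pn` must be >= 0")
  # paired rest group of the study: rest SD 0.54 among the 13 stress animals
  if (scenario == "rest_stress" && missing(mbf_sd)) mbf_sd <- 0.54
  if (is.null(infarct_mbf_mean))
    infarct_mbf_mean <- switch(scenario, ami_day1 = 0.20, ami_week1 = 0.20,
                               ami_week4 = 0.25, NA_real_)
  timepoint <- switch(scenario, baseline = "baseline", rest_stress = "baseline",
                      ami_day1 = "day1_2", ami_week1 = "week1_2",
                      ami_week4 = "week4")
  paired <- scenario == "rest_stress"
  seed <- as.integer(seed)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_slices * (1L + paired))
  cfg <- list(scenario = scenario, n_slices = n_slices, seed = seed,
              seeds = seeds[seq_len(n_slices)],
              stress_seeds = if (paired) seeds[n_slices + seq_len(n_slices)],
              subjects = .assign_subjects(scenario, n_slices),
              timepoint = timepoint, paired = paired,
              mbf_mean = mbf_mean, mbf_sd = mbf_sd,
              stress_mbf_mean = stress_mbf_mean, stress_mbf_sd = stress_mbf_sd,
              log_cor = log_cor,
              infarct_mbf_mean = infarct_mbf_mean,
              infarct_mbf_sd = infarct_mbf_sd,
              target_pn = target_pn,
              snr_mean = snr_mean, snr_sd = snr_sd, snr_range = snr_range,
              hr_mean = hr_mean, hr_sd = hr_sd,
              stress_hr_mean = stress_hr_mean, stress_hr_sd = stress_hr_sd,
              grid = as.integer(grid), pixel_spacing = pixel_spacing,
              endo_radius = endo_radius, epi_radius = epi_radius,
              rv_insertion_angle = rv_insertion_angle, b0 = b0,
              n_rr_delay = as.integer(n_rr_delay), t1_blood = t1_blood)
  structure(cfg, class = "scenario_config")
}

# Study-like subject assignment: animals contribute 1-3 slices each.
.assign_subjects <- function(scenario, n) {
  n_subj <- switch(scenario, baseline = 24L, rest_stress = 13L, n)
  n_subj <- min(n_subj, n)
  # round-robin: first (n - n_subj) subjects get a 2nd slice, then a 3rd, ...
  sort(rep(seq_len(n_subj), length.out = n))
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> ", x$scenario, ": ", x$n_slices, " slices, ",
      length(unique(x$subjects)), " subjects\n", sep = "")
  cat("  rest MBF ", x$mbf_mean, " ± ", x$mbf_sd, " ml/g/min, target PN ",
      x$target_pn, ", SNR ", x$snr_mean, ", HR ", x$hr_mean, " bpm\n", sep = "")
  invisible(x)
}

# lognormal parameters for a given arithmetic mean and SD
.lnorm_params <- function(m, s) {
  if (m <= 0) stop("lognormal mean must be positive")
  sdlog <- sqrt(log1p((s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

.rtruncnorm1 <- function(mean, sd, lo = -Inf, hi = Inf) {
  for (i in 1:1000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  stop("truncated-normal rejection failed; check bounds")
}

#' Ground-truth phantom for one synthetic slice
#'
#' Draws one slice's ground truth from a scenario: annulus geometry,
#' per-segment true MBF, base-image SNR and heart rate. For the paired
#' scenario, rest and stress true MBF are drawn jointly (bivariate lognormal)
#' along with separate heart rates. For the AMI scenarios the anteroseptal
#' (infarct) segment is overridden by the low-flow infarct distribution while
#' the remaining segments follow the baseline distribution. Deterministic
#' given `seed`.
#'
#' @param config A [scenario_config()].
#' @param slice_index Slice index within the cohort (1-based).
#' @param seed Integer seed for this slice's ground-truth draw.
#' @return An object of class `phantom_slice` with fields `grid`,
#'   `lv_center`, `endo_radius`/`epi_radius` (mm), `rv_insertion_angle`,
#'   `f_true` (6 segments, ml/g/min; plus `f_true_stress` when paired), `b0`,
#'   `snr`, `target_pn`, `heart_rate` (plus `heart_rate_stress` when paired),
#'   and acquisition metadata.
#' @export
build_phantom <- function(config, slice_index, seed) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(as.integer(seed))
  snr <- .rtruncnorm1(config$snr_mean, config$snr_sd,
                      config$snr_range[1], config$snr_range[2])
  hr <- .rtruncnorm1(config$hr_mean, config$hr_sd, lo = 40)
  f_stress <- NULL; hr_stress <- NULL
  if (config$paired) {
    pr <- .lnorm_params(config$mbf_mean, config$mbf_sd)
    ps <- .lnorm_params(config$stress_mbf_mean, config$stress_mbf_sd)
    z1 <- stats::rnorm(6); z2 <- stats::rnorm(6)
    zs <- config$log_cor * z1 + sqrt(1 - config$log_cor^2) * z2
    f_true <- exp(pr$meanlog + pr$sdlog * z1)
    f_stress <- exp(ps$meanlog + ps$sdlog * zs)
    hr_stress <- .rtruncnorm1(config$stress_hr_mean, config$stress_hr_sd,
                              lo = 40)
  } else {
    pr <- .lnorm_params(config$mbf_mean, config$mbf_sd)
    f_true <- stats::rlnorm(6, pr$meanlog, pr$sdlog)
    if (startsWith(config$scenario, "ami")) {
      pi_ <- .lnorm_params(config$infarct_mbf_mean, config$infarct_mbf_sd)
      f_true[2L] <- stats::rlnorm(1, pi_$meanlog, pi_$sdlog)  # anteroseptal
    }
  }
  structure(list(
    grid = config$grid,
    lv_center = (config$grid - 1) / 2,
    pixel_spacing = config$pixel_spacing,
    endo_radius = config$endo_radius, epi_radius = config$epi_radius,
    rv_insertion_angle = config$rv_insertion_angle,
    f_true = f_true, f_true_stress = f_stress,
    b0 = config$b0, snr = snr, target_pn = config$target_pn,
    heart_rate = hr, heart_rate_stress = hr_stress,
    n_rr_delay = config$n_rr_delay, t1_blood = config$t1_blood,
    scenario = config$scenario, timepoint = config$timepoint,
    slice_index = slice_index, seed = as.integer(seed)),
    class = "phantom_slice")
}

#' Myocardial annulus mask of a phantom
#'
#' @param phantom A `phantom_slice`.
#' @return A [myocardial_mask()] marking pixels whose center-distance (mm)
#'   lies in (endo_radius, epi_radius].
#' @export
phantom_mask <- function(phantom) {
  g <- phantom$grid
  rows <- matrix(0:(g[1] - 1), g[1], g[2])
  cols <- matrix(0:(g[2] - 1), g[1], g[2], byrow = TRUE)
  d <- sqrt((rows - phantom$lv_center[1])^2 +
            (cols - phantom$lv_center[2])^2) * phantom$pixel_spacing
  myocardial_mask(d > phantom$endo_radius & d <= phantom$epi_radius,
                  phantom$lv_center, phantom$rv_insertion_angle)
}
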