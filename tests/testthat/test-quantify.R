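test_that("post-labeling delay follows the RR interval", {
  expect_equal(compute_td(60, 2), 2000)
  expect_equal(compute_td(120, 1), 500)
  expect_equal(compute_td(93, 2), 2 * 60000 / 93)  # ~1290.3 ms at study HR
  expect_error(compute_td(0), "positive")
  expect_error(compute_td(-50), "positive")
  expect_error(timing_params(93, t1_blood = 0), "t1_blood")
})

test_that("Buxton inversion matches independent arithmetic", {
  # C - L = 0.2, B = 100, T_D = 1290 ms, T1blood = 1650 ms
  expected <- 60000 * 0.2 / (2 * 100 * 1290 * exp(-1290 / 1650))
  expect_equal(expected, 0.1016485, tolerance = 1e-6)
  expect_equal(mbf_from_pair(100.1, 99.9, 100, 1290, 1650), expected)
  expect_equal(mbf_from_pair(5, 5, 7, 1000), 0)     # zero difference
  expect_error(mbf_from_pair(1, 0.9, 0, 1000), "positive")
  expect_error(mbf_from_pair(1, 0.9, 1, -5), "positive")
})

test_that("forward and inverse model are exact algebraic inverses", {
  set.seed(13)
  for (i in 1:50) {
    f <- stats::runif(1, -1, 5)
    b <- stats::runif(1, 10, 500)
    t_d <- stats::runif(1, 400, 3000)
    t1b <- stats::runif(1, 1000, 2200)
    dm <- forward_delta_m(f, b, t_d, t1b)
    expect_equal(mbf_from_pair(b + dm / 2, b - dm / 2, b, t_d, t1b), f,
                 tolerance = 1e-12)
  }
  expect_equal(forward_delta_m(0, 100, 1290), 0)
  # direct formula evaluation of the difference signal at unit flow
  expect_equal(forward_delta_m(1, 100, 1290, 1650),
               2 * 100 * (1 / 60000) * 1290 * exp(-1290 / 1650))
  expect_error(forward_delta_m(1, 100, -10), "positive")
})

test_that("MBF is scale-invariant in signal and monotone in its arguments", {
  f0 <- mbf_from_pair(101, 99, 100, 1290)
  for (k in c(0.01, 0.5, 7, 1e4))
    expect_equal(mbf_from_pair(101 * k, 99 * k, 100 * k, 1290), f0)
  # linear in (C - L)
  expect_equal(mbf_from_pair(103, 99, 100, 1290), 2 * f0)
  # strictly decreasing in B
  expect_lt(mbf_from_pair(101, 99, 150, 1290), f0)
})

test_that("noise-free segment repeats equal the phantom truth", {
  f_true <- c(0.4, 0.9, 1.3, 1.8, 2.2, 0.05)
  rec <- simulate_series(make_phantom(f_true), seed = 5)
  reps <- segment_mbf_repeats(rec$series, rec$labels)
  for (p in 1:6) expect_equal(unname(reps[, p]), f_true, tolerance = 1e-12)
  # permuting pair order permutes columns only
  s2 <- rec$series
  s2$pairs <- s2$pairs[c(3, 1, 2, 6, 4, 5)]
  expect_equal(segment_mbf_repeats(s2, rec$labels),
               reps[, c(3, 1, 2, 6, 4, 5)], ignore_attr = TRUE)
})

test_that("segment-mean and pixelwise-map routes agree on noise-free input", {
  f_true <- c(0.5, 1, 1.5, 2, 2.5, 3)
  rec <- simulate_series(make_phantom(f_true), seed = 9)
  mask <- myocardial_mask(rec$labels$labels > 0, rec$labels$lv_center,
                          rec$labels$rv_insertion_angle)
  map <- mbf_map(rec$series, mask, spatial_radius = 0, temporal = FALSE)
  expect_true(all(is.na(map[!mask$mask])))
  reps <- segment_mbf_repeats(rec$series, rec$labels)
  for (s in 1:6) {
    expect_equal(unique(round(map[rec$labels$labels == s], 9)), f_true[s])
    expect_equal(mean(map[rec$labels$labels == s]), mean(reps[s, ]),
                 tolerance = 1e-9)
  }
  # segment-mean base normalization agrees too (uniform B)
  map2 <- mbf_map(rec$series, mask, spatial_radius = 0, temporal = FALSE,
                  b_mode = "segment", labels = rec$labels)
  expect_equal(map2[mask$mask], map[mask$mask], tolerance = 1e-9)
})

test_that("physiological noise is the n-1 SD of the six repeats", {
  expect_equal(physiological_noise(1:6), oracle_sd(1:6))
  expect_equal(physiological_noise(1:6), 1.870829, tolerance = 1e-6)
  expect_equal(physiological_noise(rep(3.2, 6)), 0)
  expect_error(physiological_noise(1:5), "exactly 6")
  x <- c(0.9, 1.4, 1.1, 0.7, 1.6, 1.2)
  expect_equal(physiological_noise(-2.5 * x), 2.5 * physiological_noise(x))
})

test_that("tSNR exclusion applies the threshold as a retained flag", {
  q <- tsnr_and_exclude(1.08, 0.15)
  expect_equal(q$tsnr, 7.2)
  expect_true(q$included)
  q2 <- tsnr_and_exclude(0.2, 0.15)
  expect_equal(q2$tsnr, 4 / 3, tolerance = 1e-12)
  expect_false(q2$included)
  expect_true(tsnr_and_exclude(0.3, 0.15)$included)   # exactly 2 stays in
  q3 <- tsnr_and_exclude(0.5, 0)
  expect_equal(q3$tsnr, Inf)
  expect_true(q3$included)
  expect_false(tsnr_and_exclude(-0.5, 0)$included)
  expect_error(tsnr_and_exclude(1, -0.1), ">= 0")
})

test_that("raising PN at fixed mean MBF can only exclude, never re-include", {
  pn_grid <- seq(0, 1, by = 0.02)
  inc <- tsnr_and_exclude(rep(0.9, length(pn_grid)), pn_grid)$included
  expect_false(is.unsorted(rev(inc)))  # monotone TRUE -> FALSE
})

test_that("quantify_slice composes the pieces and honors the exclusion policy", {
  f_true <- c(1.2, 0.1, 1.0, 1.1, 0.9, 1.4)  # low-flow anteroseptal
  rec <- simulate_series(make_phantom(f_true, snr = 98, target_pn = 0.15),
                         seed = 31)
  q <- quantify_slice(rec$series, rec$labels)
  expect_equal(q$mbf, rowMeans(as.matrix(q[, paste0("pair", 1:6)])),
               ignore_attr = TRUE)
  expect_equal(q$pn, apply(as.matrix(q[, paste0("pair", 1:6)]), 1, oracle_sd),
               ignore_attr = TRUE)
  expect_equal(q$region, region_of(1:6))
  expect_false(q$included[2])  # tSNR ~ 0.7 for the infarct-like segment
  q2 <- quantify_slice(rec$series, rec$labels, exclusion_enabled = FALSE)
  expect_true(all(q2$included))
  expect_equal(q2$mbf, q$mbf)  # policy changes flags, never values
  # noise-free: PN = 0, everything included
  rec0 <- simulate_series(make_phantom(f_true), seed = 31)
  q0 <- quantify_slice(rec0$series, rec0$labels)
  expect_equal(q0$pn, rep(0, 6))
  expect_true(all(q0$included))
})
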