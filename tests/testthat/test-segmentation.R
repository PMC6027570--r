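std_mask <- function(rv_angle = 120) {
  ph <- make_phantom(f_true = rep(1, 6), grid = c(96L, 96L), endo = 11,
                     epi = 18, rv_angle = rv_angle)
  phantom_mask(ph)
}

test_that("AHA labels tile the mask exactly", {
  for (a in c(0, 17, 120, 251.3)) {
    m <- std_mask(a)
    lab <- aha6_labels(m)$labels
    expect_identical(lab > 0L, m$mask)           # no label outside the mask
    expect_equal(sum(tabulate(lab[lab > 0L], 6L)), sum(m$mask))
    expect_true(all(tabulate(lab[lab > 0L], 6L) > 0L))
  }
})

test_that("a symmetric annulus splits into six near-equal segments", {
  m <- std_mask(120)
  counts <- tabulate(aha6_labels(m)$labels[m$mask], 6L)
  expect_lte(max(counts) - min(counts), 1L)
})

test_that("rotating the RV insertion by 60 degrees cyclically permutes labels", {
  m1 <- std_mask(77)
  m2 <- std_mask(77 + 60)
  l1 <- aha6_labels(m1)$labels
  l2 <- aha6_labels(m2)$labels
  keep <- l1 > 0L
  # each wedge hands its pixels to the previous segment in ring order
  expect_identical(l2[keep], ((l1[keep] - 2L) %% 6L) + 1L)
})

test_that("wedge assignment matches a brute-force angle oracle", {
  set.seed(101)
  m <- std_mask(0)
  for (i in 1:200) {
    rv <- stats::runif(1, 0, 360)
    lab <- aha6_labels(myocardial_mask(m$mask, m$lv_center, rv))$labels
    px <- which(m$mask, arr.ind = TRUE)[sample(sum(m$mask), 1), ]
    theta <- (atan2(-(px[1] - 1 - m$lv_center[1]),
                    px[2] - 1 - m$lv_center[2]) * 180 / pi) %% 360
    wedge <- floor(((theta - rv) %% 360) / 60)  # 0 = anteroseptal side
    expected <- c(2L, 3L, 4L, 5L, 6L, 1L)[wedge + 1]
    expect_identical(lab[px[1], px[2]], expected)
  }
  # spec'd landmark: a pixel 30 degrees past the RV insertion is anteroseptal
  rv <- 120
  theta <- (rv + 30) * pi / 180
  r <- 10  # pixels
  px <- round(c(m$lv_center[1] - r * sin(theta), m$lv_center[2] + r * cos(theta)))
  lab <- aha6_labels(myocardial_mask(m$mask, m$lv_center, rv))$labels
  expect_identical(lab[px[1] + 1, px[2] + 1], 2L)
})

test_that("region grouping follows the infarct/remote map", {
  expect_equal(region_of(2), "infarct")                    # anteroseptal
  expect_equal(region_of(c(4, 5, 6)), rep("remote", 3))    # inferior group
  expect_equal(region_of(c(1, 3)), rep("other", 2))
  expect_equal(region_of("anteroseptal"), "infarct")
  expect_error(region_of(7), "1..6")
})

test_that("spatial filter is an in-mask neighbourhood mean", {
  m <- std_mask()
  u <- matrix(5.5, 96, 96)
  expect_equal(spatial_temporal_filter(u, m, spatial_radius = 1), u)
  x <- matrix(rnorm(96 * 96), 96, 96)
  expect_identical(spatial_temporal_filter(x, m, spatial_radius = 0), x)
  f <- spatial_temporal_filter(x, m, spatial_radius = 1)
  expect_identical(f[!m$mask], x[!m$mask])  # background untouched
  # hand-check one interior pixel: mean over in-mask 4-neighbourhood + self
  px <- which(m$mask, arr.ind = TRUE)
  interior <- px[m$mask[cbind(px[, 1] - 1, px[, 2])] &
                 m$mask[cbind(px[, 1] + 1, px[, 2])] &
                 m$mask[cbind(px[, 1], px[, 2] - 1)] &
                 m$mask[cbind(px[, 1], px[, 2] + 1)], , drop = FALSE]
  p <- interior[7, ]
  nb <- rbind(p, p + c(-1, 0), p + c(1, 0), p + c(0, -1), p + c(0, 1))
  expect_equal(f[p[1], p[2]], mean(x[nb]))
  expect_error(spatial_temporal_filter(x, m, spatial_radius = -1), ">= 0")
})

test_that("filtering white noise shrinks variance by the neighbour count", {
  m <- std_mask()
  px <- which(m$mask, arr.ind = TRUE)
  interior <- m$mask[cbind(px[, 1] - 1, px[, 2])] &
    m$mask[cbind(px[, 1] + 1, px[, 2])] &
    m$mask[cbind(px[, 1], px[, 2] - 1)] &
    m$mask[cbind(px[, 1], px[, 2] + 1)]
  set.seed(7)
  vals <- replicate(400, {
    x <- matrix(rnorm(96 * 96), 96, 96)
    spatial_temporal_filter(x, m, spatial_radius = 1)[px[interior, ]][1:50]
  })
  # radius-1 Euclidean neighbourhood holds 5 pixels -> variance ~ 1/5
  expect_equal(stats::var(as.vector(vals)), 1 / 5, tolerance = 0.05)
})

test_that("temporal averaging pools corresponding frames within the mask", {
  m <- std_mask()
  stack <- array(rnorm(96 * 96 * 4), c(96, 96, 4))
  f <- spatial_temporal_filter(stack, m, spatial_radius = 0, temporal = TRUE)
  tm <- apply(stack, c(1, 2), mean)
  for (k in 1:4) {
    fr <- f[, , k]
    expect_equal(fr[m$mask], tm[m$mask])
    expect_identical(fr[!m$mask], stack[, , k][!m$mask])
  }
})
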