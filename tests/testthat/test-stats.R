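test_that("paired t-test matches the textbook formula", {
  set.seed(17)
  for (i in 1:10) {
    x <- rnorm(5, 1.1, 0.5); y <- rnorm(5, 1.4, 0.6)
    got <- paired_ttest(x, y)
    want <- oracle_paired_t(x, y)
    expect_equal(got$t, want$t, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
  x <- c(1, 2, 3.5)
  expect_equal(paired_ttest(x, x), list(t = 0, df = 2L, p = 1, mean_diff = 0,
                                        n = 3L))
  # sign flip of all differences negates t, p unchanged
  y <- x + c(0.4, -0.2, 0.9)
  a <- paired_ttest(x, y); b <- paired_ttest(y, x)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  expect_error(paired_ttest(c(1, 2), c(2, 3)), "degenerate")
  expect_error(paired_ttest(1, 2), "at least 2")
  expect_error(paired_ttest(1:3, 1:4), "equal length")
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  got <- oneway_anova(list(c(1, 2, 3), c(4, 5, 6)))
  # SSB = 13.5 (df 1), SSW = 4 (df 4) -> F = 13.5
  expect_equal(got$F_stat, 13.5, tolerance = 1e-12)
  expect_equal(got$p, stats::pf(13.5, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  set.seed(23)
  groups <- lapply(c(5, 7, 4), function(n) rnorm(n, 1, 0.5))
  got <- oneway_anova(groups)
  want <- oracle_anova_f(groups)
  expect_equal(got$F_stat, want$F_stat, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  # location invariance
  shifted <- lapply(groups, `+`, 100)
  expect_equal(oneway_anova(shifted)$F_stat, got$F_stat, tolerance = 1e-9)
  # equal means, within-group spread -> F = 0
  expect_equal(oneway_anova(list(c(1, 2), c(1, 2)))$F_stat, 0)
  expect_error(oneway_anova(list(1, c(2, 3))), "at least 2 values")
  expect_error(oneway_anova(list(c(1, 2))), "at least 2 groups")
})

test_that("Holm-Sidak adjustment follows the step-down formula", {
  expect_equal(holm_sidak(0.37), 0.37)                    # m = 1: identity
  expect_equal(holm_sidak(c(0.01, 0.04)), c(1 - 0.99^2, 0.04))
  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    adj <- holm_sidak(p)
    expect_equal(adj, oracle_sidak_stepdown(p), tolerance = 1e-12)
    expect_true(all(adj >= p))                            # never less than raw
    expect_true(all(adj <= 1))
    expect_false(is.unsorted(adj[order(p)]))              # monotone after sort
    perm <- sample(length(p))
    expect_equal(holm_sidak(p[perm]), adj[perm])          # order-invariant
  }
  expect_error(holm_sidak(c(0.5, 1.2)), "\\[0, 1\\]")
})

make_paired_table <- function(inc_rest, inc_stress, mbf_rest, mbf_stress) {
  n <- length(mbf_rest)
  rbind(
    data.frame(subject = 1, slice = rep(1:ceiling(n / 6), each = 6)[1:n],
               segment = rep(1:6, length.out = n), region = region_of(rep(1:6, length.out = n)),
               condition = "rest", timepoint = "baseline",
               mbf = mbf_rest, pn = 0.1, tsnr = 5, included = inc_rest),
    data.frame(subject = 1, slice = rep(1:ceiling(n / 6), each = 6)[1:n],
               segment = rep(1:6, length.out = n), region = region_of(rep(1:6, length.out = n)),
               condition = "stress", timepoint = "baseline",
               mbf = mbf_stress, pn = 0.1, tsnr = 5, included = inc_stress))
}

test_that("paired filtering drops a segment excluded in either condition", {
  tab <- make_paired_table(inc_rest = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
                           inc_stress = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
                           mbf_rest = seq(1, 1.5, length.out = 6),
                           mbf_stress = seq(1.4, 2.1, length.out = 6))
  pr <- filter_paired(tab)
  expect_equal(pr$kept, 4)
  expect_equal(pr$dropped, 2)                  # stress-only exclusion drops too
  expect_equal(pr$kept + pr$dropped, 6)        # conservation
  expect_equal(pr$x, tab$mbf[c(1, 3, 5, 6)])
  all_in <- make_paired_table(rep(TRUE, 6), rep(TRUE, 6), rep(1, 6), rep(1.5, 6))
  expect_equal(filter_paired(all_in)$kept, 6)
})

test_that("perfusion reserve is the per-segment stress/rest ratio", {
  expect_equal(mpr(c(1, 1, 1), c(1, 1, 1))$mean, 1)
  expect_equal(mpr(1.0, 1.5)$ratio, 1.5)
  r <- mpr(c(1, 2, 0), c(1.5, 3, 1))
  expect_true(is.na(r$ratio[3]))               # undefined at nonpositive rest
  expect_equal(r$n_undefined, 1)
  expect_equal(r$n, 2)
  expect_equal(r$mean, 1.5)
  expect_equal(r$percent_increase, 50)
})

test_that("regional summaries pool the remote segments", {
  tab <- make_paired_table(rep(TRUE, 12), rep(TRUE, 12),
                           mbf_rest = c(1:6, 7:12) / 6,
                           mbf_stress = rep(1.5, 12))
  s <- regional_summary(tab)
  rem <- s[s$region == "remote" & s$condition == "rest", ]
  remote_vals <- tab$mbf[tab$condition == "rest" &
                           tab$segment %in% c(4, 5, 6)]
  expect_equal(rem$mean, mean(remote_vals))
  expect_equal(rem$sd, sd(remote_vals))
  expect_equal(rem$n, 6L)
  one <- regional_summary(tab[1, , drop = FALSE])
  expect_equal(one$mean, tab$mbf[1])
  expect_equal(one$sd, 0)                      # n = 1: SD reported as 0
  expect_equal(one$n, 1L)
})

test_that("cross-sectional comparison detects a large flow deficit", {
  set.seed(91)
  tab <- data.frame(
    region = "infarct", condition = "rest", included = TRUE,
    timepoint = rep(c("baseline", "day1_2", "week1_2", "week4"),
                    c(41, 9, 8, 4)),
    mbf = c(rnorm(41, 1.08, 0.62), rnorm(9, 0.2, 0.1),
            rnorm(8, 0.2, 0.1), rnorm(4, 0.25, 0.1)))
  cs <- cross_sectional_compare(tab, "infarct")
  expect_true(all(cs$comparisons$significant))
  expect_true(all(cs$comparisons$diff < 0))
  expect_lt(cs$anova$p, 0.001)
  expect_error(cross_sectional_compare(tab[tab$timepoint != "baseline", ],
                                       "infarct"), "baseline")
})
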