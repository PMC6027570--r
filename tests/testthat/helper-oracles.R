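# Independent brute-force oracles, written from textbook formulas and kept
# deliberately separate from the package implementations they check.

oracle_sd <- function(x) {
  n <- length(x)
  sqrt(sum((x - sum(x) / n)^2) / (n - 1))
}

oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  dbar <- sum(d) / n
  se <- oracle_sd(d) / sqrt(n)
  t <- dbar / se
  list(t = t, p = 2 * stats::pt(-abs(t), n - 1))
}

oracle_anova_f <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  k <- length(groups); n <- length(all_v)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F_stat = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

oracle_sidak_stepdown <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(seq_len(i), function(j) 1 - (1 - p[o][j])^(m - j + 1), 0)
    adj_sorted[i] <- min(1, max(cand))
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# Phantom with fully specified ground truth (no distributional draw), for
# controlled round-trip and noise experiments.
make_phantom <- function(f_true, snr = Inf, target_pn = 0,
                         grid = c(64L, 64L), endo = 9, epi = 15,
                         rv_angle = 120, b0 = 100, heart_rate = 93,
                         pixel_spacing = 1.5, f_true_stress = NULL,
                         heart_rate_stress = NULL) {
  structure(list(
    grid = as.integer(grid), lv_center = (grid - 1) / 2,
    pixel_spacing = pixel_spacing, endo_radius = endo, epi_radius = epi,
    rv_insertion_angle = rv_angle, f_true = f_true,
    f_true_stress = f_true_stress, b0 = b0, snr = snr,
    target_pn = target_pn, heart_rate = heart_rate,
    heart_rate_stress = heart_rate_stress, n_rr_delay = 2L, t1_blood = 1650,
    scenario = "manual", timepoint = "baseline", slice_index = 1L,
    seed = NA_integer_), class = "phantom_slice")
}
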