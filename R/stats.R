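#' Paired two-sided t-test
#'
#' Compares paired observations (pairing by index), as used for regional MBF
#' at rest versus stress. Pairs with an excluded member should be removed
#' beforehand with [filter_paired()]. The degenerate case of identical
#' vectors returns t = 0, p = 1; nonzero differences with zero variance are
#' an error (the statistic is undefined).
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return List with `t`, `df`, `p` (two-sided), `mean_diff`, `n`.
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, df = length(d) - 1L, p = 1, mean_diff = 0,
                  n = length(d)))
    stop("degenerate paired t-test: constant nonzero differences")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate), n = length(d))
}

#' Ordinary one-way ANOVA
#'
#' Classic fixed-effects one-way analysis of variance (between/within
#' mean-square ratio, equal-variance F test), as used for the cross-sectional
#' comparison of regional MBF across timepoints.
#'
#' @param groups List of >= 2 numeric vectors, each with >= 2 values.
#' @return List with `F_stat`, `df1`, `df2`, `p`, and the pooled residual
#'   mean square `mse` (used by the pairwise follow-up tests).
#' @export
oneway_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least 2 groups")
  n <- vapply(groups, length, 0L)
  if (any(n < 2L)) stop("every group needs at least 2 values")
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), n))
  if (stats::var(values) == 0) stop("zero overall variance: F undefined")
  ft <- stats::oneway.test(values ~ g, var.equal = TRUE)
  k <- length(groups); N <- length(values)
  mse <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0)) / (N - k)
  list(F_stat = unname(ft$statistic), df1 = unname(ft$parameter[1]),
       df2 = unname(ft$parameter[2]), p = ft$p.value, mse = mse)
}

#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' Step-down Sidak procedure: with the m raw p-values sorted ascending, the
#' i-th smallest is adjusted to `1 - (1 - p_(i))^(m - i + 1)`, running maxima
#' are enforced for monotonicity, the results are clipped at 1 and mapped
#' back to the input order. Controls the family-wise error rate at the
#' nominal level under independence (slightly conservatively under positive
#' dependence).
#'
#' @param pvals Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @examples
#' holm_sidak(c(0.01, 0.04))  # 1 - 0.99^2 = 0.0199, then 0.04
#' @export
holm_sidak <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  if (m == 0L) return(numeric(0))
  o <- order(pvals)
  adj <- 1 - (1 - pvals[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Extract rest/stress pairs kept under both-condition exclusion
#'
#' Pairs per (subject, slice, segment) are kept only when the segment is
#' included in *both* conditions; a segment excluded at either rest or stress
#' drops the whole pair.
#'
#' @param table Cohort table (see [quantify_cohort()]).
#' @param condition_a,condition_b Condition labels (default rest / stress).
#' @return List with vectors `x` (condition_a MBF) and `y` (condition_b MBF)
#'   aligned by pair, the `pairs` data frame, and counts `kept` / `dropped`.
#' @export
filter_paired <- function(table, condition_a = "rest",
                          condition_b = "stress") {
  a <- table[table$condition == condition_a, ]
  b <- table[table$condition == condition_b, ]
  key <- function(d) paste(d$subject, d$slice, d$segment, sep = "/")
  a <- a[!duplicated(key(a)), ]; b <- b[!duplicated(key(b)), ]
  m <- match(key(a), key(b))
  ok <- !is.na(m)
  a <- a[ok, ]; b <- b[m[ok], ]
  keep <- a$included & b$included
  list(x = a$mbf[keep], y = b$mbf[keep],
       pairs = data.frame(subject = a$subject[keep], slice = a$slice[keep],
                          segment = a$segment[keep],
                          mbf_a = a$mbf[keep], mbf_b = b$mbf[keep]),
       kept = sum(keep), dropped = sum(!keep))
}

#' Myocardial perfusion reserve
#'
#' Per-segment ratio of stress to rest MBF, summarized as mean +/- SD.
#' Segments with nonpositive rest MBF have an undefined reserve; they are
#' flagged `NA` and omitted from the summary with a count.
#'
#' @param rest_mbf,stress_mbf Numeric vectors aligned by segment.
#' @return List with `ratio` (per-segment, `NA` where undefined), `mean`,
#'   `sd`, `n`, `n_undefined`, and `percent_increase`
#'   (`100 * (mean - 1)`).
#' @export
mpr <- function(rest_mbf, stress_mbf) {
  if (length(rest_mbf) != length(stress_mbf))
    stop("rest and stress vectors must align")
  ratio <- ifelse(rest_mbf > 0, stress_mbf / rest_mbf, NA_real_)
  ok <- !is.na(ratio)
  list(ratio = ratio, mean = mean(ratio[ok]),
       sd = if (sum(ok) > 1) stats::sd(ratio[ok]) else 0,
       n = sum(ok), n_undefined = sum(!ok),
       percent_increase = 100 * (mean(ratio[ok]) - 1))
}

#' Regional summary table (mean +/- SD by region, timepoint, condition)
#'
#' Summaries are over rows flagged `included` (tables built without exclusion
#' have every row included, matching the post-AMI comparison policy). The
#' remote region pools its three segments.
#'
#' @param table Cohort table.
#' @return Data frame with `region`, `timepoint`, `condition`, `mean`, `sd`
#'   (0 when n = 1), `n`.
#' @export
regional_summary <- function(table) {
  t2 <- table[table$included, ]
  if (!nrow(t2)) stop("no included rows to summarize")
  agg <- stats::aggregate(mbf ~ region + timepoint + condition, data = t2,
                          FUN = function(v) c(mean = mean(v),
                                              sd = if (length(v) > 1) stats::sd(v) else 0,
                                              n = length(v)))
  out <- data.frame(region = agg$region, timepoint = agg$timepoint,
                    condition = agg$condition,
                    mean = agg$mbf[, "mean"], sd = agg$mbf[, "sd"],
                    n = as.integer(agg$mbf[, "n"]),
                    stringsAsFactors = FALSE)
  out[order(out$region, out$timepoint, out$condition), , drop = FALSE]
}

#' Cross-sectional comparison of a region across timepoints
#'
#' One-way ANOVA of resting regional MBF across the available timepoints,
#' followed by pairwise baseline-versus-timepoint comparisons using
#' pooled-variance t tests on the ANOVA residual mean square, with Holm-Sidak
#' adjustment of the pairwise p-values. The design is cross-sectional:
#' groups at different timepoints contain (partly) different subjects.
#'
#' @param table Cohort table with a `baseline` timepoint and at least one
#'   post-AMI timepoint; only `condition == "rest"` rows of the requested
#'   region enter.
#' @param region "infarct", "remote" or "other".
#' @param alpha Significance level (default 0.05).
#' @return List with `anova` (see [oneway_anova()]), `comparisons` (data
#'   frame: `timepoint`, `n`, `mean`, `diff` vs baseline, `t`, `df`, `p`,
#'   `p_adj`, `significant`), and `groups` (the raw value lists).
#' @export
cross_sectional_compare <- function(table, region, alpha = 0.05) {
  t2 <- table[table$region == region & table$condition == "rest" &
                table$included, ]
  tps <- unique(t2$timepoint)
  if (!"baseline" %in% tps)
    stop("table has no baseline timepoint for region ", region)
  tps <- c("baseline", setdiff(tps, "baseline"))
  groups <- lapply(tps, function(tp) t2$mbf[t2$timepoint == tp])
  names(groups) <- tps
  an <- oneway_anova(groups)
  base <- groups[["baseline"]]
  others <- setdiff(tps, "baseline")
  cmp <- data.frame(timepoint = others,
                    n = vapply(groups[others], length, 0L),
                    mean = vapply(groups[others], mean, 0),
                    stringsAsFactors = FALSE)
  cmp$diff <- cmp$mean - mean(base)
  se <- sqrt(an$mse * (1 / length(base) + 1 / cmp$n))
  cmp$t <- cmp$diff / se
  cmp$df <- an$df2
  cmp$p <- 2 * stats::pt(-abs(cmp$t), cmp$df)
  cmp$p_adj <- holm_sidak(cmp$p)
  cmp$significant <- cmp$p_adj < alpha
  list(anova = an, comparisons = cmp, groups = groups)
}
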