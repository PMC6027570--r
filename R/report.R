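#' Run the full synthetic study end-to-end
#'
#' Drives the whole pipeline on synthetic cohorts mirroring the study design:
#' simulate baseline, paired rest/stress and post-AMI cohorts; segment and
#' quantify every slice; apply the per-arm exclusion policy (tSNR exclusion
#' for the baseline/stress arm, no exclusion for the cross-sectional post-AMI
#' arm, where the infarcted segment is expected to fail tSNR); run the group
#' statistics; and write results tables, a markdown summary and figure
#' outputs. Fully reproducible from the seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param config Optional named list overriding scenario parameters: any
#'   formal of [scenario_config()] plus `n_baseline`, `n_paired`, `n_ami`
#'   (length-3), `render` (logical).
#' @return Invisibly, a list with the cohort tables and statistics; artifacts
#'   are written under `out_dir`.
#' @export
run_study <- function(out_dir, seed = 1L, config = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  render <- !isFALSE(config$render)
  extra <- config[setdiff(names(config),
                          c("n_baseline", "n_paired", "n_ami", "render"))]
  cfg_of <- function(scenario, n, seed) {
    do.call(scenario_config,
            c(list(scenario = scenario, n_slices = n, seed = seed), extra))
  }
  n_ami <- if (is.null(config$n_ami)) c(9L, 8L, 4L) else config$n_ami

  stage <- "simulate"
  res <- tryCatch({
    cfg_base <- cfg_of("baseline", config$n_baseline, seed)
    cfg_pair <- cfg_of("rest_stress", config$n_paired, seed + 1L)
    cfg_ami <- Map(cfg_of, c("ami_day1", "ami_week1", "ami_week4"),
                   as.list(n_ami), as.list(seed + 2:4))
    coh_base <- simulate_cohort(cfg_base)
    coh_pair <- simulate_cohort(cfg_pair)
    coh_ami <- lapply(cfg_ami, simulate_cohort)

    stage <- "quantify"
    tab_base <- quantify_cohort(coh_base, exclusion_enabled = TRUE)
    tab_pair <- quantify_cohort(coh_pair, exclusion_enabled = TRUE)
    tab_cross <- rbind(quantify_cohort(coh_base, exclusion_enabled = FALSE),
                       do.call(rbind, lapply(coh_ami, quantify_cohort,
                                             exclusion_enabled = FALSE)))
    write_results(tab_base, file.path(out_dir, "results_baseline.csv"))
    write_results(tab_pair, file.path(out_dir, "results_rest_stress.csv"))
    write_results(tab_cross, file.path(out_dir, "results_cross_sectional.csv"))

    stage <- "stats"
    pair <- filter_paired(tab_pair)
    tt <- paired_ttest(pair$y, pair$x)  # stress vs rest
    reserve <- mpr(pair$x, pair$y)
    cs_inf <- cross_sectional_compare(tab_cross, "infarct")
    cs_rem <- cross_sectional_compare(tab_cross, "remote")
    summ <- regional_summary(tab_cross)

    stage <- "report"
    .write_study_report(out_dir, seed, cfg_base, cfg_pair,
                        tab_base, tab_pair, pair, tt, reserve,
                        cs_inf, cs_rem, summ)
    if (render) {
      maps <- .study_maps(coh_pair)
      render_outputs(list(pair = pair, summary = summ, tab_pair = tab_pair),
                     maps, out_dir)
    }
    list(tables = list(baseline = tab_base, rest_stress = tab_pair,
                       cross_sectional = tab_cross),
         paired_ttest = tt, mpr = reserve,
         cross_sectional = list(infarct = cs_inf, remote = cs_rem),
         regional_summary = summ)
  }, error = function(e) {
    writeLines(paste0("FAILED at stage: ", stage, "\n", conditionMessage(e)),
               file.path(out_dir, "FAILED.txt"))
    stop("study run failed at stage `", stage, "`: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

# FNV-1a hash of a deparsed object, for the run log
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    low <- h %% 256  # xor touches the low byte only (b < 256)
    h <- h - low + bitwXor(as.integer(low), b)
    # multiply mod 2^32 in two 16-bit halves to stay within double precision
    hi <- h %/% 65536; lo <- h %% 65536
    h <- (((hi * m) %% 65536) * 65536 + lo * m) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.study_maps <- function(coh_pair) {
  rest <- coh_pair[[1]]
  stress <- coh_pair[[2]]
  mk <- function(rec) mbf_map(rec$series,
                              myocardial_mask(rec$labels$labels > 0,
                                              rec$labels$lv_center,
                                              rec$labels$rv_insertion_angle))
  list(rest = mk(rest), stress = mk(stress))
}

.write_study_report <- function(out_dir, seed, cfg_base, cfg_pair,
                                tab_base, tab_pair, pair, tt, reserve,
                                cs_inf, cs_rem, summ) {
  fmt <- function(x, d = 3) formatC(x, digits = d, format = "fg")
  lines <- c(
    "# Synthetic ASL-CMR study report", "",
    paste0("- seed: ", seed),
    paste0("- config hash: ", .config_hash(list(cfg_base, cfg_pair))),
    paste0("- R version: ", R.version.string), "",
    "## Baseline arm (tSNR exclusion enabled)",
    paste0("- slices: ", cfg_base$n_slices,
           "; segments excluded: ", sum(!tab_base$included), " / ",
           nrow(tab_base)),
    paste0("- regional MBF (included): ",
           fmt(mean(tab_base$mbf[tab_base$included])), " ± ",
           fmt(stats::sd(tab_base$mbf[tab_base$included])), " ml/g/min"),
    paste0("- physiological noise (included): ",
           fmt(mean(tab_base$pn[tab_base$included])), " ± ",
           fmt(stats::sd(tab_base$pn[tab_base$included])), " ml/g/min"), "",
    "## Rest/stress arm (both-condition exclusion)",
    paste0("- pairs kept: ", pair$kept, "; dropped: ", pair$dropped),
    paste0("- rest MBF: ", fmt(mean(pair$x)), " ± ", fmt(stats::sd(pair$x)),
           "; stress MBF: ", fmt(mean(pair$y)), " ± ",
           fmt(stats::sd(pair$y)), " ml/g/min"),
    paste0("- paired t-test (stress vs rest): t = ", fmt(tt$t),
           ", df = ", tt$df, ", p = ", format.pval(tt$p)),
    paste0("- MPR: ", fmt(reserve$mean), " ± ", fmt(reserve$sd),
           " (", fmt(reserve$percent_increase, 3), "% increase; ",
           reserve$n_undefined, " undefined)"), "",
    "## Cross-sectional arm (no exclusion)",
    "### Infarct region vs baseline",
    utils::capture.output(print(cs_inf$comparisons, row.names = FALSE)),
    "### Remote region vs baseline",
    utils::capture.output(print(cs_rem$comparisons, row.names = FALSE)), "",
    "## Regional summary",
    utils::capture.output(print(summ, row.names = FALSE)))
  writeLines(lines, file.path(out_dir, "report.md"))
}

#' Render figure-style outputs
#'
#' Writes the study figures: rest and stress MBF maps on one shared color
#' scale, a rest-versus-stress box plot of the kept paired segments, and a
#' regional bar chart with SD error bars. Plot data come straight from the
#' results tables handed in (single source of truth).
#'
#' @param results List with `pair` (from [filter_paired()]) and `summary`
#'   (from [regional_summary()]).
#' @param maps List with `rest` and `stress` MBF map matrices (see
#'   [mbf_map()]).
#' @param out_dir Output directory.
#' @return Character vector of the files written, invisibly.
#' @export
render_outputs <- function(results, maps, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  save_plot <- function(p, name, width = 6, height = 4) {
    f <- file.path(out_dir, name)
    ggplot2::ggsave(f, p, width = width, height = height, dpi = 120,
                    device = grDevices::png, type = "cairo")
    files <<- c(files, f)
  }
  map_df <- do.call(rbind, lapply(names(maps), function(cond) {
    m <- maps[[cond]]
    data.frame(condition = cond,
               row = as.vector(row(m)), col = as.vector(col(m)),
               mbf = as.vector(m))
  }))
  map_df <- map_df[!is.na(map_df$mbf), ]
  lim <- range(map_df$mbf)
  p_map <- ggplot2::ggplot(map_df, ggplot2::aes(x = .data$col, y = -.data$row,
                                                fill = .data$mbf)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::scale_fill_viridis_c(limits = lim, name = "MBF\n(ml/g/min)") +
    ggplot2::coord_fixed() + ggplot2::theme_void()
  save_plot(p_map, "mbf_maps.png", width = 8, height = 4)

  pair <- results$pair
  box_df <- data.frame(
    condition = factor(rep(c("rest", "stress"), c(length(pair$x),
                                                  length(pair$y))),
                       levels = c("rest", "stress")),
    mbf = c(pair$x, pair$y))
  p_box <- ggplot2::ggplot(box_df, ggplot2::aes(.data$condition, .data$mbf)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(y = "Regional MBF (ml/g/min)", x = NULL) +
    ggplot2::theme_classic()
  save_plot(p_box, "rest_stress_boxplot.png")

  summ <- results$summary
  summ <- summ[summ$condition == "rest" & summ$region %in%
                 c("infarct", "remote"), ]
  p_bar <- ggplot2::ggplot(summ, ggplot2::aes(.data$timepoint, .data$mean,
                                              fill = .data$region)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           position = ggplot2::position_dodge(0.9),
                           width = 0.25) +
    ggplot2::labs(y = "Resting MBF (ml/g/min)", x = NULL) +
    ggplot2::theme_classic()
  save_plot(p_bar, "regional_mbf_bars.png")
  invisible(files)
}
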