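## Stratified summaries, trough-ratio tables, threshold percentages and
## percentile concentration-time ribbons.

#' Stratified exposure summaries
#'
#' Arithmetic mean and sample SD (n - 1 denominator) of each steady-state
#' exposure metric per stratum, the stratum-mean trough ratio versus a
#' reference stratum (reported to 2 decimals; the reference's ratio is
#' exactly 1), and the percentage of subjects maintaining the trough
#' threshold.
#'
#' @param results An `igsim_scenario` from [run_scenario()], or a metrics
#'   data.frame with a `stratum` column.
#' @param reference_label Reference stratum for the trough ratio (default
#'   `"healthy"` for BMI stratification, `">=18 y"` for age).
#' @param threshold Trough threshold in g/L (default 7).
#' @return A data.frame with one row per stratum: `regimen`, `stratum`, `n`,
#'   mean and SD for `auc_ss`, `cmax_ss`, `cmin_ss`, `cave_ss`,
#'   `cmin_ratio`, `pct_cmin_ge_threshold`.
#' @export
summarize_groups <- function(results, reference_label = NULL, threshold = 7) {
  if (inherits(results, "igsim_scenario")) {
    metrics <- results$metrics
    regimen_label <- results$regimen$formulation
    stratify_by <- results$stratify_by
  } else {
    metrics <- results
    regimen_label <- attr(results, "regimen") %||% NA_character_
    stratify_by <- attr(results, "stratify_by") %||% "bmi"
  }
  if (is.null(metrics$stratum)) stopf("metrics must carry a `stratum` column")
  reference_label <- reference_label %||%
    if (identical(stratify_by, "age")) ">=18 y" else "healthy"
  levels <- if (identical(stratify_by, "age")) age_groups()$label else bmi_groups()$label
  levels <- intersect(levels, unique(metrics$stratum))
  if (length(levels) == 0) levels <- unique(metrics$stratum)
  if (!reference_label %in% metrics$stratum) {
    stopf("reference stratum \"%s\" not present in the results", reference_label)
  }
  rows <- lapply(levels, function(lab) {
    m <- metrics[metrics$stratum == lab, ]
    data.frame(
      regimen = regimen_label, stratum = lab, n = nrow(m),
      auc_ss_mean = mean(m$auc_ss), auc_ss_sd = stats::sd(m$auc_ss),
      cmax_mean = mean(m$cmax_ss), cmax_sd = stats::sd(m$cmax_ss),
      cmin_mean = mean(m$cmin_ss), cmin_sd = stats::sd(m$cmin_ss),
      cave_mean = mean(m$cave_ss), cave_sd = stats::sd(m$cave_ss),
      pct_cmin_ge_threshold = threshold_fraction(m, threshold),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  ref_mean <- out$cmin_mean[out$stratum == reference_label]
  out$cmin_ratio <- round(out$cmin_mean / ref_mean, 2)
  out$cmin_ratio[out$stratum == reference_label] <- 1.00
  out[, c("regimen", "stratum", "n", "auc_ss_mean", "auc_ss_sd",
          "cmax_mean", "cmax_sd", "cmin_mean", "cmin_sd",
          "cave_mean", "cave_sd", "cmin_ratio", "pct_cmin_ge_threshold")]
}

#' Pointwise percentile concentration-time ribbon
#'
#' Empirical pointwise percentiles (linear-interpolation definition,
#' `stats::quantile` type 7) of the total concentration across subjects at
#' every grid time; by default the median with the 5th and 95th percentiles
#' (the 90% prediction band used for plotting).
#'
#' @param profiles A list of `igsim_profile` objects sharing one time grid,
#'   or an `igsim_scenario`.
#' @param percentiles Percentiles in (0, 100) (default `c(5, 50, 95)`).
#' @return A data.frame with column `time` and one `p<q>` column per
#'   percentile.
#' @export
percentile_ribbon <- function(profiles, percentiles = c(5, 50, 95)) {
  if (inherits(profiles, "igsim_scenario")) {
    times <- profiles$times
    conc <- profiles$conc_total
  } else {
    if (length(profiles) == 0) stopf("`profiles` must be non-empty")
    times <- profiles[[1]]$times
    same <- vapply(profiles, function(p) {
      length(p$times) == length(times) && all(p$times == times)
    }, logical(1))
    if (!all(same)) stopf("all profiles must share one time grid")
    conc <- do.call(rbind, lapply(profiles, function(p) p$conc_total))
  }
  qs <- apply(conc, 2, stats::quantile, probs = percentiles / 100,
              names = FALSE, type = 7)
  qs <- matrix(qs, nrow = length(percentiles))
  out <- data.frame(time = times)
  for (i in seq_along(percentiles)) {
    out[[paste0("p", percentiles[i])]] <- qs[i, ]
  }
  out
}

#' Ribbon and trough-bar figures
#'
#' `plot_ribbons()` draws the median line with the 5th-95th percentile band
#' per stratum; `plot_cmin_bars()` draws stratum-mean troughs with SD error
#' bars and a dashed line at the protective threshold (one bar per stratum
#' and regimen).
#'
#' @param ribbons A data.frame of stacked [percentile_ribbon()] outputs with
#'   `stratum` (and optionally `regimen`) columns.
#' @param summaries A [summarize_groups()] data.frame.
#' @param threshold Threshold line in g/L.
#' @return A ggplot object.
#' @export
plot_ribbons <- function(ribbons) {
  gg <- ggplot2::ggplot(ribbons, ggplot2::aes(x = .data$time, y = .data$p50)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p5, ymax = .data$p95,
                                      fill = .data$stratum), alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$stratum)) +
    ggplot2::labs(x = "Time after switch (days)",
                  y = "Serum total IgG (g/L)",
                  colour = "Stratum", fill = "Stratum") +
    ggplot2::theme_minimal()
  if ("regimen" %in% names(ribbons)) {
    gg <- gg + ggplot2::facet_wrap(~regimen, ncol = 1)
  }
  gg
}

#' @rdname plot_ribbons
#' @export
plot_cmin_bars <- function(summaries, threshold = 7) {
  summaries$stratum <- factor(summaries$stratum, levels = unique(summaries$stratum))
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$stratum, y = .data$cmin_mean,
                               fill = .data$regimen)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$cmin_mean - .data$cmin_sd,
                   ymax = .data$cmin_mean + .data$cmin_sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Mean C_min,ss (g/L)", fill = "Regimen") +
    ggplot2::theme_minimal()
}

#' Write a report directory
#'
#' Writes `summary.csv` (one row per stratum and regimen; ratios to 2
#' decimals, concentrations to 1 decimal for display), `ribbons.csv` (if
#' ribbons are supplied) and the two figures (`ribbons.png`,
#' `cmin_bars.png`). Full-precision per-subject values belong in
#' `metrics.csv` ([write_metrics()]).
#'
#' @param summaries A [summarize_groups()] data.frame (possibly for several
#'   regimens, row-bound).
#' @param ribbons Stacked [percentile_ribbon()] output with a `stratum`
#'   column, or `NULL` to skip.
#' @param out_dir Output directory (created if needed).
#' @param threshold Threshold line for the bar chart.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(summaries, ribbons, out_dir, threshold = 7) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  disp <- summaries
  for (nm in c("auc_ss_mean", "auc_ss_sd", "cmax_mean", "cmax_sd",
               "cmin_mean", "cmin_sd", "cave_mean", "cave_sd",
               "pct_cmin_ge_threshold")) {
    disp[[nm]] <- round(disp[[nm]], 1)
  }
  disp$cmin_ratio <- round(disp$cmin_ratio, 2)
  paths <- file.path(out_dir, "summary.csv")
  utils::write.csv(disp, paths, row.names = FALSE)
  if (!is.null(ribbons) && NROW(ribbons) > 0) {
    rp <- file.path(out_dir, "ribbons.csv")
    utils::write.csv(ribbons, rp, row.names = FALSE)
    paths <- c(paths, rp)
    if ("stratum" %in% names(ribbons)) {
      fp <- file.path(out_dir, "ribbons.png")
      ggplot2::ggsave(fp, plot_ribbons(ribbons), width = 8, height = 6, dpi = 120)
      paths <- c(paths, fp)
    }
  }
  bp <- file.path(out_dir, "cmin_bars.png")
  ggplot2::ggsave(bp, plot_cmin_bars(summaries, threshold),
                  width = 8, height = 5, dpi = 120)
  invisible(c(paths, bp))
}

#' Write per-subject metrics and profiles
#'
#' `metrics.csv` columns: `subject_id, stratum, auc_ss_gday_L, cmax_ss_gL,
#' cmin_ss_gL, cave_ss_gL` (full precision). `profiles.csv` columns:
#' `subject_id, time_days, conc_total_gL, conc_endog_gL`; `every` thins the
#' time grid to keep the file manageable.
#'
#' @param result An `igsim_scenario`.
#' @param path Output file path.
#' @param every Keep every `every`-th grid point (profiles only).
#' @return Invisibly, `path`.
#' @export
write_metrics <- function(result, path) {
  m <- result$metrics
  out <- data.frame(subject_id = m$subject_id, stratum = m$stratum,
                    auc_ss_gday_L = m$auc_ss, cmax_ss_gL = m$cmax_ss,
                    cmin_ss_gL = m$cmin_ss, cave_ss_gL = m$cave_ss)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
write_profiles <- function(result, path, every = 4) {
  idx <- seq(1, length(result$times), by = every)
  n <- nrow(result$subjects)
  out <- data.frame(
    subject_id = rep(result$subjects$subject_id, each = length(idx)),
    time_days = rep(result$times[idx], n),
    conc_total_gL = as.vector(t(result$conc_total[, idx, drop = FALSE])),
    conc_endog_gL = rep(result$conc_endogenous, each = length(idx))
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
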