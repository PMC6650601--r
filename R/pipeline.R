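#' Run the complete ratio-test analysis pipeline
#'
#' Wires the three evaluation stages together: dataset validation and
#' control-mortality summary, per-ratio dose-response fitting (with
#' common-concentration filtering and balanced subsampling), and threshold
#' derivation (LCx decay against %MP, NOEC, NOE%MP) plus the outcome
#' scenario. Per-series fit failures are reported but not fatal unless the
#' 0% reference series itself cannot be fitted.
#'
#' @param input A CSV path (see [read_dataset()]) or a
#'   [bioassay_dataset()].
#' @param x_level Effect percentage anchoring the threshold (default 10).
#' @param common_only,scheme,hill_fixed,hill,conf_level Passed to
#'   [fit_all()].
#' @param control_threshold Validity threshold for [control_mortality()].
#' @return An object of class `analysis_report`: a list with `dataset`
#'   (summary counts), `control` (the [control_mortality()] result),
#'   `fits` (the [fit_all()] result), `decay_lc10`/`decay_lc50` (LC10- and
#'   LC50-level [fit_decay()] results, when derivable), `threshold` (the
#'   [derive_thresholds()] result at `x_level`, or NULL with a warning),
#'   `scenario` (`"A"`, `"B"` or `"C"`, or NA), and `config` (every option
#'   resolved, including the subsampling seed, sufficient to reproduce the
#'   report bit for bit).
#' @export
run_pipeline <- function(input, x_level = 10, common_only = TRUE,
                         scheme = subsample_scheme(), hill_fixed = TRUE,
                         hill = 1, conf_level = 0.95,
                         control_threshold = 0.10) {
  ds <- if (inherits(input, "bioassay_dataset")) input else read_dataset(input)
  ctl <- control_mortality(ds, threshold = control_threshold)
  fits <- fit_all(ds, common_only = common_only, scheme = scheme,
                  hill_fixed = hill_fixed, hill = hill,
                  conf_level = conf_level)
  if (!"0" %in% names(fits$fits)) {
    abort(paste("The 0% MP reference series failed to fit;",
                "thresholds cannot be anchored.",
                if (length(fits$errors) > 0) {
                  paste0("Series errors: ",
                         paste(names(fits$errors), collapse = ", "))
                }),
          class = "mpratio_anchor_error")
  }

  n_levels <- length(fits$fits)
  threshold <- NULL
  decay10 <- NULL
  decay50 <- NULL
  scenario <- NA_character_
  if (n_levels >= 3) {
    threshold <- derive_thresholds(fits, x_level = x_level)
    decay10 <- if (x_level == 10) threshold$decay else
      derive_thresholds(fits, x_level = 10)$decay
    decay50 <- if (x_level == 50) threshold$decay else
      derive_thresholds(fits, x_level = 50)$decay
  } else {
    warn(sprintf(
      "Only %d mixture ratio(s) fitted; thresholds need 3 or more levels.",
      n_levels))
  }
  if (n_levels >= 2) scenario <- classify_scenario(fits)

  counts <- cell_counts(ds)
  structure(
    list(
      dataset = list(
        n_records = nrow(ds$records),
        n_controls = sum(ds$records$is_control),
        n_cells = nrow(counts),
        cells = counts,
        duration_h = ds$duration_h,
        metadata = ds$metadata
      ),
      control = ctl,
      fits = fits,
      decay_lc10 = decay10,
      decay_lc50 = decay50,
      threshold = threshold,
      scenario = scenario,
      config = list(
        x_level = x_level, common_only = common_only,
        target_replicates = scheme$target_replicates,
        iterations = scheme$iterations, seed = scheme$seed,
        hill_fixed = hill_fixed, hill = hill, conf_level = conf_level,
        control_threshold = control_threshold,
        version = as.character(utils::packageVersion("mpratio"))
      )
    ),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Ratio-test analysis report ==\n")
  cat(sprintf("Dataset : %d records (%d controls) over %d treatment cells\n",
              x$dataset$n_records, x$dataset$n_controls, x$dataset$n_cells))
  cat(sprintf("Controls: %.1f%% mortality%s\n", 100 * x$control$pooled,
              if (length(x$control$flagged_runs) > 0) {
                sprintf(" (flagged runs: %s)",
                        paste(x$control$flagged_runs, collapse = ", "))
              } else ""))
  cat("Fits    :\n")
  print(x$fits$table)
  if (!is.null(x$threshold)) {
    print(x$threshold)
  }
  if (!is.na(x$scenario)) {
    cat(sprintf("Scenario: %s (%s)\n", x$scenario, switch(
      x$scenario,
      A = "no test-particle effect beyond suspended solids",
      B = "additive test-particle effect",
      C = "ameliorating test-particle effect")))
  }
  invisible(x)
}

# Flatten a report into plain lists for JSON serialisation.
report_to_list <- function(report) {
  thr <- report$threshold
  decay_block <- function(d) {
    if (is.null(d)) return(NULL)
    list(y0 = d$y0, plateau = d$plateau, k = d$k, r_squared = d$r_squared,
         degenerate = d$degenerate, x_level = d$x_level)
  }
  list(
    dataset = list(
      n_records = report$dataset$n_records,
      n_controls = report$dataset$n_controls,
      n_cells = report$dataset$n_cells,
      duration_h = report$dataset$duration_h
    ),
    control_mortality = list(
      pooled = report$control$pooled,
      flagged_runs = as.list(report$control$flagged_runs),
      threshold = report$control$threshold
    ),
    fits = report$fits$table,
    comparison = report$fits$comparison,
    fit_errors = report$fits$errors,
    decay_lc10 = decay_block(report$decay_lc10),
    decay_lc50 = decay_block(report$decay_lc50),
    threshold = if (is.null(thr)) NULL else list(
      noec_mg_per_l = thr$noec,
      noe_pct_mp = if (is.infinite(thr$noe_pct_mp)) {
        "no %MP threshold within model range"
      } else thr$noe_pct_mp,
      x_level = thr$x_level
    ),
    scenario = report$scenario,
    config = report$config
  )
}

#' Write an analysis report to JSON
#'
#' @param report An `analysis_report` from [run_pipeline()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Plot the LCx decay curve with the threshold intersection
#'
#' Renders the threshold construction: per-ratio LCx estimates, the fitted
#' one-phase exponential decay, the NOEC as a horizontal reference, and the
#' NOE%MP as the intersection point.
#'
#' @param threshold A [derive_thresholds()] result.
#' @return A ggplot object.
#' @export
plot_threshold <- function(threshold) {
  stopifnot(inherits(threshold, "threshold_result"))
  pts <- threshold$points
  curve <- tibble::tibble(pct_mp = seq(0, max(pts$pct_mp), length.out = 200))
  curve$lcx <- predict(threshold$decay, curve$pct_mp)
  g <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$pct_mp, y = .data$lcx)) +
    ggplot2::geom_line(data = curve, colour = "grey30") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = threshold$noec, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Test particle contribution (%MP by mass)",
      y = sprintf("LC%g (mg/L)", threshold$x_level),
      title = sprintf("NOEC %.3g mg/L", threshold$noec)
    ) +
    ggplot2::theme_minimal()
  if (is.finite(threshold$noe_pct_mp) && threshold$noe_pct_mp > 0) {
    g <- g +
      ggplot2::geom_vline(xintercept = threshold$noe_pct_mp,
                          linetype = "dotted", colour = "firebrick") +
      ggplot2::annotate("point", x = threshold$noe_pct_mp,
                        y = threshold$noec, colour = "firebrick", size = 3) +
      ggplot2::labs(subtitle = sprintf("NOE%%MP %.3g%%",
                                       threshold$noe_pct_mp))
  }
  g
}

#' Plot a fitted dose-response curve with its replicate observations
#'
#' @param fit A [fit_dose_response()] result.
#' @param points Optional tibble of the replicate observations (`ss_conc`
#'   plus counts or `p_obs`) to overlay.
#' @param p_control Control mortality used to Abbott-correct the overlaid
#'   points.
#' @return A ggplot object.
#' @export
plot_dose_response <- function(fit, points = NULL, p_control = 0) {
  stopifnot(inherits(fit, "dose_response_fit"))
  rng <- range(fit$ss_used)
  curve <- tibble::tibble(
    ss_conc = 10^seq(log10(rng[1]) - 0.5, log10(rng[2]) + 0.5,
                     length.out = 200)
  )
  curve$p <- predict(fit, curve$ss_conc)
  g <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$ss_conc, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = fit$lc50[["estimate"]],
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Suspended solids (mg/L)",
                  y = "Corrected mortality proportion",
                  title = if (is.na(fit$pct_mp)) NULL else
                    sprintf("%g%% MP", fit$pct_mp)) +
    ggplot2::theme_minimal()
  if (!is.null(points)) {
    pts <- prepare_points(points)
    pts <- pts[pts$ss_conc > 0, ]
    pts$p <- abbott_correct(pts$p_obs, p_control)
    g <- g + ggplot2::geom_point(data = pts, alpha = 0.6)
  }
  g
}
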