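#' Concentrations shared by every mixture ratio
#'
#' Ratio designs give the endpoint mixtures (0% and 100% MP) a longer
#' concentration series than the intermediates. To compare LC estimates
#' across ratios on equal footing, only SS concentrations common to all
#' treatment combinations are fitted. This returns that intersection along
#' with what each %MP level loses to the filter.
#'
#' @param ds A [bioassay_dataset()].
#' @return A list with `common` (sorted numeric vector of shared positive
#'   concentrations) and `dropped` (tibble: `pct_mp`, `ss_conc` for every
#'   excluded cell).
#' @export
common_concentrations <- function(ds) {
  stopifnot(inherits(ds, "bioassay_dataset"))
  pos <- ds$records[ds$records$ss_conc > 0, ]
  levels <- sort(unique(pos$pct_mp))
  if (length(levels) < 2) {
    abort("Need at least two pct_mp levels to intersect concentration grids.")
  }
  sets <- lapply(levels, function(p) unique(pos$ss_conc[pos$pct_mp == p]))
  common <- sort(Reduce(intersect, sets))
  if (length(common) == 0) {
    abort(paste("No SS concentration is shared by all pct_mp levels;",
                "analyse the levels separately."),
          class = "mpratio_empty_intersection")
  }
  dropped <- purrr::map2_dfr(levels, sets, function(p, s) {
    lost <- sort(setdiff(s, common))
    if (length(lost) == 0) return(tibble::tibble())
    tibble::tibble(pct_mp = p, ss_conc = lost)
  })
  list(common = common, dropped = dropped)
}

#' Subsampling scheme for over-replicated treatments
#'
#' @param target_replicates Replicates drawn per (pct_mp, ss_conc) cell
#'   (default 5, matching the replication of the least-replicated mixture
#'   treatments).
#' @param iterations Number of repeated subsamples to aggregate over.
#' @param seed Master seed; iteration i and each cell use derived streams,
#'   so results do not depend on execution order.
#' @return A list of class `subsample_scheme`.
#' @export
subsample_scheme <- function(target_replicates = 5, iterations = 100,
                             seed = 1L) {
  stopifnot_scalar_number(target_replicates, "target_replicates", lower = 2)
  stopifnot_scalar_number(iterations, "iterations", lower = 1)
  structure(
    list(target_replicates = as.integer(target_replicates),
         iterations = as.integer(iterations), seed = as.integer(seed)),
    class = "subsample_scheme"
  )
}

#' Balanced replicated subsampling fit
#'
#' An unevenly replicated treatment (e.g. 5–43 tubes per concentration in
#' the reference series) would dominate a pooled comparison; balanced
#' replicated subsampling without replacement draws `target_replicates`
#' tubes per concentration cell, fits the dose-response on the draw, and
#' repeats. The aggregate reports the median LC50/LC10 and the medians of
#' the per-iteration confidence bounds, together with the between-iteration
#' spread. When every cell holds exactly `target_replicates` tubes there is
#' a single possible subsample and the result equals the direct fit.
#'
#' @param series Treatment replicates of one mixture ratio: a data frame
#'   with `ss_conc`, counts or `p_obs`, and optionally `run_id`.
#' @param scheme A [subsample_scheme()].
#' @param p_control Pooled control mortality for Abbott's correction.
#' @param ... Passed on to [fit_dose_response()] (e.g. `hill_fixed`,
#'   `pct_mp`).
#' @return A `dose_response_fit` whose estimates are subsample aggregates,
#'   with extra elements `iterations` (per-iteration tibble), `spread`
#'   (IQR and sd of the iteration LC50s) and `subsampled = TRUE`.
#' @export
subsample_fit <- function(series, scheme = subsample_scheme(),
                          p_control = 0, ...) {
  stopifnot(inherits(scheme, "subsample_scheme"))
  pts <- prepare_points(series)
  pts <- pts[pts$ss_conc > 0, ]
  # Canonical within-cell order makes draws invariant to input row order.
  ord <- order(pts$ss_conc, pts$p_obs,
               if ("run_id" %in% names(pts)) pts$run_id else seq_len(nrow(pts)))
  pts <- pts[ord, ]
  cells <- split(seq_len(nrow(pts)), pts$ss_conc)
  short <- names(cells)[vapply(cells, length, integer(1)) <
                          scheme$target_replicates]
  if (length(short) > 0) {
    abort(sprintf(
      "Cells with fewer than %d replicates cannot be subsampled: ss_conc = %s.",
      scheme$target_replicates, paste(short, collapse = ", ")),
      class = "mpratio_subsample_error")
  }

  single <- all(vapply(cells, length, integer(1)) == scheme$target_replicates)
  iters <- if (single) 1L else scheme$iterations
  per_iter <- purrr::map_dfr(seq_len(iters), function(i) {
    idx <- unlist(purrr::imap(cells, function(rows, key) {
      if (length(rows) == scheme$target_replicates) return(rows)
      s <- cell_seed(scheme$seed, 0, as.numeric(key), tag = i)
      rows[with_stream(s, sample.int(length(rows), scheme$target_replicates))]
    }), use.names = FALSE)
    f <- fit_dose_response(pts[idx, ], p_control = p_control, ...)
    tibble::tibble(
      iteration = i, lc50 = f$lc50[["estimate"]],
      lc50_lower = f$lc50[["lower"]], lc50_upper = f$lc50[["upper"]],
      lc10 = f$lc10[["estimate"]], lc10_lower = f$lc10[["lower"]],
      lc10_upper = f$lc10[["upper"]], hill = f$model$hill,
      r_squared = f$r_squared
    )
  })

  agg <- function(v) median(v)
  base_fit <- fit_dose_response(pts, p_control = p_control, ...)
  fit <- base_fit
  fit$model$log10_lc50 <- log10(agg(per_iter$lc50))
  fit$model$hill <- agg(per_iter$hill)
  fit$lc50 <- c(estimate = agg(per_iter$lc50),
                lower = agg(per_iter$lc50_lower),
                upper = agg(per_iter$lc50_upper))
  fit$lc10 <- c(estimate = agg(per_iter$lc10),
                lower = agg(per_iter$lc10_lower),
                upper = agg(per_iter$lc10_upper))
  fit$r_squared <- agg(per_iter$r_squared)
  fit$n_obs <- scheme$target_replicates * length(cells)
  fit$subsampled <- !single
  fit$iterations <- per_iter
  fit$spread <- list(lc50_iqr = unname(diff(quantile(per_iter$lc50, c(0.25, 0.75)))),
                     lc50_sd = if (iters > 1) sd(per_iter$lc50) else 0)
  fit$scheme <- scheme
  fit
}

#' Fit dose-response curves for every mixture ratio
#'
#' Orchestrates the per-%MP analysis of a ratio experiment: pools the
#' control mortality, applies the common-concentration filter, routes
#' over-replicated ratios through [subsample_fit()] and the rest through
#' [fit_dose_response()], and tabulates confidence-interval overlap of each
#' ratio against the 0% reference. A series that fails to fit is reported
#' and skipped; the remaining series still run.
#'
#' @param ds A [bioassay_dataset()].
#' @param common_only Restrict every series to the dataset-wide common
#'   concentrations (default TRUE).
#' @param scheme A [subsample_scheme()] controlling balancing of
#'   over-replicated cells.
#' @param hill_fixed,hill,conf_level Passed to [fit_dose_response()].
#' @return An object of class `mixture_fits`: a list with `fits` (named
#'   list of `dose_response_fit`, ordered by %MP), `table` (one row per
#'   ratio: estimates, CIs, R², `subsampled`), `comparison` (CI overlap of
#'   each ratio vs the reference 0% level), `errors` (named list of failed
#'   series), `p_control`, and `common` (the concentration filter used).
#' @export
fit_all <- function(ds, common_only = TRUE, scheme = subsample_scheme(),
                    hill_fixed = TRUE, hill = 1, conf_level = 0.95) {
  stopifnot(inherits(ds, "bioassay_dataset"))
  p_control <- control_mortality(ds)$pooled
  pos <- ds$records[ds$records$ss_conc > 0, ]
  levels <- sort(unique(pos$pct_mp))

  common <- NULL
  if (common_only && length(levels) >= 2) {
    common <- common_concentrations(ds)$common
    pos <- pos[pos$ss_conc %in% common, ]
  }

  fits <- list()
  errors <- list()
  for (p in levels) {
    series <- pos[pos$pct_mp == p, ]
    n_per_cell <- table(series$ss_conc)
    res <- tryCatch({
      if (any(n_per_cell > scheme$target_replicates) &&
          all(n_per_cell >= scheme$target_replicates)) {
        subsample_fit(series, scheme = scheme, p_control = p_control,
                      hill_fixed = hill_fixed, hill = hill,
                      conf_level = conf_level, pct_mp = p)
      } else {
        fit_dose_response(series, p_control = p_control,
                          hill_fixed = hill_fixed, hill = hill,
                          conf_level = conf_level, pct_mp = p)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[as.character(p)]] <- conditionMessage(res)
    } else {
      fits[[as.character(p)]] <- res
    }
  }
  if (length(fits) == 0) {
    abort("No mixture series could be fitted.", class = "mpratio_fit_error")
  }

  table <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(
      pct_mp = f$pct_mp,
      lc50 = f$lc50[["estimate"]], lc50_lower = f$lc50[["lower"]],
      lc50_upper = f$lc50[["upper"]],
      lc10 = f$lc10[["estimate"]], lc10_lower = f$lc10[["lower"]],
      lc10_upper = f$lc10[["upper"]],
      hill = f$model$hill, r_squared = f$r_squared, n_obs = f$n_obs,
      subsampled = isTRUE(f$subsampled)
    )
  }) |>
    dplyr::arrange(.data$pct_mp)

  comparison <- tibble::tibble()
  ref <- fits[["0"]]
  if (!is.null(ref) && length(fits) > 1) {
    others <- setdiff(names(fits), "0")
    comparison <- purrr::map_dfr(others, function(nm) {
      cmp <- compare_fits(fits[[nm]], ref)
      tibble::tibble(pct_mp = fits[[nm]]$pct_mp, overlap = cmp$overlap,
                     significant = cmp$significant, gap = cmp$gap)
    }) |>
      dplyr::arrange(.data$pct_mp)
  }

  structure(
    list(fits = fits[order(as.numeric(names(fits)))], table = table,
         comparison = comparison, errors = errors, p_control = p_control,
         common = common,
         options = list(common_only = common_only, scheme = scheme,
                        hill_fixed = hill_fixed, hill = hill,
                        conf_level = conf_level)),
    class = "mixture_fits"
  )
}

#' @export
print.mixture_fits <- function(x, ...) {
  cat(sprintf("<mixture_fits> %d ratio series | control mortality %.1f%%\n",
              length(x$fits), 100 * x$p_control))
  if (!is.null(x$common)) {
    cat(sprintf("  common concentrations: %s mg/L\n",
                paste(x$common, collapse = ", ")))
  }
  print(x$table)
  if (length(x$errors) > 0) {
    cat("  failed series:\n")
    for (nm in names(x$errors)) cat(sprintf("    %s%%: %s\n", nm, x$errors[[nm]]))
  }
  invisible(x)
}
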