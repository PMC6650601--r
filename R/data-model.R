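#' Construct a validated bioassay dataset
#'
#' A bioassay dataset holds replicate-level exposure records: one row per
#' test tube, with the nominal suspended-solids concentration (`ss_conc`,
#' mg/L), the mass percentage of the test particle (`pct_mp`, 0–100), the
#' number of animals exposed and immobilized, a run/batch label, and a
#' control flag. Controls are particle-free tubes, identified by
#' `ss_conc == 0`.
#'
#' Record invariants enforced here:
#' * `0 <= n_immobilized <= n_exposed`, `n_exposed >= 1`
#' * `is_control` exactly when `ss_conc == 0`
#' * `0 <= pct_mp <= 100`, `ss_conc >= 0`
#'
#' Dataset-level invariants: at least one control record, and at least two
#' distinct positive concentrations for at least one `pct_mp` level (the
#' minimum needed to fit any dose-response curve).
#'
#' @param records A data frame with columns `ss_conc`, `pct_mp`, `n_exposed`,
#'   `n_immobilized`, `run_id`, `is_control`. `is_control` may be omitted, in
#'   which case it is derived from `ss_conc == 0`.
#' @param duration_h Exposure duration in hours (default 96).
#' @param metadata Named list of free-form labels (test particle, reference
#'   particle, species, ...).
#' @return An object of class `bioassay_dataset`: a list with elements
#'   `records` (tibble), `duration_h`, `metadata`.
#' @examples
#' recs <- tibble::tibble(
#'   ss_conc = c(0, 10, 100, 1000),
#'   pct_mp = c(0, 0, 0, 0),
#'   n_exposed = 10, n_immobilized = c(0, 1, 5, 9),
#'   run_id = "run1"
#' )
#' ds <- bioassay_dataset(recs)
#' cell_counts(ds)
#' @seealso [read_dataset()], [control_mortality()], [generate_bioassay()]
#' @export
bioassay_dataset <- function(records, duration_h = 96, metadata = list()) {
  records <- tibble::as_tibble(records)
  needed <- c("ss_conc", "pct_mp", "n_exposed", "n_immobilized", "run_id")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(sprintf("Dataset is missing required columns: %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!"is_control" %in% names(records)) {
    records$is_control <- records$ss_conc == 0
  }
  records$is_control <- as.logical(records$is_control)
  records$run_id <- as.character(records$run_id)
  records <- records[, c(needed, "is_control")]

  bad <- validate_records(records)
  if (length(bad) > 0) {
    abort(paste0("Invalid replicate records:\n", paste(bad, collapse = "\n")),
          class = "mpratio_validation_error")
  }
  if (!any(records$is_control)) {
    abort("Dataset must contain at least one particle-free control record.",
          class = "mpratio_validation_error")
  }
  pos <- records[records$ss_conc > 0, ]
  n_conc <- tapply(pos$ss_conc, pos$pct_mp, function(x) length(unique(x)))
  if (length(n_conc) == 0 || max(n_conc) < 2) {
    abort(paste("Dataset must hold at least two distinct positive",
                "concentrations for at least one pct_mp level."),
          class = "mpratio_validation_error")
  }
  structure(
    list(records = records, duration_h = duration_h, metadata = metadata),
    class = "bioassay_dataset"
  )
}

# Per-row invariant check; returns a character vector of violation messages
# tagged with row numbers (empty when clean).
validate_records <- function(records) {
  msg <- character()
  note <- function(rows, what) {
    if (any(rows)) {
      sprintf("  row %d: %s", which(rows), what)
    } else {
      character()
    }
  }
  msg <- c(
    msg,
    note(is.na(records$ss_conc) | records$ss_conc < 0,
         "ss_conc must be >= 0"),
    note(is.na(records$pct_mp) | records$pct_mp < 0 | records$pct_mp > 100,
         "pct_mp must be within [0, 100]"),
    note(is.na(records$n_exposed) | records$n_exposed < 1,
         "n_exposed must be >= 1"),
    note(is.na(records$n_immobilized) | records$n_immobilized < 0 |
           records$n_immobilized > records$n_exposed,
         "n_immobilized must satisfy 0 <= n_immobilized <= n_exposed"),
    note(records$is_control & records$ss_conc != 0,
         "control records must have ss_conc = 0"),
    note(!records$is_control & records$ss_conc == 0,
         "ss_conc = 0 records must be flagged is_control")
  )
  msg
}

#' @export
print.bioassay_dataset <- function(x, ...) {
  r <- x$records
  cat(sprintf("<bioassay_dataset> %d records, %d-h exposure\n",
              nrow(r), x$duration_h))
  cat(sprintf("  controls: %d tubes | treatments: %d tubes over %d cells\n",
              sum(r$is_control), sum(!r$is_control),
              nrow(unique(r[!r$is_control, c("pct_mp", "ss_conc")]))))
  cat(sprintf("  pct_mp levels: %s\n",
              paste(sort(unique(r$pct_mp[!r$is_control])), collapse = ", ")))
  invisible(x)
}

#' Replicate counts per treatment cell
#'
#' @param ds A [bioassay_dataset()].
#' @return A tibble with `pct_mp`, `ss_conc`, `n_replicates` for every
#'   treatment (non-control) cell, ordered by `pct_mp` then `ss_conc`.
#' @export
cell_counts <- function(ds) {
  stopifnot(inherits(ds, "bioassay_dataset"))
  ds$records |>
    dplyr::filter(!.data$is_control) |>
    dplyr::count(.data$pct_mp, .data$ss_conc, name = "n_replicates") |>
    dplyr::arrange(.data$pct_mp, .data$ss_conc)
}

# Canonical CSV header used on disk.
csv_columns <- c(
  ss_conc = "ss_conc_mg_per_l", pct_mp = "pct_mp", n_exposed = "n_exposed",
  n_immobilized = "n_immobilized", run_id = "run_id",
  is_control = "is_control"
)

#' Read a bioassay dataset from CSV
#'
#' One row is one tube (replicate). The header must name the six record
#' fields (`ss_conc_mg_per_L`, `pct_mp`, `n_exposed`, `n_immobilized`,
#' `run_id`, `is_control`), case-insensitively and in any order. Rows that
#' violate the record invariants are reported with their row numbers and the
#' read fails.
#'
#' @param path Path to a CSV file.
#' @param duration_h,metadata Passed to [bioassay_dataset()].
#' @return A validated [bioassay_dataset()].
#' @export
read_dataset <- function(path, duration_h = 96, metadata = list()) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(raw) <- tolower(names(raw))
  missing_cols <- setdiff(unname(csv_columns), names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("CSV is missing required columns: %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "mpratio_format_error")
  }
  records <- tibble::tibble(
    ss_conc = as.numeric(raw[[csv_columns[["ss_conc"]]]]),
    pct_mp = as.numeric(raw[[csv_columns[["pct_mp"]]]]),
    n_exposed = as.integer(raw[[csv_columns[["n_exposed"]]]]),
    n_immobilized = as.integer(raw[[csv_columns[["n_immobilized"]]]]),
    run_id = as.character(raw[[csv_columns[["run_id"]]]]),
    is_control = as.logical(raw[[csv_columns[["is_control"]]]])
  )
  bioassay_dataset(records, duration_h = duration_h, metadata = metadata)
}

#' Write a bioassay dataset to CSV
#'
#' Inverse of [read_dataset()]: `read_dataset(write_dataset(ds, path))`
#' round-trips losslessly for any valid dataset.
#'
#' @param ds A [bioassay_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "bioassay_dataset"))
  out <- ds$records
  names(out) <- unname(csv_columns[names(out)])
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Control mortality with per-run breakdown
#'
#' Pools immobilization counts over all particle-free control tubes and
#' reports the pooled mortality proportion, a per-run breakdown, and flags
#' for runs whose control mortality exceeds the validity threshold. Acute
#' immobilization test guidance treats control mortality above 10% as a
#' validity concern, so the default threshold is 0.10; exceeding it warns
#' but never aborts.
#'
#' @param ds A [bioassay_dataset()].
#' @param threshold Validity threshold on the control mortality proportion.
#' @return A list of class `control_mortality` with elements `pooled`
#'   (proportion), `per_run` (tibble: `run_id`, `n_exposed`,
#'   `n_immobilized`, `mortality`, `flagged`), `flagged_runs` (character),
#'   and `threshold`.
#' @export
control_mortality <- function(ds, threshold = 0.10) {
  stopifnot(inherits(ds, "bioassay_dataset"))
  ctl <- ds$records[ds$records$is_control, ]
  if (nrow(ctl) == 0) abort("Dataset has no control records.")
  per_run <- ctl |>
    dplyr::group_by(.data$run_id) |>
    dplyr::summarise(
      n_exposed = sum(.data$n_exposed),
      n_immobilized = sum(.data$n_immobilized),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mortality = .data$n_immobilized / .data$n_exposed,
      flagged = .data$mortality > .env$threshold
    ) |>
    dplyr::arrange(.data$run_id)
  structure(
    list(
      pooled = sum(ctl$n_immobilized) / sum(ctl$n_exposed),
      per_run = per_run,
      flagged_runs = per_run$run_id[per_run$flagged],
      threshold = threshold
    ),
    class = "control_mortality"
  )
}

#' @export
print.control_mortality <- function(x, ...) {
  cat(sprintf("Control mortality: %.1f%% pooled over %d animals\n",
              100 * x$pooled, sum(x$per_run$n_exposed)))
  if (length(x$flagged_runs) > 0) {
    cat(sprintf("  runs above the %.0f%% validity threshold: %s\n",
                100 * x$threshold, paste(x$flagged_runs, collapse = ", ")))
  } else {
    cat(sprintf("  all runs within the %.0f%% validity threshold\n",
                100 * x$threshold))
  }
  invisible(x)
}

#' Build the planned exposure design
#'
#' Lays out the %MP-by-SS grid of a ratio experiment. The endpoint mixture
#' ratios (the smallest and largest `pct_levels`, typically 0% and 100%)
#' receive the full concentration series; intermediate ratios receive the
#' (usually shorter) mixture series. Per-cell nominal masses of the test and
#' reference particle are computed from the mass fraction:
#' `test_mass = ss_conc * pct_mp / 100` and
#' `ref_mass = ss_conc - test_mass`.
#'
#' @param pct_levels Mixture ratios (%MP, each in \[0, 100\]).
#' @param ss_levels_full SS concentrations (mg/L, > 0) for the endpoint
#'   ratios.
#' @param ss_levels_mixture SS concentrations for intermediate ratios;
#'   defaults to `ss_levels_full`.
#' @param replicates Planned replicates per cell.
#' @return An object of class `design_matrix`: a list with `cells` (tibble:
#'   `pct_mp`, `ss_conc`, `test_mass`, `ref_mass`, `replicates`),
#'   `pct_levels`, and `replicates_per_cell`.
#' @examples
#' d <- build_design(c(0, 20, 40, 60, 80, 100),
#'                   ss_levels_full = c(0.1, 1, 10, 100, 1000, 10000),
#'                   ss_levels_mixture = c(10, 100, 1000, 10000))
#' nrow(d$cells)  # 2*6 + 4*4 = 28 planned cells
#' @export
build_design <- function(pct_levels, ss_levels_full,
                         ss_levels_mixture = ss_levels_full,
                         replicates = 5) {
  if (length(pct_levels) == 0 || length(ss_levels_full) == 0 ||
      length(ss_levels_mixture) == 0) {
    abort("Level lists must be non-empty.")
  }
  if (any(pct_levels < 0 | pct_levels > 100)) {
    abort("pct_levels must lie within [0, 100].")
  }
  if (any(ss_levels_full <= 0) || any(ss_levels_mixture <= 0)) {
    abort("All SS concentrations must be > 0.")
  }
  stopifnot_scalar_number(replicates, "replicates", lower = 1)
  pct_levels <- sort(unique(pct_levels))
  endpoints <- range(pct_levels)
  cells <- purrr::map_dfr(pct_levels, function(p) {
    ss <- if (p %in% endpoints) sort(ss_levels_full) else sort(ss_levels_mixture)
    tibble::tibble(pct_mp = p, ss_conc = ss)
  }) |>
    dplyr::mutate(
      test_mass = .data$ss_conc * .data$pct_mp / 100,
      ref_mass = .data$ss_conc - .data$test_mass,
      replicates = as.integer(.env$replicates)
    )
  structure(
    list(cells = cells, pct_levels = pct_levels,
         replicates_per_cell = as.integer(replicates)),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d cells, %d pct_mp levels, %d replicates/cell\n",
              nrow(x$cells), length(x$pct_levels), x$replicates_per_cell))
  invisible(x)
}
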