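#' Default ratio-test exposure design
#'
#' Six mixture ratios (0–100% in steps of 20), a six-decade concentration
#' series 0.1–10 000 mg/L for the endpoint ratios and the upper four
#' concentrations for the intermediates, five replicates per cell.
#'
#' @param replicates Replicates per cell.
#' @return A [build_design()] object.
#' @export
default_design <- function(replicates = 5) {
  build_design(
    pct_levels = c(0, 20, 40, 60, 80, 100),
    ss_levels_full = c(0.1, 1, 10, 100, 1000, 10000),
    ss_levels_mixture = c(10, 100, 1000, 10000),
    replicates = replicates
  )
}

#' Configuration of the synthetic bioassay generator
#'
#' The generator draws binomial immobilization counts from a logistic
#' dose-response whose LC50 decays exponentially in the test particle's
#' mass fraction — the statistical structure the analysis pipeline assumes.
#' Background (control) mortality composes with the dose effect by
#' independence, `p_total = cm + (1 - cm) * p_model`, which makes Abbott's
#' correction exactly appropriate on expectations.
#'
#' Defaults mirror the magnitudes of a published acute *Daphnia magna*
#' immobilization experiment with PET and kaolin suspensions: reference
#' LC50 around 411 mg/L decaying to about 56 mg/L, 95.4% mean control
#' survival, ten neonates per tube.
#'
#' @param design A [build_design()] object (default [default_design()]).
#' @param y0 True LC50 at 0% MP, mg/L.
#' @param plateau True LC50 at large %MP, mg/L (must be < `y0`).
#' @param k True decay rate per %MP unit (> 0).
#' @param hill True Hill slope of the dose-response.
#' @param control_mortality Background mortality proportion in \[0, 1).
#' @param n_per_tube Animals per replicate tube.
#' @param n_control_tubes Particle-free control tubes per run.
#' @param n_runs Number of experimental runs the controls are spread over.
#' @param seed Master seed; every design cell has its own derived stream,
#'   so adding a cell does not perturb the others.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(design = default_design(), y0 = 411,
                             plateau = 56, k = 0.08, hill = 1,
                             control_mortality = 0.046, n_per_tube = 10,
                             n_control_tubes = 5, n_runs = 1, seed = 1L) {
  stopifnot(inherits(design, "design_matrix"))
  stopifnot_scalar_number(y0, "y0", lower = .Machine$double.eps)
  stopifnot_scalar_number(plateau, "plateau", lower = 0)
  if (plateau >= y0) abort("`plateau` must be smaller than `y0`.")
  stopifnot_scalar_number(k, "k", lower = .Machine$double.eps)
  stopifnot_scalar_number(hill, "hill", lower = .Machine$double.eps)
  stopifnot_scalar_number(control_mortality, "control_mortality",
                          lower = 0, upper = 1 - 1e-12)
  stopifnot_scalar_number(n_per_tube, "n_per_tube", lower = 1)
  structure(
    list(design = design, y0 = y0, plateau = plateau, k = k, hill = hill,
         control_mortality = control_mortality,
         n_per_tube = as.integer(n_per_tube),
         n_control_tubes = as.integer(n_control_tubes),
         n_runs = as.integer(n_runs), seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' True LC50 surface of the generator
#'
#' `LC50(pct_mp) = (y0 - plateau) * exp(-k * pct_mp) + plateau`.
#'
#' @param config A [generator_config()].
#' @param pct_mp Mass fraction(s), 0–100.
#' @return LC50 in mg/L.
#' @export
true_lc50 <- function(config, pct_mp) {
  stopifnot(inherits(config, "generator_config"))
  if (any(pct_mp < 0 | pct_mp > 100)) abort("`pct_mp` must lie in [0, 100].")
  (config$y0 - config$plateau) * exp(-config$k * pct_mp) + config$plateau
}

# Expected total mortality in a cell (model effect plus independent
# background mortality).
cell_p_total <- function(config, pct_mp, ss_conc) {
  p_model <- logistic_p(ss_conc, log10(true_lc50(config, pct_mp)), config$hill)
  config$control_mortality + (1 - config$control_mortality) * p_model
}

#' Generate a synthetic bioassay dataset
#'
#' Per design cell, immobilization counts are drawn as
#' `Binomial(n_per_tube, p_total)` per replicate, where
#' `p_model = 1 / (1 + (LC50(pct_mp) / C)^hill)` and
#' `p_total = cm + (1 - cm) * p_model`. Control tubes use
#' `p_total = cm`. Fully reproducible from the config seed: each cell and
#' each control run draws from its own derived stream.
#'
#' @param config A [generator_config()].
#' @return A validated [bioassay_dataset()].
#' @export
generate_bioassay <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cells <- config$design$cells
  treat <- purrr::pmap_dfr(
    cells[, c("pct_mp", "ss_conc", "replicates")],
    function(pct_mp, ss_conc, replicates) {
      p <- cell_p_total(config, pct_mp, ss_conc)
      s <- cell_seed(config$seed, pct_mp, ss_conc)
      deaths <- with_stream(s, rbinom(replicates, config$n_per_tube, p))
      tibble::tibble(
        ss_conc = ss_conc, pct_mp = pct_mp,
        n_exposed = config$n_per_tube, n_immobilized = deaths,
        run_id = sprintf("run%d", 1L +
                           (seq_len(replicates) - 1L) %% config$n_runs),
        is_control = FALSE
      )
    }
  )
  controls <- purrr::map_dfr(seq_len(config$n_runs), function(r) {
    s <- cell_seed(config$seed, -1, r, tag = 1L)
    deaths <- with_stream(
      s, rbinom(config$n_control_tubes, config$n_per_tube,
                config$control_mortality))
    tibble::tibble(
      ss_conc = 0, pct_mp = 0, n_exposed = config$n_per_tube,
      n_immobilized = deaths, run_id = sprintf("run%d", r),
      is_control = TRUE
    )
  })
  bioassay_dataset(
    dplyr::bind_rows(controls, treat),
    metadata = list(source = "synthetic", generator = unclass(config)[
      c("y0", "plateau", "k", "hill", "control_mortality", "seed")])
  )
}

#' Noiseless expectation of the generator
#'
#' Returns one point per design cell with the observed proportion set to
#' the exact model mortality (no binomial noise, no background mortality).
#' Useful for closure checks: fitting the pipeline to these points must
#' return the generator's own parameters.
#'
#' @param config A [generator_config()].
#' @return A tibble with `pct_mp`, `ss_conc`, `p_obs`.
#' @export
expected_proportions <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cells <- config$design$cells
  tibble::tibble(
    pct_mp = cells$pct_mp, ss_conc = cells$ss_conc,
    p_obs = logistic_p(cells$ss_conc,
                       log10(true_lc50(config, cells$pct_mp)), config$hill)
  )
}
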