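#' One-phase exponential decay of LCx against %MP
#'
#' Fits `Y(x) = (y0 - plateau) * exp(-k * x) + plateau` to effect
#' concentrations as a function of the test particle's mass fraction. The
#' curve starts at `y0` (the LCx of the pure reference particle), decays at
#' rate `k` per percentage unit, and levels off at `plateau` (the LCx of
#' the pure test particle). Both the amplitude `y0 - plateau` and the
#' plateau are constrained non-negative.
#'
#' The fit is deterministic: for each candidate `k` the model is linear in
#' `(y0 - plateau, plateau)` and solved by constrained least squares; the
#' profiled SSE is then minimised over `k` by a coarse log-scale scan plus
#' local refinement. When no decaying curve improves on the flat model
#' (constant LCx, or increasing points), a degenerate fit is returned with
#' `plateau = y0` and `k = NA`, with a warning carrying the flat
#' alternative.
#'
#' @param points A data frame with columns `pct_mp` and `lcx` (mg/L, > 0);
#'   at least 3 distinct `pct_mp` values.
#' @param weights Optional non-negative observation weights (e.g. inverse
#'   CI widths). Default unweighted.
#' @param x_level The effect percentage the LCx values correspond to
#'   (metadata only; 10 or 50 in practice).
#' @return An object of class `decay_fit`: list with `y0`, `plateau`, `k`,
#'   `r_squared`, `sse`, `x_level`, `degenerate`, and the fitted `points`.
#' @examples
#' pts <- tibble::tibble(pct_mp = c(0, 20, 40, 60, 80, 100))
#' pts$lcx <- (411 - 56) * exp(-0.08 * pts$pct_mp) + 56
#' fit_decay(pts)
#' @export
fit_decay <- function(points, weights = NULL, x_level = 10) {
  pts <- tibble::as_tibble(points)
  if (!all(c("pct_mp", "lcx") %in% names(pts))) {
    abort("`points` must have columns `pct_mp` and `lcx`.")
  }
  if (length(unique(pts$pct_mp)) < 3) {
    abort("Need at least 3 distinct pct_mp values to fit a decay curve.")
  }
  if (any(pts$lcx <= 0)) abort("All lcx values must be positive.")
  x <- pts$pct_mp
  y <- pts$lcx
  w <- if (is.null(weights)) rep(1, length(y)) else weights
  if (length(w) != length(y) || any(w < 0)) {
    abort("`weights` must be non-negative and match the number of points.")
  }

  # Constrained linear solve for fixed k: y ~ a*exp(-k x) + b, a >= 0, b >= 0.
  solve_linear <- function(k) {
    e <- exp(-k * x)
    X <- cbind(e, 1)
    XtW <- t(X * w)
    ab <- tryCatch(unname(drop(solve(XtW %*% X, XtW %*% y))),
                   error = function(err) c(NA_real_, NA_real_))
    cands <- list(ab)
    # Active-set fallbacks for the two non-negativity constraints.
    cands <- c(cands,
               list(c(sum(w * e * y) / sum(w * e^2), 0)),        # b = 0
               list(c(0, sum(w * y) / sum(w))))                  # a = 0 (flat)
    feasible <- Filter(function(p) all(is.finite(p)) && p[1] >= 0 && p[2] >= 0,
                       cands)
    sses <- vapply(feasible, function(p) {
      sum(w * (y - (p[1] * e + p[2]))^2)
    }, numeric(1))
    i <- which.min(sses)
    list(a = feasible[[i]][1], b = feasible[[i]][2], sse = sses[i])
  }

  span <- diff(range(x))
  logk_grid <- seq(log(1e-4 / span * 100), log(50 / span), length.out = 120)
  sse_grid <- vapply(logk_grid, function(lk) solve_linear(exp(lk))$sse,
                     numeric(1))
  i <- which.min(sse_grid)
  bracket <- exp(c(logk_grid[max(1, i - 1)],
                   logk_grid[min(length(logk_grid), i + 1)]))
  opt <- optimize(function(lk) solve_linear(exp(lk))$sse,
                  interval = log(bracket), tol = 1e-12)
  k <- exp(opt$minimum)
  sol <- solve_linear(k)

  flat_mean <- sum(w * y) / sum(w)
  sse_flat <- sum(w * (y - flat_mean)^2)
  sst <- sse_flat

  degenerate <- sol$sse >= sse_flat * (1 - 1e-9) || sol$a <= 0
  if (degenerate) {
    warn(paste("No decaying curve improves on the flat model;",
               "returning the flat alternative (k unidentifiable)."),
         class = "mpratio_degenerate_decay")
    fit <- list(y0 = flat_mean, plateau = flat_mean, k = NA_real_,
                r_squared = if (sst > 0) 1 - sse_flat / sst else 1,
                sse = sse_flat, x_level = x_level, degenerate = TRUE,
                points = pts)
  } else {
    fit <- list(y0 = sol$a + sol$b, plateau = sol$b, k = k,
                r_squared = if (sst > 0) 1 - sol$sse / sst else 1,
                sse = sol$sse, x_level = x_level, degenerate = FALSE,
                points = pts)
  }
  structure(fit, class = "decay_fit")
}

#' Evaluate a decay curve
#'
#' @param object A `decay_fit`.
#' @param pct_mp Mass fractions (%) at which to evaluate.
#' @param ... Unused.
#' @return Predicted LCx values (mg/L).
#' @export
predict.decay_fit <- function(object, pct_mp, ...) {
  k <- if (is.na(object$k)) 0 else object$k
  (object$y0 - object$plateau) * exp(-k * pct_mp) + object$plateau
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> LC%g vs %%MP\n", x$x_level))
  if (x$degenerate) {
    cat(sprintf("  degenerate (flat): level %.4g mg/L, k unidentifiable\n",
                x$y0))
  } else {
    cat(sprintf("  y0 %.4g | plateau %.4g mg/L | k %.4g per %% | R^2 %.3f\n",
                x$y0, x$plateau, x$k, x$r_squared))
  }
  invisible(x)
}

#' Solve the decay curve for the no-effect mass fraction
#'
#' Finds the %MP at which the fitted LCx-vs-%MP curve crosses a reference
#' concentration (the NOEC): the closed-form inversion
#' `x* = -(1/k) * ln((noec - plateau) / (y0 - plateau))`. When the NOEC is
#' at or above `y0` the curve starts below the threshold and the answer is
#' 0; when the NOEC is at or below the plateau the curve never reaches it
#' and `Inf` is returned (no %MP threshold within model range).
#'
#' @param fit A [fit_decay()] result (non-degenerate).
#' @param noec Reference concentration, mg/L.
#' @return The mass fraction (%), possibly 0 or `Inf`.
#' @examples
#' f <- structure(list(y0 = 400, plateau = 50, k = 0.05, degenerate = FALSE),
#'                class = "decay_fit")
#' solve_noe_pct(f, 120)  # 20*log(5) = 32.19
#' @export
solve_noe_pct <- function(fit, noec) {
  stopifnot(inherits(fit, "decay_fit"))
  stopifnot_scalar_number(noec, "noec", lower = 0)
  if (fit$degenerate || is.na(fit$k) || fit$k <= 0) {
    abort("Decay rate k must be positive; the fit is flat or degenerate.",
          class = "mpratio_degenerate_decay_error")
  }
  if (noec >= fit$y0) return(0)
  if (noec <= fit$plateau) return(Inf)
  -log((noec - fit$plateau) / (fit$y0 - fit$plateau)) / fit$k
}

#' Derive the NOEC and NOE%MP thresholds
#'
#' The last stage of the ratio-test workflow. From the per-ratio fits it
#' extracts the LCx at `x_level` for every %MP, fits the one-phase
#' exponential decay of LCx against %MP, takes the NOEC as the lower 95%
#' confidence bound of the reference (0% MP) LCx — a surrogate for the
#' no-observed-effect concentration of suspended solids — and solves the
#' decay curve for the %MP at which it crosses the NOEC (the NOE%MP).
#'
#' @param fits A `mixture_fits` object from [fit_all()], or a list of
#'   `dose_response_fit` objects (must include the 0% level; at least 3
#'   levels in total).
#' @param x_level Effect percentage defining the threshold (default 10,
#'   i.e. the LC10; 50 yields the LC50 analogue).
#' @param weights Optional weights passed to [fit_decay()].
#' @return An object of class `threshold_result`: list with `noec` (mg/L),
#'   `noe_pct_mp` (%, possibly 0 or `Inf`), `decay` (the `decay_fit`),
#'   `reference` (the 0%-MP `dose_response_fit`), `x_level`, and the decay
#'   input `points`.
#' @export
derive_thresholds <- function(fits, x_level = 10, weights = NULL) {
  flist <- if (inherits(fits, "mixture_fits")) fits$fits else fits
  stopifnot(length(flist) >= 1,
            all(vapply(flist, inherits, logical(1), "dose_response_fit")))
  pcts <- vapply(flist, `[[`, numeric(1), "pct_mp")
  if (!any(pcts == 0)) {
    abort("The 0% MP reference series is required to anchor the NOEC.",
          class = "mpratio_missing_reference")
  }
  if (length(unique(pcts)) < 3) {
    abort("Need fits at 3 or more pct_mp levels to fit the decay curve.")
  }
  # Use the stored LC vectors for the standard levels so that subsample
  # aggregates carry their own (aggregated) intervals into the thresholds.
  fit_lcx <- function(f, x) {
    if (x == 10) f$lc10 else if (x == 50) f$lc50 else lcx_ci_vec(f, x)
  }
  points <- tibble::tibble(
    pct_mp = pcts,
    lcx = vapply(flist, function(f) fit_lcx(f, x_level)[["estimate"]],
                 numeric(1))
  ) |>
    dplyr::arrange(.data$pct_mp)
  reference <- flist[[which(pcts == 0)[1]]]
  noec <- fit_lcx(reference, x_level)[["lower"]]

  decay <- withCallingHandlers(
    fit_decay(points, weights = weights, x_level = x_level),
    mpratio_degenerate_decay = function(w) invokeRestart("muffleWarning")
  )
  noe <- if (decay$degenerate) {
    if (noec >= decay$y0) 0 else Inf
  } else {
    solve_noe_pct(decay, noec)
  }
  structure(
    list(noec = noec, noe_pct_mp = noe, decay = decay, reference = reference,
         x_level = x_level, points = points),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> based on LC%g\n", x$x_level))
  cat(sprintf("  NOEC  : %.3g mg/L (lower 95%% bound of the 0%%-MP LC%g)\n",
              x$noec, x$x_level))
  if (is.infinite(x$noe_pct_mp)) {
    cat("  NOE%MP: no %MP threshold within model range (curve never reaches the NOEC)\n")
  } else {
    cat(sprintf("  NOE%%MP: %.3g%% of test particle by mass\n", x$noe_pct_mp))
  }
  invisible(x)
}

#' Classify the outcome scenario of a ratio test
#'
#' Three qualitative outcomes are possible when a test particle is diluted
#' into a reference particle: (A) no test-particle effect — mortality
#' responds to the total suspended-solids level only; (B) an additive
#' test-particle effect — toxicity increases with %MP, so the LC50 of the
#' highest ratio lies significantly below the reference; (C) an
#' ameliorating effect — the test particle is less harmful than the
#' reference. Significance is judged by confidence-interval non-overlap of
#' the LC50 between the highest-%MP series and the 0% reference.
#'
#' @param fits A `mixture_fits` object or list of `dose_response_fit` with
#'   at least two %MP levels.
#' @return `"A"`, `"B"` or `"C"`.
#' @export
classify_scenario <- function(fits) {
  flist <- if (inherits(fits, "mixture_fits")) fits$fits else fits
  stopifnot(length(flist) >= 2,
            all(vapply(flist, inherits, logical(1), "dose_response_fit")))
  pcts <- vapply(flist, `[[`, numeric(1), "pct_mp")
  lo_fit <- flist[[which.min(pcts)]]
  hi_fit <- flist[[which.max(pcts)]]
  cmp <- compare_fits(hi_fit, lo_fit)
  if (cmp$gap < 0) "B" else if (cmp$gap > 0) "C" else "A"
}
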