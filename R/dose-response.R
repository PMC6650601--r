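#' Abbott's correction for control mortality
#'
#' Adjusts an observed mortality proportion for background mortality in the
#' particle-free controls: `(p_obs - p_control) / (1 - p_control)`, clipped
#' to \[0, 1\]. With fully surviving controls the correction is the
#' identity.
#'
#' @param p_obs Observed mortality proportion(s), in \[0, 1\]. Vectorised.
#' @param p_control Control mortality proportion, in \[0, 1).
#' @return Corrected proportion(s) in \[0, 1\].
#' @examples
#' abbott_correct(0.55, 0.10)  # 0.5
#' abbott_correct(0.05, 0.10)  # clipped to 0
#' @export
abbott_correct <- function(p_obs, p_control) {
  if (any(is.na(p_obs)) || any(p_obs < 0 | p_obs > 1)) {
    abort("`p_obs` must lie within [0, 1].")
  }
  stopifnot_scalar_number(p_control, "p_control", lower = 0)
  if (p_control >= 1) {
    abort("Abbott's correction is undefined for p_control = 1 (no surviving controls).")
  }
  pmin(1, pmax(0, (p_obs - p_control) / (1 - p_control)))
}

# Predicted mortality of the constrained logistic model at concentration C:
# p(C) = bottom + (top - bottom) / (1 + (10^m / C)^h), m = log10 LC50.
logistic_p <- function(conc, log10_lc50, hill, bottom = 0, top = 1) {
  bottom + (top - bottom) / (1 + (10^log10_lc50 / conc)^hill)
}

# Sum of squared errors and its analytic Jacobian on the corrected-
# proportion scale; x = log10(conc).
logistic_sse <- function(m, h, x, y) {
  p <- 1 / (1 + 10^(h * (m - x)))
  sum((y - p)^2)
}

logistic_jacobian <- function(m, h, x, hill_fixed) {
  p <- 1 / (1 + 10^(h * (m - x)))
  dm <- -log(10) * h * p * (1 - p)
  if (hill_fixed) {
    matrix(dm, ncol = 1)
  } else {
    dh <- -log(10) * (m - x) * p * (1 - p)
    cbind(dm, dh)
  }
}

#' Fit a constrained three-parameter logistic dose-response curve
#'
#' Fits mortality against the suspended-solids concentration with the
#' log-logistic model `p(C) = 1 / (1 + (LC50 / C)^h)` — the three-parameter
#' logistic family with the bottom asymptote constrained to 0 and the top to
#' 1, so that the fitted midpoint is the LC50 directly. Each replicate tube
#' is one observation; observed proportions are Abbott-corrected for control
#' mortality before fitting and concentrations are log10-transformed
#' internally. By default the Hill slope is fixed at 1 and `log10(LC50)` is
#' the single free parameter, estimated by ordinary least squares on the
#' corrected proportions; `hill_fixed = FALSE` estimates the slope as well.
#'
#' Confidence intervals use asymptotic normal theory on the log10 scale with
#' a t critical value (df = observations minus free parameters) and are
#' back-transformed, which keeps the bounds positive. A binomial-GLM engine
#' (`engine = "glm"`, raw counts, slope estimated) is available for
#' comparison but is not the default.
#'
#' @param points A data frame of treatment replicates with column `ss_conc`
#'   (> 0) and either counts (`n_exposed`, `n_immobilized`) or an observed
#'   proportion column `p_obs`. Control rows (`ss_conc == 0`) are dropped.
#' @param p_control Pooled control mortality used for Abbott's correction.
#' @param hill_fixed Fix the Hill slope (default) or estimate it.
#' @param hill Value of the fixed Hill slope.
#' @param conf_level Confidence level for the intervals.
#' @param pct_mp Optional %MP label carried into the fit.
#' @param engine `"ols"` (default, replicate proportions) or `"glm"`
#'   (binomial likelihood on raw counts, slope always estimated).
#' @return An object of class `dose_response_fit`: a list with `model`
#'   (`log10_lc50`, `hill`, `bottom`, `top`, `hill_fixed`), `lc50` and
#'   `lc10` (each `c(estimate, lower, upper)`, mg/L), `r_squared`, `n_obs`,
#'   `pct_mp`, `ss_used`, `df`, and the parameter covariance `cov` on the
#'   (log10_lc50, hill) scale.
#' @examples
#' pts <- tibble::tibble(ss_conc = c(10, 31.6, 100, 316, 1000),
#'                       p_obs = ss_conc / (ss_conc + 100))
#' fit <- fit_dose_response(pts, p_control = 0)
#' fit$lc50[["estimate"]]  # 100
#' @export
fit_dose_response <- function(points, p_control = 0, hill_fixed = TRUE,
                              hill = 1, conf_level = 0.95, pct_mp = NA_real_,
                              engine = c("ols", "glm")) {
  engine <- match.arg(engine)
  pts <- prepare_points(points)
  pts <- pts[pts$ss_conc > 0, ]
  if (length(unique(pts$ss_conc)) < 2) {
    abort("Need at least two distinct positive concentrations to fit.")
  }
  if (engine == "glm") {
    return(fit_glm_engine(pts, conf_level, pct_mp))
  }

  y <- abbott_correct(pts$p_obs, p_control)
  x <- log10(pts$ss_conc)
  if (diff(range(y)) < .Machine$double.eps^0.5) {
    abort(sprintf(
      "Degenerate series%s: all corrected proportions are identical (%.3f).",
      if (is.na(pct_mp)) "" else sprintf(" (pct_mp = %g)", pct_mp), y[1]),
      class = "mpratio_degenerate_fit")
  }

  lo <- min(x) - 2
  hi <- max(x) + 2
  if (hill_fixed) {
    stopifnot_scalar_number(hill, "hill", lower = .Machine$double.eps)
    # Coarse scan then local refinement: deterministic and global over the
    # bounded log10 LC50 range.
    grid <- seq(lo, hi, length.out = 241)
    sse_grid <- vapply(grid, logistic_sse, numeric(1), h = hill, x = x, y = y)
    i <- which.min(sse_grid)
    bracket <- c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)])
    opt <- optimize(logistic_sse, interval = bracket, h = hill, x = x, y = y,
                    tol = 1e-10)
    m <- opt$minimum
    h <- hill
    sse <- opt$objective
    n_free <- 1L
  } else {
    obj <- function(par) logistic_sse(par[1], exp(par[2]), x = x, y = y)
    # Three deterministic multi-starts across the concentration range.
    starts <- lapply(quantile(c(lo, hi), c(0.25, 0.5, 0.75)),
                     function(m0) c(m0, 0))
    fits <- lapply(starts, function(s) {
      optim(s, obj, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-12))
    })
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
    if (best$convergence != 0) {
      abort(sprintf("Dose-response fit did not converge%s.",
                    if (is.na(pct_mp)) "" else sprintf(" (pct_mp = %g)", pct_mp)))
    }
    m <- best$par[1]
    h <- exp(best$par[2])
    sse <- best$value
    n_free <- 2L
  }

  n <- length(y)
  dfree <- n - n_free
  if (dfree < 1) abort("Not enough observations for a confidence interval.")
  s2 <- sse / dfree
  J <- logistic_jacobian(m, h, x, hill_fixed)
  jtj <- crossprod(J)
  cov2 <- matrix(0, 2, 2, dimnames = list(c("log10_lc50", "hill"),
                                          c("log10_lc50", "hill")))
  cov_free <- tryCatch(s2 * solve(jtj), error = function(e) {
    matrix(NA_real_, n_free, n_free)
  })
  if (hill_fixed) {
    cov2[1, 1] <- cov_free[1, 1]
  } else {
    cov2[] <- cov_free
  }

  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst

  fit <- structure(
    list(
      model = list(log10_lc50 = m, hill = h, bottom = 0, top = 1,
                   hill_fixed = hill_fixed),
      r_squared = r2, n_obs = n, df = dfree, sse = sse, cov = cov2,
      conf_level = conf_level, pct_mp = pct_mp,
      ss_used = sort(unique(pts$ss_conc)), engine = "ols",
      subsampled = FALSE
    ),
    class = "dose_response_fit"
  )
  fit$lc50 <- lcx_ci_vec(fit, 50)
  fit$lc10 <- lcx_ci_vec(fit, 10)
  fit
}

# Normalise input points to (ss_conc, p_obs, n_exposed?) regardless of
# whether counts or proportions were supplied.
prepare_points <- function(points) {
  pts <- tibble::as_tibble(points)
  if (!"ss_conc" %in% names(pts)) abort("`points` must have a `ss_conc` column.")
  if (!"p_obs" %in% names(pts)) {
    if (!all(c("n_exposed", "n_immobilized") %in% names(pts))) {
      abort("`points` needs either `p_obs` or `n_exposed` + `n_immobilized`.")
    }
    pts$p_obs <- pts$n_immobilized / pts$n_exposed
  }
  pts
}

# Binomial GLM engine: logit p is linear in log10(C), so the model is the
# same log-logistic family with the slope estimated by maximum likelihood.
fit_glm_engine <- function(pts, conf_level, pct_mp) {
  if (!all(c("n_exposed", "n_immobilized") %in% names(pts))) {
    abort("engine = \"glm\" requires count columns n_exposed and n_immobilized.")
  }
  x <- log10(pts$ss_conc)
  g <- stats::glm(
    cbind(pts$n_immobilized, pts$n_exposed - pts$n_immobilized) ~ x,
    family = stats::binomial()
  )
  b <- coef(g)
  h <- b[[2]] / log(10)
  m <- -b[[1]] / b[[2]]
  V <- vcov(g)
  # Delta method: m = -b0/b1, h = b1/ln 10.
  gm <- c(-1 / b[[2]], b[[1]] / b[[2]]^2)
  gh <- c(0, 1 / log(10))
  cov2 <- matrix(c(
    drop(t(gm) %*% V %*% gm), drop(t(gm) %*% V %*% gh),
    drop(t(gm) %*% V %*% gh), drop(t(gh) %*% V %*% gh)
  ), 2, 2, dimnames = list(c("log10_lc50", "hill"), c("log10_lc50", "hill")))
  p_hat <- stats::fitted(g)
  y <- pts$n_immobilized / pts$n_exposed
  sst <- sum((y - mean(y))^2)
  fit <- structure(
    list(
      model = list(log10_lc50 = m, hill = h, bottom = 0, top = 1,
                   hill_fixed = FALSE),
      r_squared = 1 - sum((y - p_hat)^2) / sst,
      n_obs = nrow(pts), df = g$df.residual, sse = sum((y - p_hat)^2),
      cov = cov2, conf_level = conf_level, pct_mp = pct_mp,
      ss_used = sort(unique(pts$ss_conc)), engine = "glm",
      subsampled = FALSE
    ),
    class = "dose_response_fit"
  )
  fit$lc50 <- lcx_ci_vec(fit, 50)
  fit$lc10 <- lcx_ci_vec(fit, 10)
  fit
}

#' Effect concentration LCx of a fitted logistic model
#'
#' For the bottom = 0, top = 1 configuration the concentration producing an
#' effect of x% is `LC50 * (x / (100 - x))^(1 / hill)`.
#'
#' @param model A `LogisticModel` (the `model` element of a
#'   [fit_dose_response()] result, or any list with `log10_lc50` and
#'   `hill`), or a `dose_response_fit`.
#' @param x Effect percentage, strictly between 0 and 100.
#' @return The concentration in mg/L.
#' @examples
#' m <- list(log10_lc50 = 2, hill = 1)
#' lcx(m, 50)  # 100
#' lcx(m, 10)  # 100/9
#' @export
lcx <- function(model, x) {
  if (inherits(model, "dose_response_fit")) model <- model$model
  stopifnot_scalar_number(x, "x")
  if (x <= 0 || x >= 100) abort("`x` must lie strictly within (0, 100).")
  10^model$log10_lc50 * (x / (100 - x))^(1 / model$hill)
}

# (estimate, lower, upper) of LCx in mg/L, computed on the log10 scale.
lcx_ci_vec <- function(fit, x) {
  m <- fit$model
  r <- x / (100 - x)
  log10_lcx <- m$log10_lc50 + log10(r) / m$hill
  if (m$hill_fixed) {
    se <- sqrt(fit$cov[1, 1])
  } else {
    grad <- c(1, -log10(r) / m$hill^2)
    se <- sqrt(drop(t(grad) %*% fit$cov %*% grad))
  }
  tcrit <- qt(1 - (1 - fit$conf_level) / 2, df = fit$df)
  half <- tcrit * se
  c(estimate = 10^log10_lcx,
    lower = 10^(log10_lcx - half),
    upper = 10^(log10_lcx + half))
}

#' Confidence interval for an LCx level
#'
#' Propagates the uncertainty of the fitted parameters to an arbitrary
#' effect level. When the Hill slope is fixed, the LCx interval is the LC50
#' interval scaled by `(x/(100-x))^(1/hill)` exactly; when the slope is
#' estimated, the delta method on `log10 LCx = log10 LC50 +
#' log10(x/(100-x))/hill` is used with the full parameter covariance.
#'
#' @param fit A [fit_dose_response()] result.
#' @param x Effect percentage in (0, 100).
#' @return Named numeric `c(lower, upper)` in mg/L.
#' @export
lcx_ci <- function(fit, x) {
  stopifnot(inherits(fit, "dose_response_fit"))
  v <- lcx_ci_vec(fit, x)
  v[c("lower", "upper")]
}

#' Compare two dose-response fits by confidence-interval overlap
#'
#' Non-overlapping 95% confidence intervals of the LC50 are taken as
#' evidence of a significant difference between two treatments. The signed
#' gap is 0 when the intervals overlap, positive (the separation between the
#' nearest endpoints) when fit A's interval lies wholly above fit B's, and
#' negative when wholly below.
#'
#' @param fit_a,fit_b [fit_dose_response()] results.
#' @return A list with `overlap` (logical), `significant` (logical,
#'   `!overlap`), and `gap` (signed separation, mg/L).
#' @export
compare_fits <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "dose_response_fit"),
            inherits(fit_b, "dose_response_fit"))
  a <- fit_a$lc50
  b <- fit_b$lc50
  gap <- if (a[["lower"]] > b[["upper"]]) {
    a[["lower"]] - b[["upper"]]
  } else if (b[["lower"]] > a[["upper"]]) {
    -(b[["lower"]] - a[["upper"]])
  } else {
    0
  }
  list(overlap = gap == 0, significant = gap != 0, gap = gap)
}

#' Predicted mortality from a fitted dose-response curve
#'
#' @param object A `dose_response_fit`.
#' @param conc Concentrations (mg/L) at which to predict.
#' @param ... Unused.
#' @return Predicted corrected mortality proportions.
#' @export
predict.dose_response_fit <- function(object, conc, ...) {
  m <- object$model
  logistic_p(conc, m$log10_lc50, m$hill, m$bottom, m$top)
}

#' @export
print.dose_response_fit <- function(x, ...) {
  lab <- if (is.na(x$pct_mp)) "" else sprintf(" [%g%% MP]", x$pct_mp)
  cat(sprintf("<dose_response_fit>%s %s\n", lab,
              if (isTRUE(x$subsampled)) "(subsample aggregate)" else ""))
  cat(sprintf("  LC50 %.3g mg/L (95%% CI %.3g-%.3g) | LC10 %.3g (%.3g-%.3g)\n",
              x$lc50[["estimate"]], x$lc50[["lower"]], x$lc50[["upper"]],
              x$lc10[["estimate"]], x$lc10[["lower"]], x$lc10[["upper"]]))
  cat(sprintf("  hill %.3g%s | R^2 %.3f | n = %d tubes\n",
              x$model$hill, if (x$model$hill_fixed) " (fixed)" else "",
              x$r_squared, x$n_obs))
  invisible(x)
}
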