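test_that("Abbott's correction matches its closed form and clips", {
  expect_equal(abbott_correct(0.55, 0), 0.55)
  expect_equal(abbott_correct(0.55, 0.10), 0.5)
  expect_equal(abbott_correct(0.05, 0.10), 0)     # negative corrected, clipped
  expect_equal(abbott_correct(1, 0.3), 1)
  expect_error(abbott_correct(0.5, 1), "undefined")

  # identity at p_control = 0, monotone in p_obs
  p <- seq(0, 1, by = 0.05)
  expect_equal(abbott_correct(p, 0), p)
  for (pc in c(0.05, 0.2, 0.5)) {
    expect_true(all(diff(abbott_correct(p, pc)) >= 0))
  }
})

test_that("model-consistent data is recovered exactly", {
  conc <- c(10, 31.6, 100, 316, 1000)
  pts <- tibble::tibble(ss_conc = conc, p_obs = conc / (conc + 100))
  fit <- fit_dose_response(pts, p_control = 0, hill_fixed = TRUE, hill = 1)
  expect_equal(fit$lc50[["estimate"]], 100, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_lt(fit$lc10[["estimate"]], fit$lc50[["estimate"]])
})

test_that("the optimizer matches a brute-force grid search", {
  grid <- seq(-1, 5, by = 1e-4)
  for (seed in 1:5) {
    set.seed(seed)
    m_true <- runif(1, 1, 3)
    pts <- simulate_series(log10_lc50 = m_true, seed = seed + 100)
    y <- pts$n_immobilized / pts$n_exposed
    x <- log10(pts$ss_conc)
    if (diff(range(y)) < 1e-8) next
    sse <- vapply(grid, function(m) sum((y - 1 / (1 + 10^(m - x)))^2),
                  numeric(1))
    m_grid <- grid[which.min(sse)]
    fit <- fit_dose_response(pts, p_control = 0)
    expect_equal(fit$model$log10_lc50, m_grid, tolerance = 2e-4)
  }
})

test_that("lcx matches its closed form and numeric inversion", {
  m1 <- list(log10_lc50 = log10(123), hill = 0.7)
  expect_equal(lcx(m1, 50), 123)                       # symmetry at x = 50
  m2 <- list(log10_lc50 = 2, hill = 1)
  expect_equal(lcx(m2, 10), 100 / 9)
  m3 <- list(log10_lc50 = 2, hill = 2)
  expect_equal(lcx(m3, 10), 100 * (1 / 9)^(1 / 2), tolerance = 1e-12)
  # independent check: invert p(C) = 0.10 numerically
  root <- uniroot(function(C) 1 / (1 + (100 / C)^2) - 0.10,
                  interval = c(1e-6, 1e6), tol = 1e-12)$root
  expect_equal(lcx(m3, 10), root, tolerance = 1e-6)
  expect_error(lcx(m2, 0), "strictly within")
  expect_error(lcx(m2, 100), "strictly within")
})

test_that("LCx intervals scale the LC50 interval when the slope is fixed", {
  fit <- make_fit(0, lc50 = sqrt(90 * 110), lower = 90, upper = 110)
  ci <- lcx_ci(fit, 10)
  expect_equal(unname(ci), c(10, 110 / 9), tolerance = 1e-9)
  expect_equal(lcx_ci(fit, 50), fit$lc50[c("lower", "upper")])
})

test_that("delta-method LC10 interval agrees with a parametric bootstrap", {
  conc <- rep(c(10, 31.6, 100, 316, 1000), each = 5)
  p_true <- 1 / (1 + (100 / conc)^1.5)
  set.seed(42)
  pts <- tibble::tibble(ss_conc = conc,
                        p_obs = pmin(1, pmax(0, p_true + rnorm(length(conc), 0, 0.05))))
  fit <- fit_dose_response(pts, p_control = 0, hill_fixed = FALSE)
  ci_delta <- lcx_ci(fit, 10)

  sigma <- sqrt(fit$sse / fit$df)
  p_hat <- predict(fit, conc)
  set.seed(43)
  boot <- replicate(2000, {
    pb <- pmin(1, pmax(0, p_hat + rnorm(length(conc), 0, sigma)))
    f <- tryCatch(
      fit_dose_response(tibble::tibble(ss_conc = conc, p_obs = pb),
                        p_control = 0, hill_fixed = FALSE),
      error = function(e) NULL)
    if (is.null(f)) NA_real_ else f$lc10[["estimate"]]
  })
  ci_boot <- quantile(boot, c(0.025, 0.975), na.rm = TRUE)
  expect_equal(unname(ci_delta[["lower"]]), unname(ci_boot[[1]]),
               tolerance = 0.1)
  expect_equal(unname(ci_delta[["upper"]]), unname(ci_boot[[2]]),
               tolerance = 0.1)
})

test_that("confidence-interval overlap verdicts and signed gaps", {
  a <- make_fit(0, 400, 300, 520)
  b <- make_fit(100, 60, 40, 80)
  cmp <- compare_fits(a, b)
  expect_false(cmp$overlap)
  expect_true(cmp$significant)
  expect_equal(cmp$gap, 300 - 80)
  expect_equal(compare_fits(b, a)$gap, -(300 - 80))

  c1 <- make_fit(0, 70, 50, 100)
  c2 <- make_fit(20, 110, 90, 140)
  expect_true(compare_fits(c1, c2)$overlap)
  expect_equal(compare_fits(c1, c2)$gap, 0)
  expect_equal(compare_fits(a, a)$gap, 0)   # identical fits overlap
})

test_that("raising observed mortality weakly lowers the fitted LC50", {
  for (seed in 1:10) {
    pts <- simulate_series(log10_lc50 = 2, seed = seed)
    pts$p_obs <- pts$n_immobilized / pts$n_exposed
    fit1 <- fit_dose_response(pts, p_control = 0)
    bumped <- pts
    bumped$p_obs <- pmin(1, pts$p_obs + 0.1)
    if (diff(range(bumped$p_obs)) < 1e-8) next
    fit2 <- fit_dose_response(bumped, p_control = 0)
    expect_lte(fit2$lc50[["estimate"]], fit1$lc50[["estimate"]] * (1 + 1e-8))
  }
})

test_that("LC50 and its interval are equivariant to concentration rescaling", {
  pts <- simulate_series(log10_lc50 = 2, seed = 3)
  fit1 <- fit_dose_response(pts, p_control = 0)
  for (c_mult in c(0.1, 7, 1000)) {
    pts2 <- pts
    pts2$ss_conc <- pts$ss_conc * c_mult
    fit2 <- fit_dose_response(pts2, p_control = 0)
    expect_equal(fit2$lc50, fit1$lc50 * c_mult, tolerance = 1e-6)
    expect_equal(fit2$lc10, fit1$lc10 * c_mult, tolerance = 1e-6)
  }
})

test_that("degenerate and underdetermined series raise errors", {
  flat <- tibble::tibble(ss_conc = c(10, 100, 1000), p_obs = 0.5)
  expect_error(fit_dose_response(flat, p_control = 0),
               class = "mpratio_degenerate_fit")
  one_conc <- tibble::tibble(ss_conc = c(100, 100), p_obs = c(0.2, 0.8))
  expect_error(fit_dose_response(one_conc, p_control = 0),
               "two distinct")
})

test_that("the binomial GLM engine recovers the same model family", {
  pts <- simulate_series(log10_lc50 = 2, hill = 1.5, reps = 10, seed = 5)
  ols <- fit_dose_response(pts, p_control = 0, hill_fixed = FALSE)
  glm_fit <- fit_dose_response(pts, p_control = 0, engine = "glm")
  expect_equal(glm_fit$model$log10_lc50, ols$model$log10_lc50,
               tolerance = 0.1)
  expect_equal(glm_fit$model$hill, ols$model$hill, tolerance = 0.25)
})
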