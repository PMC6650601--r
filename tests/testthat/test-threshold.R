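decay_points <- function(y0, plateau, k, x = c(0, 20, 40, 60, 80, 100)) {
  tibble::tibble(pct_mp = x, lcx = (y0 - plateau) * exp(-k * x) + plateau)
}

test_that("noiseless decay points are recovered exactly", {
  fit <- fit_decay(decay_points(411, 56, 0.08))
  expect_equal(fit$y0, 411, tolerance = 1e-4)
  expect_equal(fit$plateau, 56, tolerance = 1e-4)
  expect_equal(fit$k, 0.08, tolerance = 1e-4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)
  expect_false(fit$degenerate)
  # Y(0) = y0 exactly
  expect_equal(predict(fit, 0), fit$y0)
})

test_that("flat or increasing profiles yield the degenerate flat fit", {
  flat <- tibble::tibble(pct_mp = c(0, 50, 100), lcx = 200)
  expect_warning(f <- fit_decay(flat), class = "mpratio_degenerate_decay")
  expect_true(f$degenerate)
  expect_equal(f$plateau, f$y0)
  expect_true(is.na(f$k))

  rising <- tibble::tibble(pct_mp = c(0, 50, 100), lcx = c(100, 200, 400))
  expect_warning(f2 <- fit_decay(rising), class = "mpratio_degenerate_decay")
  expect_true(f2$degenerate)
})

test_that("decay fit input validation", {
  expect_error(fit_decay(tibble::tibble(pct_mp = c(0, 50), lcx = c(2, 1))),
               "3 distinct")
  expect_error(fit_decay(tibble::tibble(pct_mp = c(0, 50, 100),
                                        lcx = c(2, 1, 0))),
               "positive")
})

test_that("the decay fitter matches a brute-force parameter grid", {
  set.seed(21)
  pts <- decay_points(400, 50, 0.05)
  pts$lcx <- pts$lcx * exp(rnorm(nrow(pts), 0, 0.15))
  fit <- fit_decay(pts)
  sse_of <- function(y0, plateau, k) {
    sum((pts$lcx - ((y0 - plateau) * exp(-k * pts$pct_mp) + plateau))^2)
  }
  grid <- expand.grid(
    y0 = exp(seq(log(100), log(1200), length.out = 60)),
    plateau = exp(seq(log(5), log(200), length.out = 60)),
    k = exp(seq(log(1e-3), log(1), length.out = 60))
  )
  grid_sse <- min(mapply(sse_of, grid$y0, grid$plateau, grid$k))
  expect_lte(fit$sse, grid_sse * 1.001)
})

test_that("the decay fitter agrees with an independent nonlinear solver", {
  set.seed(77)
  pts <- decay_points(411, 56, 0.08)
  pts$lcx <- pts$lcx * exp(rnorm(6, 0, 0.1))
  ours <- fit_decay(pts)
  nls_fit <- minpack.lm::nlsLM(
    lcx ~ (y0 - plateau) * exp(-k * pct_mp) + plateau,
    data = pts, start = list(y0 = 300, plateau = 30, k = 0.05),
    lower = c(0, 0, 1e-8), control = minpack.lm::nls.lm.control(maxiter = 500))
  expect_equal(ours$sse, sum(residuals(nls_fit)^2), tolerance = 1e-6)
  expect_equal(ours$k, coef(nls_fit)[["k"]], tolerance = 1e-3)
})

test_that("solve_noe_pct matches its closed form and bisection", {
  f <- fit_decay(decay_points(400, 50, 0.05))
  expect_equal(solve_noe_pct(f, 120), 20 * log(5), tolerance = 1e-6)
  expect_equal(solve_noe_pct(f, f$y0), 0)          # curve starts at threshold
  expect_equal(solve_noe_pct(f, 500), 0)
  expect_equal(solve_noe_pct(f, 50), Inf)          # never reaches the NOEC
  expect_equal(solve_noe_pct(f, 10), Inf)

  # property: agreement with bisection to 1e-8 over random valid draws
  set.seed(31)
  for (i in 1:50) {
    y0 <- runif(1, 50, 1000)
    plateau <- runif(1, 0, y0 * 0.8)
    k <- runif(1, 0.01, 0.5)
    noec <- runif(1, plateau + 1e-3 * (y0 - plateau),
                  y0 - 1e-3 * (y0 - plateau))
    fit <- structure(list(y0 = y0, plateau = plateau, k = k,
                          degenerate = FALSE), class = "decay_fit")
    x_closed <- solve_noe_pct(fit, noec)
    x_bis <- uniroot(function(x) (y0 - plateau) * exp(-k * x) + plateau - noec,
                     interval = c(0, 1e4), tol = 1e-12)$root
    expect_equal(x_closed, x_bis, tolerance = 1e-8)
  }
})

test_that("solve_noe_pct rejects non-decaying fits", {
  flat <- structure(list(y0 = 100, plateau = 100, k = NA_real_,
                         degenerate = TRUE), class = "decay_fit")
  expect_error(solve_noe_pct(flat, 50),
               class = "mpratio_degenerate_decay_error")
})

test_that("derive_thresholds anchors the NOEC on the 0% reference", {
  lc50s <- (400 - 50) * exp(-0.05 * c(0, 20, 40, 60, 80, 100)) + 50
  fits <- purrr::map2(c(0, 20, 40, 60, 80, 100), lc50s, function(p, l) {
    make_fit(p, l, l * 0.8, l / 0.8)
  })
  thr <- derive_thresholds(fits, x_level = 10)
  expect_equal(thr$noec, fits[[1]]$lc10[["lower"]])
  expect_equal(predict(thr$decay, thr$noe_pct_mp), thr$noec,
               tolerance = 1e-6)
  # LC10 decay of a hill-1 family is the LC50 decay scaled by 1/9
  expect_equal(thr$decay$y0, 400 / 9, tolerance = 1e-3)
  expect_equal(thr$decay$k, 0.05, tolerance = 1e-3)

  expect_error(derive_thresholds(fits[-1]),
               class = "mpratio_missing_reference")
})

test_that("constant LCx across ratios gives the no-threshold sentinel", {
  fits <- purrr::map(c(0, 50, 100), function(p) make_fit(p, 200, 150, 270))
  thr <- derive_thresholds(fits, x_level = 10)
  expect_equal(thr$noe_pct_mp, Inf)
  expect_equal(classify_scenario(fits), "A")
})

test_that("a stricter NOEC never loosens the %MP threshold", {
  f <- fit_decay(decay_points(400, 50, 0.05))
  noecs <- seq(390, 60, by = -10)
  noes <- vapply(noecs, function(n) solve_noe_pct(f, n), numeric(1))
  expect_true(all(diff(noes) >= 0))
})

test_that("thresholds are equivariant to rescaling concentrations", {
  pts <- decay_points(400, 50, 0.05)
  set.seed(5)
  pts$lcx <- pts$lcx * exp(rnorm(6, 0, 0.05))
  f1 <- fit_decay(pts)
  noec <- 100
  for (c_mult in c(0.2, 30)) {
    pts2 <- pts
    pts2$lcx <- pts$lcx * c_mult
    f2 <- fit_decay(pts2)
    expect_equal(f2$y0, f1$y0 * c_mult, tolerance = 1e-5)
    expect_equal(f2$plateau, f1$plateau * c_mult, tolerance = 1e-4)
    expect_equal(solve_noe_pct(f2, noec * c_mult),
                 solve_noe_pct(f1, noec), tolerance = 1e-5)
  }
})

test_that("scenario classification separates A, B and C profiles", {
  ref <- make_fit(0, 400, 300, 520)
  expect_equal(classify_scenario(list(ref, make_fit(100, 60, 40, 80))), "B")
  expect_equal(classify_scenario(list(ref, make_fit(100, 400, 300, 520))), "A")
  expect_equal(classify_scenario(list(ref, make_fit(100, 900, 700, 1100))),
               "C")
  # the verdict uses the extreme ratios regardless of list order
  fits <- list(make_fit(50, 200, 150, 260), make_fit(100, 60, 40, 80), ref)
  expect_equal(classify_scenario(fits), "B")
})
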