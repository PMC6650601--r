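# Shared fixture builders. All fixtures are constructed in code.

# A minimal dose_response_fit with prescribed LC50 interval; the covariance
# is back-derived from the interval width so lcx_ci_vec stays consistent.
make_fit <- function(pct_mp, lc50, lower, upper, hill = 1, df = 20,
                     conf_level = 0.95) {
  se <- (log10(upper) - log10(lower)) / (2 * qt(1 - (1 - conf_level) / 2, df))
  cov2 <- matrix(c(se^2, 0, 0, 0), 2, 2,
                 dimnames = list(c("log10_lc50", "hill"),
                                 c("log10_lc50", "hill")))
  fit <- structure(
    list(model = list(log10_lc50 = log10(lc50), hill = hill, bottom = 0,
                      top = 1, hill_fixed = TRUE),
         r_squared = NA_real_, n_obs = df + 1L, df = df, sse = NA_real_,
         cov = cov2, conf_level = conf_level, pct_mp = pct_mp,
         ss_used = c(10, 100, 1000), engine = "ols", subsampled = FALSE),
    class = "dose_response_fit"
  )
  # carry the prescribed interval exactly; LC10 scales by (1/9)^(1/hill)
  fit$lc50 <- c(estimate = lc50, lower = lower, upper = upper)
  fit$lc10 <- fit$lc50 * (1 / 9)^(1 / hill)
  fit
}

# Replicate-level points simulated from the constrained logistic model.
simulate_series <- function(log10_lc50, hill = 1,
                            conc = c(10, 31.6, 100, 316, 1000),
                            reps = 5, n = 10, seed = 1) {
  p <- 1 / (1 + (10^log10_lc50 / rep(conc, each = reps))^hill)
  deaths <- mpratio:::with_stream(seed, rbinom(length(p), n, p))
  tibble::tibble(ss_conc = rep(conc, each = reps), n_exposed = n,
                 n_immobilized = deaths)
}

# A tiny valid dataset: one control tube plus one 0%-MP series.
tiny_dataset <- function() {
  bioassay_dataset(tibble::tibble(
    ss_conc = c(0, 10, 100, 1000, 10000),
    pct_mp = 0,
    n_exposed = 10,
    n_immobilized = c(0, 1, 4, 8, 10),
    run_id = "run1"
  ))
}

write_tiny_csv <- function(path, rows) {
  header <- "ss_conc_mg_per_L,pct_mp,n_exposed,n_immobilized,run_id,is_control"
  writeLines(c(header, rows), path)
  path
}
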