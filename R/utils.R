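# Internal helpers: deterministic seed streams and input checks.

# Mix integers into a 31-bit seed so each (iteration, cell) pair gets its own
# reproducible stream, independent of execution order. Plain modular
# arithmetic in double precision (exact below 2^53).
derive_seed <- function(master, ...) {
  parts <- c(...)
  h <- as.double(master %% 2147483647)
  for (p in parts) {
    h <- (h * 48271 + as.double(p) + 11) %% 2147483647
  }
  as.integer(h)
}

# Deterministic stream key for a design cell identified by its values, not
# its position, so adding cells elsewhere does not perturb existing draws.
cell_seed <- function(master, pct_mp, ss_conc, tag = 0L) {
  key <- sprintf("%.6f|%.6g|%d", pct_mp, ss_conc, as.integer(tag))
  h <- 7.0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483629
  derive_seed(master, h)
}

# Run expr with a local RNG state seeded from `seed`; restores global state.
with_stream <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}
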