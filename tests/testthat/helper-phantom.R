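# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# A small, fast phantom spec for unit tests (the acceptance suite uses the
# spec-mandated 64^3 configuration instead).
small_spec <- function(seed = 42, ...) {
  phantom_spec(shape = c(32, 32, 20), seed = seed, ...)
}

small_cohort <- function() {
  cached_fixture("small_cohort", generate_cohort(small_spec(), 3))
}

noiseless_cohort <- function() {
  cached_fixture("noiseless_cohort",
                 generate_cohort(small_spec(ct_noise_sd = 0,
                                            excluded_fraction = 0), 3))
}

# Random bin-grid sample set on [0, axis_max]^2.
random_samples <- function(n, axis_max = c(100, 200), seed = 1) {
  withr_seed <- function(s, code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv(), inherits = FALSE)
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s)
    force(code)
  }
  withr_seed(seed, data.frame(s1 = runif(n, 0, axis_max[1]),
                              s2 = runif(n, 0, axis_max[2]),
                              ct = rnorm(n, 100, 50)))
}

# Independent brute-force imputation oracle: all-pairs distance scan with the
# tie rule (average value / average weight of all minimal-distance bins).
impute_oracle <- function(grid, fraction = 0.1) {
  n <- grid$nbin
  out <- grid
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (is.finite(grid$mean_ct[i, j]) && grid$weights[i, j] > 0) next
      best <- Inf
      vals <- c()
      wts <- c()
      for (a in seq_len(n)) {
        for (b in seq_len(n)) {
          if (!is.finite(grid$mean_ct[a, b]) || grid$weights[a, b] <= 0) next
          d2 <- (a - i)^2 + (b - j)^2
          if (d2 < best) {
            best <- d2
            vals <- grid$mean_ct[a, b]
            wts <- grid$weights[a, b]
          } else if (d2 == best) {
            vals <- c(vals, grid$mean_ct[a, b])
            wts <- c(wts, grid$weights[a, b])
          }
        }
      }
      out$mean_ct[i, j] <- mean(vals)
      out$weights[i, j] <- fraction * mean(wts)
    }
  }
  out
}
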