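vol3 <- function(values, shape = NULL) {
  if (is.null(shape)) shape <- c(length(values), 1, 1)
  image_volume(array(values, shape), modality = "CT")
}

test_that("mae and rms_diff follow their definitions and the mask contract", {
  m <- array(TRUE, c(2, 1, 1))
  expect_equal(mae(vol3(c(0, 100)), vol3(c(10, 90)), m), 10)
  expect_equal(mae(vol3(c(5, 5)), vol3(c(5, 5)), m), 0)
  expect_equal(rms_diff(vol3(c(10, 20)), vol3(c(0, 0)), m), sqrt(250))
  expect_equal(rms_diff(vol3(c(1, 1)), vol3(c(1, 1)), m), 0)

  # sigma >= MAE on the same mask
  p <- vol3(c(0, 20)); r <- vol3(c(0, 0))
  expect_equal(mae(p, r, m), 10)
  expect_equal(rms_diff(p, r, m), sqrt(200))
  expect_gte(rms_diff(p, r, m), mae(p, r, m))

  # masked-out gross error is invisible
  p2 <- vol3(c(0, 1000, 3)); r2 <- vol3(c(0, 0, 3))
  m2 <- array(c(TRUE, FALSE, TRUE), c(3, 1, 1))
  expect_equal(mae(p2, r2, m2), 0)
  expect_error(mae(p2, r2, array(FALSE, c(3, 1, 1))), "empty")
})

test_that("fit_errors computes count-weighted deviations over filled bins", {
  # two filled bins, counts {1, 3}, |deviations| {4, 0}
  s <- data.frame(s1 = c(rep(0.5, 1), rep(5.5, 3)), s2 = rep(0.5, 4),
                  ct = c(50, 80, 80, 80))
  g <- build_bin_grid(s, 10, c(10, 10))
  model <- structure(list(degree = 0L,
                          exponents = pseudoCT:::poly_exponents(0),
                          coefficients = 0,  # placeholder, replaced below
                          input_scale = c(10, 10), clamp = c(-1000, 2000)),
                     class = "polynomial_model")
  # model predicting 54 at the first bin and 80 at the second is easiest to
  # realize as a plane; use degree 1 in s1
  model$exponents <- pseudoCT:::poly_exponents(1)
  # pred(c) = a + b*c1; c1 centers are 0.05 and 0.55 (scaled); solve
  b <- (80 - 54) / 0.5
  a <- 54 - b * 0.05
  # exponent order is (0,0), (0,1), (1,0): the slope sits on the s1 monomial
  model$coefficients <- c(a, 0, b)
  fe <- fit_errors(g, model)
  expect_equal(fe[["mae_fit"]], (4 * 1 + 0 * 3) / 4)
  expect_equal(fe[["sigma_fit"]], sqrt(16 / 4))

  # exact interpolation gives (0, 0)
  interp <- interpolation_model(fill_empty_bins(g))
  fe0 <- fit_errors(g, interp)
  expect_equal(unname(fe0), c(0, 0))

  # brute-force weighted loop oracle on a random grid
  set.seed(11)
  sr <- random_samples(400, seed = 11)
  gr <- build_bin_grid(sr, 8, c(100, 200))
  mr <- fit_polynomial(fill_empty_bins(gr), 2)
  fer <- fit_errors(gr, mr)
  tot <- 0; sa <- 0; sq <- 0
  for (i in 1:8) {
    for (j in 1:8) {
      n <- gr$counts[i, j]
      if (n == 0) next
      pred <- evaluate_model(mr, bin_centers(gr, 1)[i], bin_centers(gr, 2)[j])
      dev <- gr$mean_ct[i, j] - pred
      tot <- tot + n; sa <- sa + abs(dev) * n; sq <- sq + dev^2 * n
    }
  }
  expect_equal(fer[["mae_fit"]], sa / tot)
  expect_equal(fer[["sigma_fit"]], sqrt(sq / tot))
})

test_that("spread_errors measures intra-bin CT spread", {
  s <- data.frame(s1 = c(1, 1), s2 = c(1, 1), ct = c(10, 30))
  g <- build_bin_grid(s, 5, c(10, 10))
  se <- spread_errors(s$s1, s$s2, s$ct, g)
  expect_equal(se[["mae_rct"]], 10)
  expect_equal(se[["sigma_rct"]], 10)

  # one voxel per bin -> zero spread
  s1v <- c(1, 3, 5, 7); s2v <- c(1, 3, 5, 7)
  g1 <- build_bin_grid(data.frame(s1 = s1v, s2 = s2v, ct = c(5, 6, 7, 8)), 5, c(10, 10))
  se1 <- spread_errors(s1v, s2v, c(5, 6, 7, 8), g1)
  expect_equal(unname(se1), c(0, 0))

  # brute-force group-by oracle
  sr <- random_samples(600, seed = 3)
  gr <- build_bin_grid(sr, 7, c(100, 200))
  ser <- spread_errors(sr$s1, sr$s2, sr$ct, gr)
  key <- paste(bin_index(sr$s1, 100, 7), bin_index(sr$s2, 200, 7))
  devs <- unlist(lapply(split(sr$ct, key), function(v) v - mean(v)))
  expect_equal(ser[["mae_rct"]], mean(abs(devs)))
  expect_equal(ser[["sigma_rct"]], sqrt(mean(devs^2)))
})

test_that("decomposition_check handles identities and degenerate input", {
  expect_equal(decomposition_check(5, 3, 4), 0)
  expect_equal(decomposition_check(0, 0, 0), 0)
  expect_error(decomposition_check(0, 1, 0), "zero")
  expect_equal(decomposition_check(10, 6, 8), 0)
  expect_gt(decomposition_check(10, 3, 4), 0)
})

test_that("weighted region MAEs sum to the overall MAE", {
  t1 <- weighted_region_table(c(a = 100, b = 20), c(a = 10, b = 90))
  expect_equal(t1$weighted_mae, c(10, 18))
  expect_equal(attr(t1, "overall_mae"), 28)

  t2 <- weighted_region_table(c(only = 55), c(only = 123))
  expect_equal(t2$weighted_mae, 55)

  # random three-region volume: accounting identity vs a direct computation
  set.seed(13)
  shape <- c(10, 10, 5)
  lab <- array(sample(1:3, prod(shape), replace = TRUE), shape)
  p <- image_volume(array(rnorm(prod(shape), 0, 50), shape), modality = "PCT")
  r <- image_volume(array(rnorm(prod(shape), 0, 50), shape), modality = "CT")
  raw <- sapply(1:3, function(k) mae(p, r, lab == k))
  cnt <- sapply(1:3, function(k) sum(lab == k))
  tab <- weighted_region_table(setNames(raw, c("BONY", "SOFT", "MIXED")),
                               setNames(cnt, c("BONY", "SOFT", "MIXED")))
  overall <- mae(p, r, array(TRUE, shape))
  expect_equal(attr(tab, "overall_mae"), overall, tolerance = 1e-12)
})

test_that("dose passing rate is exact, inclusive at the 2% boundary", {
  shape <- c(10, 10, 2)
  ref <- 56
  base <- image_volume(array(50, shape), modality = "DOSE")
  m <- array(TRUE, shape)

  expect_equal(dose_passing_rate(base, base, m, reference = ref)$passing_rate, 100)

  # half the voxels off by 5% of reference
  off <- base
  half <- seq_len(prod(shape)) <= prod(shape) / 2
  off$data[half] <- off$data[half] + 0.05 * ref
  expect_equal(dose_passing_rate(off, base, m, reference = ref)$passing_rate, 50)

  # exactly 2% of reference passes (inclusive); integer doses with a
  # reference of 100 keep the comparison binary-exact
  edge <- base
  edge$data[1] <- edge$data[1] + 2
  expect_equal(dose_passing_rate(edge, base, m, reference = 100)$passing_rate, 100)
  over <- base
  over$data[1] <- over$data[1] + 2.1
  expect_lt(dose_passing_rate(over, base, m, reference = 100)$passing_rate, 100)

  # local normalization mode
  expect_equal(dose_passing_rate(off, base, m, local = TRUE)$passing_rate, 50)
  expect_error(dose_passing_rate(base, base, m, reference = -1), "positive")
  expect_error(dose_passing_rate(base, base, array(FALSE, shape), reference = ref),
               "empty")
})

test_that("evaluate_pct assembles a consistent region report", {
  cohort <- small_cohort()
  tr <- run_train(cohort[-1], run_config(nbin = 20, degree = 3))
  pred <- run_predict(tr, cohort[[1]])
  rep <- evaluate_pct(pred$pct, pred$normalized$ct, pred$normalized$labels,
                      models = tr$models, mr1 = pred$normalized$mr1,
                      mr2 = pred$normalized$mr2)
  tab <- rep$table
  regions <- tab[tab$scope != "overall", ]
  overall <- tab[tab$scope == "overall", ]
  expect_equal(sum(regions$weighted_mae), overall$mae, tolerance = 1e-9)
  expect_equal(sum(regions$n), overall$n)
  expect_true(all(tab$sigma >= tab$mae - 1e-12))
  expect_true(all(tab$sigma_fit >= tab$mae_fit - 1e-12))
  expect_true(all(tab$sigma_rct >= tab$mae_rct - 1e-12))

  # report writing round-trips through CSV
  p <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, p, cycle = 1)
  back <- read.csv(p)
  expect_equal(back$mae, tab$mae, tolerance = 1e-6)
  expect_equal(back$cycle, rep(1, nrow(tab)))
})
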