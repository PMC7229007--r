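grid_from_fun <- function(nbin, axis_max, f, weights = NULL) {
  # build a fully-filled grid whose means are f(center1, center2)
  g <- build_bin_grid(data.frame(s1 = axis_max[1] / 2, s2 = axis_max[2] / 2,
                                 ct = 0), nbin, axis_max)
  c1 <- bin_centers(g, 1)
  c2 <- bin_centers(g, 2)
  g$mean_ct <- outer(c1, c2, f)
  g$counts <- matrix(1L, nbin, nbin)
  g$filled <- matrix(TRUE, nbin, nbin)
  g$weights <- if (is.null(weights)) matrix(1, nbin, nbin) else weights
  g
}

test_that("constant and planar surfaces are fitted exactly", {
  for (degree in c(0, 3, 8)) {
    g <- grid_from_fun(12, c(100, 300), function(a, b) 40 + 0 * a)
    m <- fit_polynomial(g, degree)
    s <- expand.grid(s1 = seq(0, 100, length.out = 7),
                     s2 = seq(0, 300, length.out = 7))
    expect_equal(evaluate_model(m, s$s1, s$s2), rep(40, nrow(s)),
                 tolerance = 1e-6)
  }
  gp <- grid_from_fun(12, c(100, 300),
                      function(a, b) 100 * (a / 100) + 50 * (b / 300))
  mp <- fit_polynomial(gp, 1)
  res <- fit_errors(gp, mp)
  expect_lt(res[["mae_fit"]], 1e-6)
})

test_that("weighted fit matches the normal-equations oracle", {
  set.seed(4)
  nbin <- 20
  am <- c(50, 80)
  truth <- function(a, b) 30 + 120 * (a / 50) - 60 * (b / 80) +
    45 * (a / 50)^2 - 25 * (a / 50) * (b / 80) + 10 * (b / 80)^2
  w <- matrix(sample(1:50, nbin^2, replace = TRUE), nbin, nbin)
  g <- grid_from_fun(nbin, am, truth, weights = w)
  m <- fit_polynomial(g, 2)

  # oracle: explicit weighted normal equations, solved independently
  ex <- pseudoCT:::poly_exponents(2)
  c1 <- bin_centers(g, 1) / am[1]
  c2 <- bin_centers(g, 2) / am[2]
  s1 <- rep(c1, nbin); s2 <- rep(c2, each = nbin)
  X <- sapply(seq_len(nrow(ex)), function(k) s1^ex[k, 1] * s2^ex[k, 2])
  W <- as.vector(w)
  beta <- solve(crossprod(X, X * W), crossprod(X, W * as.vector(g$mean_ct)))
  fitted_oracle <- as.vector(X %*% beta)
  fitted_pkg <- evaluate_model(m, s1 * am[1], s2 * am[2])
  expect_equal(fitted_pkg, fitted_oracle, tolerance = 1e-8)
})

test_that("fit residual is non-increasing in degree", {
  set.seed(8)
  g <- grid_from_fun(15, c(10, 10),
                     function(a, b) 100 * sin(a / 3) * cos(b / 4))
  g$weights <- matrix(runif(225, 0.5, 5), 15, 15)
  g$counts <- matrix(1L, 15, 15)
  prev <- Inf
  for (d in 0:6) {
    m <- fit_polynomial(g, d)
    res <- fit_errors(g, m)[["sigma_fit"]]
    expect_lte(res, prev + 1e-9)
    prev <- res
  }
})

test_that("predictions clamp to [-1000, 2000] HU", {
  g_hi <- grid_from_fun(6, c(10, 10), function(a, b) 2500 + 0 * a)
  expect_equal(evaluate_model(fit_polynomial(g_hi, 0), 5, 5), 2000)
  g_lo <- grid_from_fun(6, c(10, 10), function(a, b) -1500 + 0 * a)
  expect_equal(evaluate_model(fit_polynomial(g_lo, 0), 5, 5), -1000)
  expect_equal(evaluate_model(interpolation_model(g_hi), 5, 5), 2000)
})

test_that("bilinear interpolation reproduces nodes and stays inside the hull", {
  set.seed(6)
  g <- grid_from_fun(8, c(80, 40), function(a, b) 0 * a)
  g$mean_ct <- matrix(rnorm(64, 100, 200), 8, 8)
  m <- interpolation_model(g)
  c1 <- bin_centers(g, 1)
  c2 <- bin_centers(g, 2)
  for (i in c(1, 4, 8)) {
    for (j in c(1, 5, 8)) {
      expect_equal(evaluate_model(m, c1[i], c2[j]), g$mean_ct[i, j])
    }
  }
  # constant extrapolation beyond the lattice hull
  expect_equal(evaluate_model(m, 0, 0), g$mean_ct[1, 1])
  expect_equal(evaluate_model(m, 1000, 1000), g$mean_ct[8, 8])
  # interior queries stay within the four surrounding node values
  q1 <- runif(50, c1[1], c1[8]); q2 <- runif(50, c2[1], c2[8])
  v <- evaluate_model(m, q1, q2)
  expect_true(all(v >= min(g$mean_ct) - 1e-9 & v <= max(g$mean_ct) + 1e-9))
})

test_that("train_region_models pools regions and honors the excluded overlay", {
  shape <- c(12, 12, 6)
  labels <- region_labels(array(REGION_CODES[["SOFT"]], shape))
  mk_vol <- function(x, mod) image_volume(array(x, shape), modality = mod)
  set.seed(2)
  p <- list(id = "a",
            mr1 = image_volume(array(runif(prod(shape), 10, 100), shape), modality = "MR1"),
            mr2 = image_volume(array(runif(prod(shape), 10, 100), shape), modality = "MR2"),
            ct = mk_vol(40, "CT"), labels = labels)
  set <- train_region_models(list(p), nbin = 8, degree = 2)
  expect_named(set$models, "SOFT")
  expect_equal(evaluate_model(set$models$SOFT, 50, 50), 40, tolerance = 1e-6)

  # excluded voxels with corrupted CT leave the fit untouched
  excl <- array(runif(prod(shape)) < 0.5, shape)
  ct_bad <- p$ct
  ct_bad$data[excl] <- 1900
  p_bad <- p; p_bad$ct <- ct_bad; p_bad$labels <- region_labels(labels$labels, excl)
  p_clean <- p; p_clean$labels <- region_labels(labels$labels, excl)
  m_bad <- train_region_models(list(p_bad), nbin = 8, degree = 2,
                               axis_max = c(100, 100))
  m_clean <- train_region_models(list(p_clean), nbin = 8, degree = 2,
                                 axis_max = c(100, 100))
  expect_equal(m_bad$models$SOFT$coefficients, m_clean$models$SOFT$coefficients,
               tolerance = 1e-12)
  # ... but including them (use_excluded) changes the model
  m_incl <- train_region_models(list(p_bad), nbin = 8, degree = 2,
                                axis_max = c(100, 100), use_excluded = TRUE)
  expect_gt(max(abs(m_incl$models$SOFT$coefficients -
                      m_bad$models$SOFT$coefficients)), 1)

  # duplicating a patient doubles counts but leaves the fit unchanged
  m_two <- train_region_models(list(p, p), nbin = 8, degree = 2,
                               axis_max = c(100, 100))
  m_one <- train_region_models(list(p), nbin = 8, degree = 2,
                               axis_max = c(100, 100))
  expect_equal(m_two$models$SOFT$coefficients, m_one$models$SOFT$coefficients,
               tolerance = 1e-8)

  expect_error(train_region_models(list()), "no training patients")
})

test_that("predict_pct matches voxel-wise evaluation and fills air", {
  ph <- generate_phantom(small_spec(), 2)
  cohort <- list(generate_phantom(small_spec(), 1), ph)
  set <- train_region_models(cohort, nbin = 20, degree = 3)
  pct <- predict_pct(set, ph$mr1, ph$mr2, ph$labels)
  expect_s3_class(pct, "image_volume")
  expect_identical(pct$modality, "PCT")
  expect_true(all(pct$data >= -1000 & pct$data <= 2000))
  outside <- ph$labels$labels == REGION_CODES[["OUTSIDE"]]
  expect_true(all(pct$data[outside] == -1000))

  # loop oracle over a voxel subset
  idx <- which(!outside)[seq(1, sum(!outside), by = 211)]
  for (k in idx) {
    rn <- names(REGION_CODES)[match(ph$labels$labels[k], REGION_CODES)]
    expect_equal(pct$data[k],
                 evaluate_model(set$models[[rn]],
                                max(ph$mr1$data[k], 0), max(ph$mr2$data[k], 0)))
  }

  # all-outside labels give a -1000 volume
  lab0 <- region_labels(array(0L, dim(ph$labels$labels)))
  pct0 <- predict_pct(set, ph$mr1, ph$mr2, lab0)
  expect_true(all(pct0$data == -1000))

  # a label map with a region the model set lacks fails loudly
  soft_only <- train_region_models(list(local({
    q <- ph
    q$labels <- region_labels(array(REGION_CODES[["SOFT"]], dim(ph$labels$labels)))
    q
  })), nbin = 10, degree = 1)
  expect_error(predict_pct(soft_only, ph$mr1, ph$mr2, ph$labels), "BONY")
})

test_that("polynomial and interpolation models agree on smooth noisy data", {
  # mirrors the near-identical whole-volume MAE of the two model types: on a
  # smooth mapping with dense bins the surfaces coincide where the data live
  cohort <- small_cohort()
  cfg_p <- run_config(nbin = 25, degree = 4)
  cfg_i <- run_config(nbin = 25, degree = 4, model_type = "interpolation")
  t_p <- run_train(cohort, cfg_p)
  t_i <- run_train(cohort, cfg_i)
  target <- cohort[[1]]
  body <- target$labels$labels != 0 & !target$labels$excluded
  mae_p <- mae(run_predict(t_p, target)$pct, target$ct, body)
  mae_i <- mae(run_predict(t_i, target)$pct, target$ct, body)
  expect_lt(abs(mae_p - mae_i) / max(mae_p, mae_i), 0.05)
})

test_that("model sets round trip through their text persistence", {
  cohort <- small_cohort()
  for (type in c("polynomial", "interpolation")) {
    set <- train_region_models(cohort, nbin = 12, degree = 3, model_type = type)
    dir <- withr::local_tempdir()
    write_region_models(set, dir)
    set2 <- read_region_models(dir)
    s1 <- runif(100, 0, set$axis_max[1])
    s2 <- runif(100, 0, set$axis_max[2])
    for (rn in names(set$models)) {
      expect_equal(evaluate_model(set2$models[[rn]], s1, s2),
                   evaluate_model(set$models[[rn]], s1, s2), tolerance = 1e-12)
    }
  }
  expect_error(read_region_models(withr::local_tempdir()), "models.json")
})
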