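HU_CLAMP <- c(-1000, 2000)

# Monomial exponent table for a total-degree-<=n bivariate polynomial,
# ordered by ascending total degree, then ascending power of the first
# variable (a stable order for both accumulation and persistence).
poly_exponents <- function(degree) {
  stopifnot(degree >= 0)
  g <- expand.grid(i1 = 0:degree, i2 = 0:degree)
  g <- g[g$i1 + g$i2 <= degree, ]
  g <- g[order(g$i1 + g$i2, g$i1), ]
  rownames(g) <- NULL
  as.matrix(g)
}

# Design matrix of scaled monomials. s1, s2 are already in [0, 1].
poly_design <- function(s1, s2, exponents) {
  degree <- max(exponents)
  p1 <- outer(s1, 0:degree, "^")
  p2 <- outer(s2, 0:degree, "^")
  p1[, exponents[, 1] + 1L, drop = FALSE] * p2[, exponents[, 2] + 1L, drop = FALSE]
}

#' Fit the per-region bivariate polynomial to a bin grid
#'
#' Weighted least squares of the per-bin mean CT numbers against a
#' total-degree-`degree` polynomial in the two (scaled) bin-center
#' intensities, with the bin weights (counts on filled bins, a fraction of the
#' donor count on imputed bins) as regression weights. Intensities are mapped
#' to `[0, 1]` by `axis_max` before the monomials are built: raw intensities
#' in the tens of thousands raised to the 30th power would overflow. The
#' system is solved by SVD with a relative singular-value cutoff of 1e-10,
#' which keeps the severely ill-conditioned high-degree bases deterministic.
#'
#' @param grid An imputed `bin_grid` (see [fill_empty_bins()]).
#' @param degree Total polynomial degree `n` (default 30, the operating
#'   point of the method; tests use far smaller values).
#' @return An object of class `polynomial_model`: `degree`, `exponents`,
#'   `coefficients`, `input_scale` (= `axis_max`), `clamp`.
#' @export
fit_polynomial <- function(grid, degree = 30) {
  stopifnot(inherits(grid, "bin_grid"), degree >= 0)
  y <- as.vector(grid$mean_ct)
  w <- as.vector(grid$weights)
  use <- w > 0
  if (!any(use)) stop("all regression weights are zero", call. = FALSE)
  if (any(!is.finite(y[use]))) {
    stop("non-finite bin means; run fill_empty_bins() first", call. = FALSE)
  }
  c1 <- bin_centers(grid, 1L) / grid$axis_max[1]
  c2 <- bin_centers(grid, 2L) / grid$axis_max[2]
  s1 <- rep(c1, grid$nbin)[use]
  s2 <- rep(c2, each = grid$nbin)[use]
  ex <- poly_exponents(degree)
  X <- poly_design(s1, s2, ex)
  sw <- sqrt(w[use])
  sv <- svd(X * sw)
  keep <- sv$d > 1e-10 * sv$d[1]
  coef <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% (y[use] * sw)) / sv$d[keep])
  structure(list(degree = as.integer(degree), exponents = ex,
                 coefficients = as.vector(coef),
                 input_scale = grid$axis_max, clamp = HU_CLAMP),
            class = "polynomial_model")
}

#' Build the bilinear-lookup alternative model
#'
#' Stores the imputed bin grid; predictions are bilinear interpolations of the
#' per-bin mean CT numbers over the four surrounding bin centers, with
#' constant extrapolation outside the bin-center lattice.
#'
#' @param grid An imputed `bin_grid`.
#' @return An object of class `interpolation_model`.
#' @export
interpolation_model <- function(grid) {
  stopifnot(inherits(grid, "bin_grid"))
  if (any(!is.finite(grid$mean_ct))) {
    stop("lattice has non-finite nodes; run fill_empty_bins() first", call. = FALSE)
  }
  structure(list(grid = grid, input_scale = grid$axis_max, clamp = HU_CLAMP),
            class = "interpolation_model")
}

#' Evaluate a prediction model at (MR1, MR2) intensities
#'
#' Vectorized over the inputs. Inputs are clamped to the trained intensity
#' range, and the output is clamped to `[-1000, 2000]` HU.
#'
#' @param model A `polynomial_model` or `interpolation_model`.
#' @param s1,s2 Non-negative normalized intensities (equal length).
#' @return Numeric vector of predicted CT numbers (HU).
#' @export
evaluate_model <- function(model, s1, s2) UseMethod("evaluate_model")

#' @export
evaluate_model.polynomial_model <- function(model, s1, s2) {
  if (any(s1 < 0) || any(s2 < 0)) stop("intensities must be >= 0", call. = FALSE)
  u <- pmin(s1 / model$input_scale[1], 1)
  v <- pmin(s2 / model$input_scale[2], 1)
  raw <- as.vector(poly_design(u, v, model$exponents) %*% model$coefficients)
  pmin(pmax(raw, model$clamp[1]), model$clamp[2])
}

#' @export
evaluate_model.interpolation_model <- function(model, s1, s2) {
  if (any(s1 < 0) || any(s2 < 0)) stop("intensities must be >= 0", call. = FALSE)
  g <- model$grid
  n <- g$nbin
  interp_axis <- function(q, axis) {
    w <- g$axis_max[axis] / n
    u <- (pmin(pmax(q, 0.5 * w), (n - 0.5) * w) - 0.5 * w) / w  # in [0, n-1]
    i0 <- pmin(pmax(floor(u), 0), max(n - 2, 0))
    list(i = as.integer(i0) + 1L, f = if (n > 1) u - i0 else rep(0, length(u)))
  }
  a1 <- interp_axis(s1, 1L)
  a2 <- interp_axis(s2, 2L)
  i1 <- a1$i; f1 <- a1$f
  i2 <- a2$i; f2 <- a2$f
  ip <- pmin(i1 + 1L, n)
  jp <- pmin(i2 + 1L, n)
  M <- g$mean_ct
  raw <- (1 - f1) * (1 - f2) * M[cbind(i1, i2)] +
    f1 * (1 - f2) * M[cbind(ip, i2)] +
    (1 - f1) * f2 * M[cbind(i1, jp)] +
    f1 * f2 * M[cbind(ip, jp)]
  pmin(pmax(raw, model$clamp[1]), model$clamp[2])
}

# -- training over a cohort ---------------------------------------------------

zero_channel <- function(vals, sequences, which_seq) {
  if (sequences == "both" || sequences == which_seq) vals else rep(0, length(vals))
}

# Pool non-excluded body voxels of one region across patients.
pool_region_samples <- function(patients, code, use_excluded, sequences) {
  parts <- lapply(patients, function(p) {
    sel <- p$labels$labels == code
    if (!use_excluded) sel <- sel & !p$labels$excluded
    data.frame(s1 = zero_channel(pmax(p$mr1$data[sel], 0), sequences, "MR1"),
               s2 = zero_channel(pmax(p$mr2$data[sel], 0), sequences, "MR2"),
               ct = p$ct$data[sel])
  })
  do.call(rbind, parts)
}

#' Train per-region prediction models on a cohort
#'
#' For each region, pools all non-excluded body voxels across the (already
#' normalized) training patients, accumulates them on the bin grid, imputes
#' empty bins, and fits the configured model. With `segmentation = FALSE` all
#' body voxels are pooled into one whole-body model. With a single-sequence
#' configuration the unused channel is collapsed to a constant, so the
#' polynomial degenerates to one variable.
#'
#' @param patients List of patient datasets; each a list with [image_volume()]
#'   elements `mr1`, `mr2`, `ct` and a [region_labels()] element `labels`, all
#'   on the same grid.
#' @param nbin Bins per intensity axis (default 200).
#' @param degree Polynomial degree (default 30).
#' @param model_type `"polynomial"` or `"interpolation"`.
#' @param axis_max Optional length-2 override of the intensity range; default
#'   is the per-axis maximum over the pooled training body voxels.
#' @param segmentation Train one model per region (`TRUE`) or a single
#'   whole-body model (`FALSE`).
#' @param use_excluded If `TRUE`, excluded-region voxels enter training (the
#'   ablation direction; default `FALSE`).
#' @param sequences `"both"`, `"MR1"` or `"MR2"`.
#' @param empty_weight_fraction Weight fraction for imputed bins.
#' @return An object of class `region_model_set`.
#' @export
train_region_models <- function(patients, nbin = 200, degree = 30,
                                model_type = c("polynomial", "interpolation"),
                                axis_max = NULL, segmentation = TRUE,
                                use_excluded = FALSE,
                                sequences = c("both", "MR1", "MR2"),
                                empty_weight_fraction = 0.1) {
  if (!length(patients)) stop("no training patients", call. = FALSE)
  model_type <- match.arg(model_type)
  sequences <- match.arg(sequences)
  region_codes <- if (segmentation) {
    # train only the regions that appear in the cohort's label maps; a region
    # that is present but ends up with zero usable voxels is an error below
    present <- Reduce(union, lapply(patients, function(p) unique(as.vector(p$labels$labels))))
    codes <- REGION_CODES[c("BONY", "SOFT", "MIXED")]
    codes[codes %in% present]
  } else {
    c(BODY = NA_integer_)  # sentinel: all body voxels
  }
  if (!length(region_codes)) stop("labels contain no body voxels", call. = FALSE)
  samples <- lapply(names(region_codes), function(rn) {
    code <- region_codes[[rn]]
    if (is.na(code)) {
      parts <- lapply(REGION_CODES[c("BONY", "SOFT", "MIXED")], function(cc) {
        pool_region_samples(patients, cc, use_excluded, sequences)
      })
      do.call(rbind, parts)
    } else {
      pool_region_samples(patients, code, use_excluded, sequences)
    }
  })
  names(samples) <- names(region_codes)
  empty <- vapply(samples, function(s) is.null(s) || nrow(s) == 0, logical(1))
  if (any(empty)) {
    stop("no training voxels for region(s): ",
         paste(names(samples)[empty], collapse = ", "), call. = FALSE)
  }
  if (is.null(axis_max)) {
    axis_max <- c(max(vapply(samples, function(s) max(s$s1), numeric(1))),
                  max(vapply(samples, function(s) max(s$s2), numeric(1))))
  }
  axis_max <- pmax(axis_max, .Machine$double.eps)
  models <- lapply(samples, function(s) {
    grid <- fill_empty_bins(build_bin_grid(s, nbin, axis_max),
                            empty_weight_fraction)
    if (model_type == "polynomial") fit_polynomial(grid, degree)
    else interpolation_model(grid)
  })
  structure(list(models = models, nbin = as.integer(nbin),
                 degree = as.integer(degree), model_type = model_type,
                 axis_max = as.double(axis_max), segmentation = segmentation,
                 sequences = sequences), class = "region_model_set")
}

#' Synthesize a pseudo-CT volume
#'
#' Maps every body voxel through its region's model (or the whole-body model
#' when the set was trained without segmentation); voxels outside the body are
#' set to exactly -1000 HU. The excluded overlay is ignored here: predictions
#' are made everywhere in the body.
#'
#' @param models A `region_model_set` from [train_region_models()].
#' @param mr1,mr2 Normalized MRI volumes ([image_volume()]).
#' @param labels A [region_labels()] object on the same grid.
#' @param mode `"per-voxel"` evaluates the model at each voxel's own
#'   intensities; `"per-bin"` snaps intensities to their bin centers first
#'   (the mode in which the variance decomposition is an exact identity).
#' @return A `PCT` [image_volume()], all values in `[-1000, 2000]`.
#' @export
predict_pct <- function(models, mr1, mr2, labels,
                        mode = c("per-voxel", "per-bin")) {
  stopifnot(inherits(models, "region_model_set"),
            inherits(labels, "region_labels"))
  mode <- match.arg(mode)
  if (!identical(dim(mr1$data), dim(labels$labels)) ||
      !identical(dim(mr2$data), dim(labels$labels))) {
    stop("volumes and labels must share one grid", call. = FALSE)
  }
  if (models$segmentation) {
    present <- intersect(unique(as.vector(labels$labels)),
                         REGION_CODES[c("BONY", "SOFT", "MIXED")])
    missing <- setdiff(names(REGION_CODES)[match(present, REGION_CODES)],
                       names(models$models))
    if (length(missing)) {
      stop("missing region model(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  out <- array(-1000, dim(labels$labels))
  for (rn in names(models$models)) {
    sel <- if (rn == "BODY") labels$labels != REGION_CODES[["OUTSIDE"]]
           else labels$labels == REGION_CODES[[rn]]
    if (!any(sel)) next
    s1 <- zero_channel(pmax(mr1$data[sel], 0), models$sequences, "MR1")
    s2 <- zero_channel(pmax(mr2$data[sel], 0), models$sequences, "MR2")
    if (mode == "per-bin") {
      w1 <- models$axis_max[1] / models$nbin
      w2 <- models$axis_max[2] / models$nbin
      s1 <- (bin_index(s1, models$axis_max[1], models$nbin) - 0.5) * w1
      s2 <- (bin_index(s2, models$axis_max[2], models$nbin) - 0.5) * w2
    }
    out[sel] <- evaluate_model(models$models[[rn]], s1, s2)
  }
  image_volume(out, spacing = mr1$spacing, modality = "PCT")
}

# -- persistence --------------------------------------------------------------

#' Write a region model set as plain structured text
#'
#' One file per region (`model_<REGION>.txt`) holding degree, input scale,
#' clamp and the coefficient list (polynomial), or the imputed bin grid
#' (interpolation), plus a `models.json` with shared metadata.
#'
#' @param models A `region_model_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_region_models <- function(models, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(nbin = models$nbin, degree = models$degree,
               model_type = models$model_type, axis_max = models$axis_max,
               segmentation = models$segmentation, sequences = models$sequences,
               regions = names(models$models))
  jsonlite::write_json(meta, file.path(dir, "models.json"), auto_unbox = TRUE,
                       digits = NA)
  for (rn in names(models$models)) {
    m <- models$models[[rn]]
    path <- file.path(dir, paste0("model_", rn, ".txt"))
    if (inherits(m, "polynomial_model")) {
      con <- file(path, "w")
      writeLines(c(sprintf("region %s", rn),
                   sprintf("degree %d", m$degree),
                   sprintf("input_scale %.17g %.17g", m$input_scale[1], m$input_scale[2]),
                   sprintf("clamp %g %g", m$clamp[1], m$clamp[2]),
                   "i1\ti2\tcoefficient",
                   sprintf("%d\t%d\t%.17g", m$exponents[, 1], m$exponents[, 2],
                           m$coefficients)), con)
      close(con)
    } else {
      write_bin_grid(m$grid, path)
    }
  }
  invisible(dir)
}

#' Read a region model set written by [write_region_models()]
#'
#' @param dir Directory holding `models.json` and the per-region files.
#' @return A `region_model_set`.
#' @export
read_region_models <- function(dir) {
  meta_path <- file.path(dir, "models.json")
  if (!file.exists(meta_path)) {
    stop("no model metadata at '", meta_path, "'", call. = FALSE)
  }
  meta <- jsonlite::fromJSON(meta_path)
  models <- lapply(meta$regions, function(rn) {
    path <- file.path(dir, paste0("model_", rn, ".txt"))
    if (!file.exists(path)) stop("missing model file '", path, "'", call. = FALSE)
    if (meta$model_type == "polynomial") {
      lines <- readLines(path, n = 4L)
      degree <- as.integer(strsplit(lines[2], " ")[[1]][2])
      input_scale <- as.double(strsplit(lines[3], " ")[[1]][2:3])
      clamp <- as.double(strsplit(lines[4], " ")[[1]][2:3])
      tab <- read.table(path, header = TRUE, sep = "\t", skip = 4L)
      ex <- poly_exponents(degree)
      # persisted in canonical order; verify before trusting
      stopifnot(identical(ex[, 1], as.integer(tab$i1)),
                identical(ex[, 2], as.integer(tab$i2)))
      structure(list(degree = degree, exponents = ex,
                     coefficients = tab$coefficient,
                     input_scale = input_scale, clamp = clamp),
                class = "polynomial_model")
    } else {
      interpolation_model(read_bin_grid(path))
    }
  })
  names(models) <- meta$regions
  structure(list(models = models, nbin = as.integer(meta$nbin),
                 degree = as.integer(meta$degree), model_type = meta$model_type,
                 axis_max = as.double(meta$axis_max),
                 segmentation = isTRUE(meta$segmentation),
                 sequences = meta$sequences), class = "region_model_set")
}
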