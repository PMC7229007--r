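#' Mean absolute error between two CT-valued volumes
#'
#' Voxel-wise mean of `|pCT - rCT|` over a mask; the caller's mask is expected
#' to exclude air and excluded-region voxels.
#'
#' @param pct,rct [image_volume()]s on the same grid.
#' @param mask Non-empty 3D logical array.
#' @return MAE in HU.
#' @export
mae <- function(pct, rct, mask) {
  check_pair(pct, rct, mask)
  mean(abs(pct$data[mask] - rct$data[mask]))
}

#' Root-mean-square difference between two CT-valued volumes
#'
#' @inheritParams mae
#' @return rms difference (sigma_pCT) in HU; always >= the MAE on the same
#'   mask.
#' @export
rms_diff <- function(pct, rct, mask) {
  check_pair(pct, rct, mask)
  sqrt(mean((pct$data[mask] - rct$data[mask])^2))
}

check_pair <- function(pct, rct, mask) {
  if (!identical(dim(pct$data), dim(rct$data)) ||
      !identical(dim(pct$data), dim(mask))) {
    stop("volumes and mask must share a shape", call. = FALSE)
  }
  if (!any(mask)) stop("empty evaluation mask", call. = FALSE)
  invisible(TRUE)
}

#' Goodness-of-fit errors of a model against its bin grid
#'
#' Count-weighted mean absolute and rms deviation between the per-bin mean CT
#' and the model evaluated at the bin centers, summed over filled bins with
#' their voxel counts: `MAE_fit = sum |mean_ct - pred| * N_ij / N`,
#' `sigma_fit = sqrt(sum (mean_ct - pred)^2 * N_ij / N)` with
#' `N = sum N_ij`.
#'
#' @param grid A `bin_grid` (imputation optional; only filled bins enter).
#' @param model A `polynomial_model` or `interpolation_model`.
#' @return Named numeric vector `c(mae_fit, sigma_fit)` in HU.
#' @export
fit_errors <- function(grid, model) {
  stopifnot(inherits(grid, "bin_grid"))
  use <- grid$counts > 0
  N <- sum(grid$counts[use])
  if (N == 0) stop("grid has zero total count", call. = FALSE)
  c1 <- bin_centers(grid, 1L)
  c2 <- bin_centers(grid, 2L)
  idx <- which(use, arr.ind = TRUE)
  pred <- evaluate_model(model, c1[idx[, 1]], c2[idx[, 2]])
  dev <- grid$mean_ct[use] - pred
  n <- grid$counts[use]
  c(mae_fit = sum(abs(dev) * n) / N, sigma_fit = sqrt(sum(dev^2 * n) / N))
}

#' Intra-bin spread of reference-CT numbers
#'
#' Mean absolute and rms deviation of each voxel's reference CT from its bin's
#' mean CT, pooled over all bins (`N` = total voxel count). With the grid
#' built from the same voxels this measures the irreducible within-bin CT
#' fluctuation that no intensity-to-HU map can remove.
#'
#' @param s1,s2 Voxel intensities (define the bin assignment).
#' @param ct Voxel reference-CT numbers, same length.
#' @param grid The `bin_grid` supplying the per-bin means.
#' @return Named numeric vector `c(mae_rct, sigma_rct)` in HU.
#' @export
spread_errors <- function(s1, s2, ct, grid) {
  stopifnot(inherits(grid, "bin_grid"))
  if (!length(ct)) stop("no voxels", call. = FALSE)
  i <- bin_index(s1, grid$axis_max[1], grid$nbin)
  j <- bin_index(s2, grid$axis_max[2], grid$nbin)
  m <- grid$mean_ct[cbind(i, j)]
  dev <- ct - m
  c(mae_rct = mean(abs(dev)), sigma_rct = sqrt(mean(dev^2)))
}

#' Check the variance decomposition of the pseudo-CT error
#'
#' Relative discrepancy `|sigma_pct^2 - (sigma_rct^2 + sigma_fit^2)| /
#' sigma_pct^2`. When every voxel is assigned its bin-center prediction
#' (per-bin mode) the cross term vanishes by the bin-mean property and the
#' discrepancy is exactly zero; in per-voxel mode it stays small on smooth
#' data.
#'
#' @param sigma_pct,sigma_rct,sigma_fit Non-negative rms error components, HU.
#' @return Relative discrepancy (dimensionless).
#' @export
decomposition_check <- function(sigma_pct, sigma_rct, sigma_fit) {
  stopifnot(sigma_pct >= 0, sigma_rct >= 0, sigma_fit >= 0)
  if (sigma_pct == 0) {
    if (sigma_rct > 0 || sigma_fit > 0) {
      stop("sigma_pct is zero but components are not", call. = FALSE)
    }
    return(0)
  }
  abs(sigma_pct^2 - (sigma_rct^2 + sigma_fit^2)) / sigma_pct^2
}

#' Region-weighted MAE accounting table
#'
#' The weighted MAE of a region is its raw MAE multiplied by the region's
#' voxel fraction, so the weighted values of a partition sum to the overall
#' MAE.
#'
#' @param raw_mae Named numeric vector of per-region raw MAEs (HU).
#' @param counts Matching vector of per-region voxel counts (> 0).
#' @return A data.frame with `region`, `n`, `fraction`, `raw_mae`,
#'   `weighted_mae`, plus attribute `overall_mae`.
#' @export
weighted_region_table <- function(raw_mae, counts) {
  stopifnot(length(raw_mae) == length(counts), all(counts > 0))
  total <- sum(counts)
  frac <- counts / total
  out <- data.frame(region = names(raw_mae), n = as.integer(counts),
                    fraction = as.double(frac), raw_mae = as.double(raw_mae),
                    weighted_mae = as.double(raw_mae * frac),
                    row.names = NULL)
  attr(out, "overall_mae") <- sum(out$weighted_mae)
  out
}

#' Point-to-point dose comparison passing rate
#'
#' A voxel passes when `|D_p - D_r| / reference <= tolerance_pct / 100`
#' (boundary inclusive); this is a DTA = 0 comparison, stricter than a gamma
#' index. The difference is normalized to a single global reference dose
#' (e.g. the prescription) by default; pass `local = TRUE` to normalize each
#' voxel by its own reference dose instead.
#'
#' @param dose_p,dose_r Dose [image_volume()]s (Gy) on the same grid.
#' @param mask 3D logical evaluation mask (must exclude air).
#' @param tolerance_pct Tolerance in percent (default 2).
#' @param reference Global reference dose in Gy (> 0); ignored when
#'   `local = TRUE`.
#' @param local Normalize per voxel by the local reference dose.
#' @return A list of class `dose_report`: `passing_rate` (percent),
#'   `tolerance`, `reference`, `voxel_count`.
#' @export
dose_passing_rate <- function(dose_p, dose_r, mask, tolerance_pct = 2,
                              reference, local = FALSE) {
  check_pair(dose_p, dose_r, mask)
  diff <- abs(dose_p$data[mask] - dose_r$data[mask])
  if (local) {
    den <- dose_r$data[mask]
    if (any(den <= 0)) stop("local normalization needs positive reference dose everywhere in the mask", call. = FALSE)
  } else {
    if (missing(reference) || !is.finite(reference) || reference <= 0) {
      stop("'reference' dose must be positive", call. = FALSE)
    }
    den <- reference
  }
  pass <- diff / den <= tolerance_pct / 100
  structure(list(passing_rate = 100 * mean(pass), tolerance = tolerance_pct,
                 reference = if (local) NA_real_ else reference,
                 voxel_count = sum(mask)), class = "dose_report")
}

#' Full per-region evaluation of a pseudo-CT volume
#'
#' Computes raw MAE and sigma_pCT overall and per region (on body voxels,
#' minus the excluded overlay unless `use_excluded`), the voxel fractions and
#' weighted MAEs, and optionally the error decomposition against a model set:
#' per-region fit errors and intra-bin spread computed from the evaluated
#' patient's own voxels, pooled to an overall row.
#'
#' @param pct,rct pseudo-CT and reference-CT [image_volume()]s.
#' @param labels [region_labels()] on the same grid.
#' @param models Optional `region_model_set`; when given (and trained with
#'   segmentation matching the labels), decomposition columns are added.
#' @param mr1,mr2 Required with `models`: the normalized MRI volumes used for
#'   prediction (they define the bin assignment).
#' @param use_excluded Include excluded voxels in the evaluation mask.
#' @return A list of class `evaluation_report`: `table` (one row per scope,
#'   `overall` first) and `overall` (named list of the overall metrics).
#' @export
evaluate_pct <- function(pct, rct, labels, models = NULL, mr1 = NULL,
                         mr2 = NULL, use_excluded = FALSE) {
  stopifnot(inherits(labels, "region_labels"))
  body <- labels$labels != REGION_CODES[["OUTSIDE"]]
  emask <- if (use_excluded) body else body & !labels$excluded
  region_names <- if (!is.null(models) && !models$segmentation) "BODY"
                  else c("BONY", "SOFT", "MIXED")
  rows <- list()
  counts <- c()
  for (rn in region_names) {
    sel <- if (rn == "BODY") emask
           else emask & labels$labels == REGION_CODES[[rn]]
    if (!any(sel)) next
    r <- list(scope = rn, n = sum(sel), mae = mae(pct, rct, sel),
              sigma = rms_diff(pct, rct, sel))
    if (!is.null(models)) {
      stopifnot(!is.null(mr1), !is.null(mr2))
      s1 <- zero_channel(pmax(mr1$data[sel], 0), models$sequences, "MR1")
      s2 <- zero_channel(pmax(mr2$data[sel], 0), models$sequences, "MR2")
      g <- build_bin_grid(data.frame(s1 = s1, s2 = s2, ct = rct$data[sel]),
                          models$nbin, models$axis_max)
      fe <- fit_errors(g, models$models[[rn]])
      se <- spread_errors(s1, s2, rct$data[sel], g)
      r <- c(r, as.list(fe), as.list(se))
    }
    rows[[rn]] <- r
    counts[rn] <- r$n
  }
  if (!length(rows)) stop("empty evaluation mask", call. = FALSE)
  tab <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  tab$fraction <- tab$n / sum(tab$n)
  tab$weighted_mae <- tab$mae * tab$fraction
  overall <- list(scope = "overall", n = sum(tab$n),
                  mae = mae(pct, rct, emask), sigma = rms_diff(pct, rct, emask))
  if (!is.null(models)) {
    # pool the per-region decompositions: variances and absolute deviations
    # are voxel averages, so they combine with count weights
    wts <- tab$n / sum(tab$n)
    overall$mae_fit <- sum(wts * tab$mae_fit)
    overall$sigma_fit <- sqrt(sum(wts * tab$sigma_fit^2))
    overall$mae_rct <- sum(wts * tab$mae_rct)
    overall$sigma_rct <- sqrt(sum(wts * tab$sigma_rct^2))
    overall$decomposition_discrepancy <-
      decomposition_check(overall$sigma, overall$sigma_rct, overall$sigma_fit)
  }
  overall$fraction <- 1
  overall$weighted_mae <- overall$mae
  keep <- intersect(names(overall), names(tab))
  tab <- rbind(as.data.frame(overall[keep]), tab[, keep, drop = FALSE])
  rownames(tab) <- NULL
  structure(list(table = tab, overall = overall), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) round(v, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report as CSV
#'
#' @param report An `evaluation_report` (or a data.frame).
#' @param path Output path.
#' @param ... Extra constant columns to prepend (e.g. `cycle = 1`).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, ...) {
  tab <- if (inherits(report, "evaluation_report")) report$table else report
  extra <- list(...)
  for (nm in rev(names(extra))) tab <- cbind(setNames(data.frame(extra[[nm]]), nm), tab)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
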