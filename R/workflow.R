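#' Assemble a run configuration
#'
#' Central knob set for train / predict / evaluate / LOOCV runs. Defaults are
#' the method's operating point (`nbin = 200`, `degree = 30`); test suites use
#' far smaller values for speed.
#'
#' @param nbin Bins per intensity axis.
#' @param degree Polynomial degree.
#' @param model_type `"polynomial"` or `"interpolation"`.
#' @param axis_max Optional length-2 intensity-range override.
#' @param segmentation Train per-region models (`TRUE`) or one whole-body
#'   model.
#' @param use_excluded Let excluded voxels enter training/evaluation.
#' @param sequences `"both"`, `"MR1"` or `"MR2"`.
#' @param empty_weight_fraction Weight fraction for imputed bins.
#' @param predict_mode `"per-voxel"` or `"per-bin"` (see [predict_pct()]).
#' @param dose_tolerance_pct,dose_reference Dose-comparison settings (percent
#'   tolerance; global reference dose in Gy, e.g. the 56 Gy prescription).
#' @param seed Seed recorded with the run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(nbin = 200, degree = 30,
                       model_type = c("polynomial", "interpolation"),
                       axis_max = NULL, segmentation = TRUE,
                       use_excluded = FALSE,
                       sequences = c("both", "MR1", "MR2"),
                       empty_weight_fraction = 0.1,
                       predict_mode = c("per-voxel", "per-bin"),
                       dose_tolerance_pct = 2, dose_reference = 56,
                       seed = 1L) {
  stopifnot(nbin >= 1, degree >= 0)
  structure(list(nbin = as.integer(nbin), degree = as.integer(degree),
                 model_type = match.arg(model_type), axis_max = axis_max,
                 segmentation = isTRUE(segmentation),
                 use_excluded = isTRUE(use_excluded),
                 sequences = match.arg(sequences),
                 empty_weight_fraction = empty_weight_fraction,
                 predict_mode = match.arg(predict_mode),
                 dose_tolerance_pct = dose_tolerance_pct,
                 dose_reference = dose_reference, seed = as.integer(seed)),
            class = "run_config")
}

body_mask_of <- function(patient) {
  patient$labels$labels != REGION_CODES[["OUTSIDE"]]
}

# Fit the two per-sequence normalization models on a training cohort.
fit_cohort_normalization <- function(patients) {
  mk <- function(field, tag) {
    fit_normalization(lapply(patients, function(p) {
      list(id = p$id, volume = p[[field]], mask = body_mask_of(p))
    }), sequence = tag)
  }
  list(MR1 = mk("mr1", "MR1"), MR2 = mk("mr2", "MR2"))
}

apply_cohort_normalization <- function(patient, norm) {
  # target patients not in the training cohort are normalized against the
  # training cohort mean using their own body mean
  factor_for <- function(model, vol) {
    if (patient$id %in% names(model$factors)) {
      model$factors[[patient$id]]
    } else {
      model$cohort_mean / mean(vol$data[body_mask_of(patient)])
    }
  }
  patient$mr1 <- apply_normalization(patient$mr1, factor_for(norm$MR1, patient$mr1))
  patient$mr2 <- apply_normalization(patient$mr2, factor_for(norm$MR2, patient$mr2))
  patient
}

#' Train models end-to-end on a cohort
#'
#' Runs cohort normalization then region-model training under a
#' [run_config()].
#'
#' @param patients List of patient datasets (elements `id`, `mr1`, `mr2`,
#'   `ct`, `labels`).
#' @param config A [run_config()].
#' @return List of class `trained_pipeline`: `models` (a `region_model_set`),
#'   `normalization`, `config`.
#' @export
run_train <- function(patients, config = run_config()) {
  if (!length(patients)) stop("training stage: no patients", call. = FALSE)
  norm <- fit_cohort_normalization(patients)
  normalized <- lapply(patients, apply_cohort_normalization, norm = norm)
  models <- train_region_models(
    normalized, nbin = config$nbin, degree = config$degree,
    model_type = config$model_type, axis_max = config$axis_max,
    segmentation = config$segmentation, use_excluded = config$use_excluded,
    sequences = config$sequences,
    empty_weight_fraction = config$empty_weight_fraction)
  structure(list(models = models, normalization = norm, config = config),
            class = "trained_pipeline")
}

#' Predict a pseudo-CT for one patient with a trained pipeline
#'
#' Normalizes the target against the training cohort means and applies the
#' region models.
#'
#' @param trained A `trained_pipeline` from [run_train()].
#' @param patient Target patient dataset.
#' @return A list with `pct` (the pseudo-CT [image_volume()]) and
#'   `normalized` (the normalized target, useful for evaluation).
#' @export
run_predict <- function(trained, patient) {
  stopifnot(inherits(trained, "trained_pipeline"))
  normalized <- apply_cohort_normalization(patient, trained$normalization)
  pct <- predict_pct(trained$models, normalized$mr1, normalized$mr2,
                     normalized$labels, mode = trained$config$predict_mode)
  list(pct = pct, normalized = normalized)
}

#' Leave-one-out cross-validation over a cohort
#'
#' For each cycle one patient is held out, the remaining patients train the
#' pipeline (normalization + binning + imputation + fit), and the held-out
#' patient is predicted and evaluated with its excluded region omitted from
#' the evaluation mask. The summary aggregates per-cycle values as mean and
#' sample standard deviation across cycles.
#'
#' @param patients List of >= 2 patient datasets.
#' @param config A [run_config()].
#' @param decompose Add the error-decomposition columns (fit vs intra-bin
#'   spread) to each cycle's report.
#' @return List of class `loocv_result`: `cycles` (data.frame, one row per
#'   cycle x scope), `summary` (mean and sd of the overall and per-region
#'   MAE/sigma across cycles).
#' @export
run_loocv <- function(patients, config = run_config(), decompose = TRUE) {
  n <- length(patients)
  if (n < 2) stop("LOOCV needs at least 2 patients", call. = FALSE)
  rows <- list()
  for (cycle in seq_len(n)) {
    trained <- run_train(patients[-cycle], config)
    pred <- run_predict(trained, patients[[cycle]])
    rep <- evaluate_pct(pred$pct, pred$normalized$ct, pred$normalized$labels,
                        models = if (decompose) trained$models else NULL,
                        mr1 = pred$normalized$mr1, mr2 = pred$normalized$mr2,
                        use_excluded = config$use_excluded)
    tab <- rep$table
    if (decompose) {
      tab$decomposition_discrepancy <- NA_real_
      tab$decomposition_discrepancy[tab$scope == "overall"] <-
        rep$overall$decomposition_discrepancy
    }
    tab <- cbind(data.frame(cycle = cycle, held_out = patients[[cycle]]$id), tab)
    rows[[cycle]] <- tab
  }
  common <- Reduce(intersect, lapply(rows, names))
  cycles <- do.call(rbind, lapply(rows, function(t) t[, common, drop = FALSE]))
  rownames(cycles) <- NULL
  overall <- cycles[cycles$scope == "overall", ]
  per_scope <- split(cycles, cycles$scope)
  summary <- do.call(rbind, lapply(per_scope, function(s) {
    data.frame(scope = s$scope[1],
               mae_mean = mean(s$mae), mae_sd = sd(s$mae),
               sigma_mean = mean(s$sigma), sigma_sd = sd(s$sigma))
  }))
  rownames(summary) <- NULL
  structure(list(cycles = cycles, summary = summary,
                 overall_mae = mean(overall$mae),
                 overall_mae_sd = sd(overall$mae), config = config),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> %d cycles; overall MAE %.1f +/- %.1f HU\n",
              max(x$cycles$cycle), x$overall_mae, x$overall_mae_sd))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
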