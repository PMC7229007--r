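#' Map an intensity to its bin index
#'
#' Bins are half-open `[i*w, (i+1)*w)` with width `w = axis_max / nbin`,
#' except the last bin which is closed above, so `value == axis_max` lands in
#' bin `nbin`. Values beyond `axis_max` clamp into the last bin (the model is
#' untrained past the observed range). Indices are 1-based.
#'
#' @param value Non-negative intensity (vectorized).
#' @param axis_max Upper end of the binned range (> 0).
#' @param nbin Number of bins (>= 1).
#' @return Integer bin indices in `1..nbin`.
#' @export
bin_index <- function(value, axis_max, nbin) {
  if (any(value < 0)) stop("intensity values must be >= 0", call. = FALSE)
  stopifnot(axis_max > 0, nbin >= 1)
  pmin(pmax(as.integer(floor(value / (axis_max / nbin))) + 1L, 1L), as.integer(nbin))
}

#' Accumulate training samples into a 2D intensity bin grid
#'
#' Builds the Nbin x Nbin accumulator over the joint (MR1, MR2) intensity
#' plane for one region: per-bin voxel counts, per-bin arithmetic-mean CT
#' number, a filled flag, and regression weights equal to the counts on filled
#' bins.
#'
#' @param samples A data.frame with columns `s1`, `s2` (normalized
#'   intensities, >= 0) and `ct` (HU).
#' @param nbin Number of bins per axis.
#' @param axis_max Length-2 numeric, upper range of the two axes.
#' @return An object of class `bin_grid`: list with `nbin`, `axis_max`,
#'   `counts`, `mean_ct` (`NA` on empty bins), `filled`, `weights` (all
#'   `nbin x nbin` matrices, MR1 on rows).
#' @export
build_bin_grid <- function(samples, nbin, axis_max) {
  if (!nrow(samples)) stop("no training samples", call. = FALSE)
  stopifnot(length(axis_max) == 2L, all(axis_max > 0))
  if (any(!is.finite(samples$ct))) stop("non-finite CT values", call. = FALSE)
  nbin <- as.integer(nbin)
  i <- bin_index(samples$s1, axis_max[1], nbin)
  j <- bin_index(samples$s2, axis_max[2], nbin)
  idx <- i + nbin * (j - 1L)
  counts <- tabulate(idx, nbins = nbin * nbin)
  sums <- numeric(nbin * nbin)
  agg <- rowsum(samples$ct, group = idx)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  mean_ct <- ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_)
  structure(list(nbin = nbin, axis_max = as.double(axis_max),
                 counts = matrix(counts, nbin, nbin),
                 mean_ct = matrix(mean_ct, nbin, nbin),
                 filled = matrix(counts > 0, nbin, nbin),
                 weights = matrix(as.double(counts), nbin, nbin)),
            class = "bin_grid")
}

#' Bin-center coordinates of a grid axis
#'
#' @param grid A `bin_grid`.
#' @param axis 1 (MR1) or 2 (MR2).
#' @return Numeric vector of the `nbin` bin-center intensities.
#' @export
bin_centers <- function(grid, axis) {
  w <- grid$axis_max[axis] / grid$nbin
  (seq_len(grid$nbin) - 0.5) * w
}

#' Impute empty bins from their nearest filled neighbour
#'
#' Each empty bin receives the mean CT of the filled bin minimizing the
#' Euclidean index distance `sqrt((i - i_e)^2 + (j - j_e)^2)`; when several
#' filled bins tie at the minimal distance, the average of their values is
#' assigned. The imputed bin's regression weight is
#' `empty_weight_fraction` times the donor weight (mean donor weight for a
#' tie). Filled bins are untouched, and the operation is idempotent: bins that
#' already carry a finite mean and positive weight are never re-imputed.
#'
#' @param grid A `bin_grid`.
#' @param empty_weight_fraction Weight fraction given to imputed bins
#'   (default 0.1).
#' @return The grid with every bin holding a finite `mean_ct` and positive
#'   weight.
#' @export
fill_empty_bins <- function(grid, empty_weight_fraction = 0.1) {
  stopifnot(inherits(grid, "bin_grid"), empty_weight_fraction > 0)
  empty <- which(!is.finite(grid$mean_ct) | grid$weights <= 0)
  if (!length(empty)) return(grid)
  donors <- which(is.finite(grid$mean_ct) & grid$weights > 0)
  if (!length(donors)) stop("all bins are empty; nothing to impute from", call. = FALSE)
  nbin <- grid$nbin
  di <- (donors - 1L) %% nbin
  dj <- (donors - 1L) %/% nbin
  dval <- grid$mean_ct[donors]
  dwt <- grid$weights[donors]
  ei <- (empty - 1L) %% nbin
  ej <- (empty - 1L) %/% nbin
  # chunk the empty bins so the distance matrix stays small
  chunk <- max(1L, as.integer(2e6 / length(donors)))
  for (s in seq(1L, length(empty), by = chunk)) {
    e <- s:min(s + chunk - 1L, length(empty))
    # squared distances are integers, so ties are exact
    d2 <- outer(ei[e], di, "-")^2 + outer(ej[e], dj, "-")^2
    dmin <- d2 == apply(d2, 1L, min)
    nt <- rowSums(dmin)
    grid$mean_ct[empty[e]] <- as.vector(dmin %*% dval) / nt
    grid$weights[empty[e]] <- empty_weight_fraction * as.vector(dmin %*% dwt) / nt
  }
  grid
}

#' Write a bin grid as tab-separated text
#'
#' One row per bin: `i`, `j`, `n`, `mean_ct`, `filled`, `weight`; grid
#' metadata on `#`-prefixed header lines.
#'
#' @param grid A `bin_grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bin_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nbin %d", grid$nbin), con)
  writeLines(sprintf("# axis_max %.17g %.17g", grid$axis_max[1], grid$axis_max[2]), con)
  df <- data.frame(i = rep(seq_len(grid$nbin), grid$nbin),
                   j = rep(seq_len(grid$nbin), each = grid$nbin),
                   n = as.vector(grid$counts),
                   mean_ct = as.vector(grid$mean_ct),
                   filled = as.integer(as.vector(grid$filled)),
                   weight = as.vector(grid$weights))
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bin grid written by [write_bin_grid()]
#'
#' @param path File path.
#' @return A `bin_grid`.
#' @export
read_bin_grid <- function(path) {
  hdr <- readLines(path, n = 2L)
  nbin <- as.integer(strsplit(hdr[1], " ")[[1]][3])
  axis_max <- as.double(strsplit(hdr[2], " ")[[1]][3:4])
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  ord <- order(df$j, df$i)
  df <- df[ord, ]
  structure(list(nbin = nbin, axis_max = axis_max,
                 counts = matrix(df$n, nbin, nbin),
                 mean_ct = matrix(df$mean_ct, nbin, nbin),
                 filled = matrix(df$filled > 0, nbin, nbin),
                 weights = matrix(df$weight, nbin, nbin)),
            class = "bin_grid")
}
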