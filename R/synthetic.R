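# Reproducible multi-patient phantom cohorts: paired MR1/MR2/CT volumes with
# region labels and a known, noisy intensity -> HU mapping, so the whole
# pipeline is testable without patient data.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Separable Gaussian smoothing along the three axes; kernel truncated at
# 3 sigma and renormalized row-wise, so edges are handled by weight
# renormalization rather than padding.
gauss_smooth3 <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    n <- d[axis]
    half <- max(1L, as.integer(ceiling(3 * s)))
    x <- seq_len(n)
    K <- exp(-outer(x, x, "-")^2 / (2 * s^2))
    K[abs(outer(x, x, "-")) > half] <- 0
    K <- K / rowSums(K)
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    dims <- dim(a)
    a <- K %*% matrix(a, nrow = dims[1])
    dim(a) <- dims
    arr <- aperm(a, order(perm))
  }
  arr
}

# Smooth standard field: filtered white noise, standardized later per region.
smooth_field <- function(shape, sigma_vox) {
  gauss_smooth3(array(rnorm(prod(shape)), shape), sigma_vox)
}

#' Specification of a synthetic phantom cohort
#'
#' Describes the stated world the pipeline is tested in: nested-ellipsoid
#' anatomy (body, a bone shell, and the transition shell the margins carve
#' out), region-dependent dual-channel intensity distributions built from
#' spatially smooth random fields, a known low-degree polynomial
#' intensity-to-HU map per region, additive Gaussian CT noise, an excluded
#' overlay with corrupted CT, and per-patient multiplicative MR gain factors
#' that make cohort normalization do real work.
#'
#' Within each region the smooth field is standardized to zero mean and unit
#' sd over the region's voxels, so every patient's underlying (pre-gain)
#' intensity distribution has exactly the stated mean and sd; cohort
#' normalization can then remove the gains exactly, which is what makes the
#' noiseless exact-recovery oracle meaningful.
#'
#' Ground-truth maps take normalized inputs `u = S1/1000`, `v = S2/2500`
#' (fixed reference scales) and are total-degree <= 2 polynomials chosen so
#' that (a) both channels contribute substantially to the CT variance in
#' every region, and (b) the mixed region overlaps the soft region in
#' intensity while mapping to very different HU, so segmentation genuinely
#' helps. An optional sigmoidal bone map exercises non-polynomial
#' approximation error.
#'
#' @param shape Voxel dimensions (default `c(64, 64, 64)`).
#' @param spacing Voxel size in mm (default `c(0.81, 0.81, 5)`, the
#'   resolution convention of pelvic dual-contrast protocols).
#' @param ct_noise_sd Additive Gaussian CT noise sd in HU (default 50,
#'   consistent with observed soft-tissue intra-bin spreads of ~40 HU).
#' @param excluded_fraction Fraction of body voxels flagged excluded, as a
#'   contiguous blob, with CT replaced by the outlier `excluded_value`
#'   (default 0.05).
#' @param excluded_value HU value written into excluded voxels (default -400,
#'   a bowel-gas-like mismatch).
#' @param gain_sd sd of the per-patient, per-sequence log-normal MR gain
#'   (default 0.15).
#' @param sigma_vox Smoothness (voxel sd) of the random fields per axis.
#' @param bone_map `"polynomial"` (exactly recoverable) or `"sigmoid"`.
#' @param seed Master seed; every patient draws from a deterministic
#'   substream.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing = c(0.81, 0.81, 5),
                         ct_noise_sd = 50, excluded_fraction = 0.05,
                         excluded_value = -400, gain_sd = 0.15,
                         sigma_vox = c(2.5, 2.5, 1.5),
                         bone_map = c("polynomial", "sigmoid"), seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 8), ct_noise_sd >= 0,
            excluded_fraction >= 0, excluded_fraction < 1, gain_sd >= 0)
  bone_map <- match.arg(bone_map)
  structure(list(
    shape = as.integer(shape), spacing = as.double(spacing),
    # normalized-radius geometry: body ellipsoid, bone shell inside it
    body_semi = c(0.82, 0.78, 0.85),   # fractions of the half-dimensions
    bone_r = c(inner = 0.45, outer = 0.62),  # body-normalized radii
    intensity = list(
      BONY  = list(m1 = 250, s1 = 90,  m2 = 350,  s2 = 110),
      SOFT  = list(m1 = 800, s1 = 160, m2 = 2000, s2 = 420),
      MIXED = list(m1 = 550, s1 = 180, m2 = 1300, s2 = 380)),
    map_scale = c(1000, 2500),
    # coefficient rows: (i1, i2, c) on u = S1/1000, v = S2/2500
    maps = list(
      BONY = rbind(c(0, 0, 800), c(1, 0, 420), c(0, 1, -700),
                   c(1, 1, 150), c(2, 0, -120)),
      SOFT = rbind(c(0, 0, 120), c(1, 0, 140), c(0, 1, -160),
                   c(1, 1, 40), c(0, 2, -30)),
      MIXED = rbind(c(0, 0, 500), c(1, 0, 260), c(0, 1, -420),
                    c(2, 0, 80))),
    bone_map = bone_map,
    ct_noise_sd = ct_noise_sd, excluded_fraction = excluded_fraction,
    excluded_value = excluded_value, gain_sd = gain_sd,
    sigma_vox = as.double(sigma_vox), seed = as.integer(seed)),
    class = "phantom_spec")
}

# Evaluate a ground-truth map at true (pre-gain) intensities.
truth_map <- function(spec, region, s1, s2) {
  u <- s1 / spec$map_scale[1]
  v <- s2 / spec$map_scale[2]
  if (region == "BONY" && spec$bone_map == "sigmoid") {
    # non-polynomial alternative: cortical-bone-like saturation in u with a
    # T2-driven decrease
    return(250 + 900 / (1 + exp(-6 * (u - 0.2))) - 650 * v + 120 * u * v)
  }
  coefs <- spec$maps[[region]]
  val <- numeric(length(s1))
  for (r in seq_len(nrow(coefs))) {
    val <- val + coefs[r, 3] * u^coefs[r, 1] * v^coefs[r, 2]
  }
  val
}

# Highest total degree among the ground-truth maps (for recovery oracles).
truth_degree <- function(spec) {
  max(vapply(spec$maps, function(m) max(m[, 1] + m[, 2]), numeric(1)))
}

phantom_geometry <- function(spec) {
  d <- spec$shape
  ax <- lapply(1:3, function(a) {
    c0 <- (d[a] + 1) / 2
    ((seq_len(d[a]) - c0) / (d[a] / 2)) / spec$body_semi[a]
  })
  rho2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  rho <- sqrt(rho2)
  body <- rho <= 1
  bone <- rho >= spec$bone_r[["inner"]] & rho <= spec$bone_r[["outer"]]
  list(body = body, bone = bone)
}

#' Generate one phantom patient
#'
#' Deterministic given `(spec$seed, patient_index)`. Returns co-registered
#' MR1, MR2 and CT volumes plus region labels (built with the package's own
#' margin rules around the bone shell), the geometry masks, and bookkeeping
#' needed by oracles: the pre-gain true intensities and the uncorrupted CT.
#'
#' @param spec A [phantom_spec()].
#' @param patient_index Positive integer selecting the random substream.
#' @return A list with elements `id`, `mr1`, `mr2`, `ct` ([image_volume()]s),
#'   `labels` ([region_labels()]), `body`, `bone` (logical arrays), `gains`
#'   (length 2), `ct_clean` (CT before excluded-region corruption) and
#'   `ct_true` (noiseless CT).
#' @export
generate_phantom <- function(spec, patient_index = 1L) {
  stopifnot(inherits(spec, "phantom_spec"), patient_index >= 1)
  geo <- phantom_geometry(spec)
  labels <- build_region_labels(geo$bone, geo$body, spec$spacing, mask_params())
  with_seed(as.double(spec$seed) * 10007 + patient_index * 97, {
    gains <- exp(rnorm(2, 0, spec$gain_sd))
    g1 <- smooth_field(spec$shape, spec$sigma_vox)
    g2 <- smooth_field(spec$shape, spec$sigma_vox)
    gx <- smooth_field(spec$shape, spec$sigma_vox * 2)
    noise <- if (spec$ct_noise_sd > 0) {
      array(rnorm(prod(spec$shape), 0, spec$ct_noise_sd), spec$shape)
    } else NULL
    mr1_true <- array(0, spec$shape)
    mr2_true <- array(0, spec$shape)
    ct_true <- array(-1000, spec$shape)
    for (rn in c("BONY", "SOFT", "MIXED")) {
      sel <- labels$labels == REGION_CODES[[rn]]
      if (!any(sel)) next
      p <- spec$intensity[[rn]]
      # standardize the field within the region (see ?phantom_spec)
      f1 <- g1[sel]; f1 <- (f1 - mean(f1)) / max(sd(f1), 1e-12)
      f2 <- g2[sel]; f2 <- (f2 - mean(f2)) / max(sd(f2), 1e-12)
      s1 <- pmax(p$m1 + p$s1 * f1, 0)
      s2 <- pmax(p$m2 + p$s2 * f2, 0)
      mr1_true[sel] <- s1
      mr2_true[sel] <- s2
      ct_true[sel] <- truth_map(spec, rn, s1, s2)
    }
    body <- geo$body
    ct <- ct_true
    if (!is.null(noise)) ct[body] <- ct[body] + noise[body]
    ct <- pmin(pmax(ct, -1000), 2000)
    ct[!body] <- -1000
    ct_clean <- ct
    excluded <- array(FALSE, spec$shape)
    if (spec$excluded_fraction > 0) {
      # threshold a coarser smooth field to get a contiguous excluded blob
      thr <- quantile(gx[body], probs = 1 - spec$excluded_fraction)
      excluded <- body & gx > thr
      ct[excluded] <- spec$excluded_value
    }
    list(id = sprintf("P%02d", patient_index),
         mr1 = image_volume(mr1_true * gains[1], spec$spacing, "MR1"),
         mr2 = image_volume(mr2_true * gains[2], spec$spacing, "MR2"),
         ct = image_volume(ct, spec$spacing, "CT"),
         labels = region_labels(labels$labels, excluded),
         body = body, bone = geo$bone, gains = gains,
         ct_clean = ct_clean, ct_true = ct_true)
  })
}

#' Generate a phantom cohort
#'
#' Patients share the geometry and ground-truth map but differ in their
#' random intensity fields, CT noise, excluded blobs and MR gain factors.
#'
#' @param spec A [phantom_spec()].
#' @param n_patients Number of patients (>= 1).
#' @return List of patient datasets (see [generate_phantom()]).
#' @export
generate_cohort <- function(spec, n_patients) {
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  lapply(seq_len(n_patients), function(i) generate_phantom(spec, i))
}

#' Analytic region volume fractions of the phantom geometry
#'
#' Exact ellipsoid-volume ratios implied by the spec, for comparison with
#' voxel counts: the bone shell occupies `r_out^3 - r_in^3` of the body
#' ellipsoid volume.
#'
#' @param spec A [phantom_spec()].
#' @return Named list with `body_fraction` (of the bounding box) and
#'   `bone_fraction` (of the body).
#' @export
phantom_analytic_fractions <- function(spec) {
  body_frac <- (4 / 3) * pi * prod(spec$body_semi) / 8
  bone_frac <- spec$bone_r[["outer"]]^3 - spec$bone_r[["inner"]]^3
  list(body_fraction = body_frac, bone_fraction = unname(bone_frac))
}
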