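# Binary 3D morphology on logical arrays.
#
# Structuring elements are ellipsoids specified by a per-axis voxel radius,
# obtained from a mm radius via the voxel spacing (round half up, minimum 0);
# with 5 mm slices a 2.5 mm margin therefore spans 1 slice axially but 3
# voxels in-plane at 0.81 mm. Outside the image everything counts as
# background (dilation never wraps, erosion shrinks at the border).

mm_to_voxel_radius <- function(radius_mm, spacing) {
  stopifnot(radius_mm >= 0, length(spacing) == 3L)
  pmax(0L, as.integer(floor(radius_mm / spacing + 0.5)))
}

# Offsets (dx, dy, dz) inside the ellipsoid with semi-axes r_vox (per axis).
ellipsoid_offsets <- function(r_vox) {
  r <- as.integer(r_vox)
  g <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  den <- pmax(r, 1L)  # axes with radius 0 contribute only offset 0
  keep <- (g$dx / den[1])^2 + (g$dy / den[2])^2 + (g$dz / den[3])^2 <= 1 + 1e-9
  keep <- keep & !(r[1] == 0 & g$dx != 0) & !(r[2] == 0 & g$dy != 0) &
    !(r[3] == 0 & g$dz != 0)
  as.matrix(g[keep, , drop = FALSE])
}

shift_mask <- function(m, off) {
  d <- dim(m)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    o <- off[a]
    if (abs(o) >= d[a]) return(out)
    if (o >= 0) {
      src[[a]] <- seq_len(d[a] - o)
      dst[[a]] <- src[[a]] + o
    } else {
      dst[[a]] <- seq_len(d[a] + o)
      src[[a]] <- dst[[a]] - o
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

binary_dilate <- function(mask, r_vox) {
  if (all(r_vox == 0L) || !any(mask)) return(mask)
  offs <- ellipsoid_offsets(r_vox)
  out <- array(FALSE, dim(mask))
  for (k in seq_len(nrow(offs))) {
    out <- out | shift_mask(mask, offs[k, ])
  }
  out
}

binary_erode <- function(mask, r_vox) {
  if (all(r_vox == 0L)) return(mask)
  offs <- ellipsoid_offsets(r_vox)
  out <- array(TRUE, dim(mask))
  for (k in seq_len(nrow(offs))) {
    out <- out & shift_mask(mask, offs[k, ])
    if (!any(out)) break
  }
  out
}

binary_close <- function(mask, r_vox) {
  binary_erode(binary_dilate(mask, r_vox), r_vox)
}

# 6-connected components by frontier BFS on a zero-padded copy.
# Returns a list of integer index vectors (into the original array).
connected_components <- function(mask) {
  d <- dim(mask)
  dp <- d + 2L
  p <- array(FALSE, dp)
  p[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  strides <- c(1L, dp[1], dp[1] * dp[2])
  offs <- c(strides, -strides)
  unvisited <- p
  comps <- list()
  repeat {
    seeds <- which(unvisited)
    if (!length(seeds)) break
    frontier <- seeds[1]
    unvisited[frontier] <- FALSE
    pieces <- list()
    while (length(frontier)) {
      pieces[[length(pieces) + 1L]] <- frontier
      nb <- unique(as.vector(outer(frontier, offs, "+")))
      frontier <- nb[unvisited[nb]]
      unvisited[frontier] <- FALSE
    }
    comps[[length(comps) + 1L]] <- unlist(pieces)
  }
  # map padded linear indices back to the original array
  lapply(comps, function(idx) {
    z <- (idx - 1L) %/% (dp[1] * dp[2])
    rem <- (idx - 1L) %% (dp[1] * dp[2])
    y <- rem %/% dp[1]
    x <- rem %% dp[1]
    (x - 1L) + d[1] * (y - 1L) + d[1] * d[2] * (z - 1L) + 1L
  })
}

largest_component <- function(mask) {
  comps <- connected_components(mask)
  out <- array(FALSE, dim(mask))
  if (!length(comps)) return(out)
  out[comps[[which.max(lengths(comps))]]] <- TRUE
  out
}

# Fill interior cavities: background is the complement component reachable
# from the (padded) border; everything else belongs to the object.
fill_holes <- function(mask) {
  d <- dim(mask)
  dp <- d + 2L
  p <- array(TRUE, dp)  # complement, with a TRUE border ring connecting outside
  p[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- !mask
  strides <- c(1L, dp[1], dp[1] * dp[2])
  offs <- c(strides, -strides)
  unvisited <- p
  frontier <- 1L  # corner of the padding ring
  unvisited[frontier] <- FALSE
  outside <- array(FALSE, dp)
  while (length(frontier)) {
    outside[frontier] <- TRUE
    nb <- unique(as.vector(outer(frontier, offs, "+")))
    nb <- nb[nb >= 1L & nb <= prod(dp)]
    frontier <- nb[unvisited[nb]]
    unvisited[frontier] <- FALSE
  }
  inner <- outside[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
  !inner
}
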