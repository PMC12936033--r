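# First-order intensity statistics.
#
# Computed on the raw region intensities; Entropy and Uniformity use the
# fixed-bin-count discretized histogram (range-relative, shared bin count
# from the schema). Moments use the population convention; Kurtosis is the
# Pearson fourth standardized moment (normal -> 3). Degenerate inputs
# (constant region) take their analytic limits: Skewness 0, Kurtosis 0 per
# the 0/0 -> 0 policy used throughout, Entropy 0, Uniformity 1.

EPS_LOG <- 2.2e-16

firstorder_features <- function(x, voxel_volume = 1, n_bins = 25L,
                                include_total_energy = TRUE) {
  n <- length(x)
  stopifnot(n >= 1)
  m <- mean(x)
  v <- mean((x - m)^2)               # population variance
  q <- stats::quantile(x, c(.10, .25, .50, .75, .90), names = FALSE, type = 7)
  bins <- bin_intensities(x, min(x), max(x), n_bins)
  p <- tabulate(bins, n_bins) / n
  robust <- x[x >= q[1] & x <= q[5]]
  sdv <- sqrt(v)
  skew <- if (v > 0) mean((x - m)^3) / v^1.5 else 0
  kurt <- if (v > 0) mean((x - m)^4) / v^2 else 0
  out <- c(
    Energy = sum(x^2),
    TotalEnergy = voxel_volume * sum(x^2),
    Entropy = -sum(p * log2(p + EPS_LOG)),
    Minimum = min(x),
    Percentile10 = q[1],
    Percentile90 = q[5],
    Maximum = max(x),
    Mean = m,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - m)),
    RobustMeanAbsoluteDeviation = mean(abs(robust - mean(robust))),
    RootMeanSquared = sqrt(mean(x^2)),
    StandardDeviation = sdv,
    Skewness = skew,
    Kurtosis = kurt,
    Variance = v,
    Uniformity = sum(p^2))
  if (!include_total_energy) out <- out[names(out) != "TotalEnergy"]
  out
}

# Shape features computed on the voxelized mask geometry.
#
# Volume by voxel counting, surface area by exposed-face counting (so the
# analytic value for an axis-aligned box is exact), diameters between voxel
# centers, and principal axes from the eigenvalues of the physical
# coordinate covariance (sample covariance, axes = 4*sqrt(lambda)).
shape_features <- function(mask_vals, spacing_mm) {
  idx <- which(mask_vals, arr.ind = TRUE)
  n <- nrow(idx)
  stopifnot(n >= 1)
  vv <- prod(spacing_mm)
  volume <- n * vv
  d <- dim(mask_vals)

  # exposed faces per axis
  area <- 0
  face_area <- c(spacing_mm[2] * spacing_mm[3],
                 spacing_mm[1] * spacing_mm[3],
                 spacing_mm[1] * spacing_mm[2])
  for (ax in 1:3) {
    o <- c(0L, 0L, 0L); o[ax] <- 1L
    pad_dim <- d; pad_dim[ax] <- d[ax] + 1L
    a <- array(FALSE, pad_dim); b <- array(FALSE, pad_dim)
    ia <- lapply(1:3, function(k) seq_len(d[k]))
    ib <- ia; ib[[ax]] <- ib[[ax]] + 1L
    a[ia[[1]], ia[[2]], ia[[3]]] <- mask_vals
    b[ib[[1]], ib[[2]], ib[[3]]] <- mask_vals
    area <- area + sum(xor(a, b)) * face_area[ax]
  }

  sphericity <- (pi^(1 / 3) * (6 * volume)^(2 / 3)) / area

  co <- sweep(idx, 2, spacing_mm, "*")     # physical voxel centers
  max_pair <- function(m) {
    if (nrow(m) < 2L) return(0)
    if (nrow(m) > 2000L) m <- m[convex_extremes(m), , drop = FALSE]
    max(stats::dist(m))
  }
  d3 <- max_pair(co)
  per_plane_max <- function(fixed_axis) {
    planes <- split.data.frame(co, idx[, fixed_axis])
    max(vapply(planes, function(p)
      max_pair(as.matrix(p)[, -fixed_axis, drop = FALSE]), 0))
  }
  d2_slice <- per_plane_max(3)    # within constant-z (axial) planes
  d2_col <- per_plane_max(2)      # within constant-y planes
  d2_row <- per_plane_max(1)      # within constant-x planes

  if (n >= 2) {
    ev <- sort(eigen(stats::cov(co), symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else ev <- c(0, 0, 0)
  axes <- 4 * sqrt(ev)
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1

  c(VoxelVolume = volume, SurfaceArea = area, SurfaceVolumeRatio = area / volume,
    Sphericity = sphericity, Maximum3DDiameter = d3,
    Maximum2DDiameterSlice = d2_slice, Maximum2DDiameterColumn = d2_col,
    Maximum2DDiameterRow = d2_row, MajorAxisLength = axes[1],
    MinorAxisLength = axes[2], LeastAxisLength = axes[3],
    Elongation = elong, Flatness = flat)
}

# reduce a big point cloud to per-direction extremes before the O(n^2)
# diameter search (extremes along many random directions contain the pair)
convex_extremes <- function(m, n_dir = 64L) {
  dirs <- with_seed(0, matrix(stats::rnorm(3 * n_dir), ncol = 3))
  proj <- m %*% t(dirs)
  unique(c(apply(proj, 2, which.min), apply(proj, 2, which.max)))
}
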