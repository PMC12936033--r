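#' Resample a volume and its masks to an isotropic grid
#'
#' Resamples to `target_mm` isotropic voxels. Masks always use
#' nearest-neighbor interpolation so they stay binary; the image uses
#' nearest-neighbor by default (matching the mask dialect) or trilinear when
#' `interpolation = "linear"`.
#'
#' Output grid: axis k gets `ceiling(n_k * spacing_k / target_mm)` voxels;
#' output voxel centers are mapped back to input continuous coordinates and
#' sampled there.
#'
#' @param volume an [image_volume()].
#' @param masks a list of [region_mask()] aligned with `volume`.
#' @param target_mm positive scalar, output voxel size (mm).
#' @param interpolation `"nearest"` (default) or `"linear"` for the image.
#' @return list with elements `volume` and `masks` on the new grid.
#' @export
resample_isotropic <- function(volume, masks = list(), target_mm = 1,
                               interpolation = c("nearest", "linear")) {
  interpolation <- match.arg(interpolation)
  stopifnot(target_mm > 0)
  sp <- volume$spacing_mm
  d <- dim(volume$values)
  if (max(abs(sp - target_mm)) < 1e-9) {   # already isotropic at target
    return(list(volume = volume, masks = masks))
  }
  nd <- pmax(as.integer(ceiling(d * sp / target_mm)), 1L)
  # output voxel centers in input voxel (1-based, continuous) coordinates
  src <- lapply(1:3, function(k) {
    phys <- ((seq_len(nd[k]) - 0.5) * target_mm)      # center, mm from grid edge
    (phys / sp[k]) + 0.5                              # continuous input index
  })
  nn_idx <- lapply(1:3, function(k) pmin(pmax(round(src[[k]]), 1L), d[k]))

  sample_nn <- function(a) a[nn_idx[[1]], nn_idx[[2]], nn_idx[[3]], drop = FALSE]

  out_vol <- if (interpolation == "nearest") {
    sample_nn(volume$values)
  } else {
    trilinear_sample(volume$values, src)
  }
  out_volume <- image_volume(out_vol, spacing_mm = rep(target_mm, 3),
                             origin = volume$origin)
  out_masks <- lapply(seq_along(masks), function(i) {
    m <- masks[[i]]
    stopifnot_aligned(volume, m, "volume/mask")
    rv <- sample_nn(m$values)
    if (!any(rv)) stop("resample_isotropic: mask ", i, " is empty after resampling")
    region_mask(rv, spacing_mm = rep(target_mm, 3), origin = m$origin)
  })
  names(out_masks) <- names(masks)
  list(volume = out_volume, masks = out_masks)
}

# trilinear interpolation at grid positions given per-axis continuous indices
trilinear_sample <- function(a, src) {
  d <- dim(a)
  f <- lapply(1:3, function(k) pmin(pmax(src[[k]], 1), d[k]))
  lo <- lapply(1:3, function(k) pmin(floor(f[[k]]), d[k] - 1L))
  w <- lapply(1:3, function(k) f[[k]] - lo[[k]])
  n <- vapply(src, length, 1L)
  out <- array(0, dim = n)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wx <- if (cx) w[[1]] else 1 - w[[1]]
    wy <- if (cy) w[[2]] else 1 - w[[2]]
    wz <- if (cz) w[[3]] else 1 - w[[3]]
    sub <- a[lo[[1]] + cx, lo[[2]] + cy, lo[[3]] + cz, drop = FALSE]
    out <- out + sub * (wx %o% wy %o% wz)
  }
  out
}

#' Build the whole volume of interest (WVOI) around a tumor mask
#'
#' Expands the gross tumor volume (GTV) by a physical margin (default 3 mm)
#' to form a peritumoral ring, clips the ring to the lung mask so it never
#' reaches the chest wall, and returns GTV, ring and their union (the WVOI).
#' Distances are Euclidean in physical millimetres with an inclusive
#' threshold (a voxel center at exactly `margin_mm` from the nearest GTV
#' voxel center belongs to the ring).
#'
#' @param gtv [region_mask()], nonempty tumor mask.
#' @param lung [region_mask()] aligned with `gtv`; the ring is intersected
#'   with it. The GTV itself is kept verbatim even where it leaves the lung
#'   (with a warning).
#' @param margin_mm expansion margin in mm (default 3).
#' @return list of class `wvoi_regions` with masks `gtv`, `ring`, `wvoi`.
#' @export
expand_gtv <- function(gtv, lung, margin_mm = 3) {
  stopifnot(margin_mm >= 0)
  stopifnot_aligned(gtv, lung, "gtv/lung")
  if (!any(gtv$values)) stop("expand_gtv: empty GTV mask")
  if (any(gtv$values & !lung$values))
    warning("expand_gtv: GTV extends outside the lung mask; GTV kept verbatim")
  dil <- dilate_mm(gtv$values, gtv$spacing_mm, margin_mm)
  ring_vals <- dil & !gtv$values & lung$values
  ring <- region_mask(ring_vals, gtv$spacing_mm, gtv$origin)
  wvoi <- region_mask(gtv$values | ring_vals, gtv$spacing_mm, gtv$origin)
  structure(list(gtv = gtv, ring = ring, wvoi = wvoi, margin_mm = margin_mm),
            class = "wvoi_regions")
}

# Morphological dilation with a physical-unit spherical structuring element:
# the union of the mask shifted by every integer offset whose physical length
# is <= margin_mm. Exact for Euclidean distance between voxel centers.
dilate_mm <- function(mask_vals, spacing_mm, margin_mm) {
  if (margin_mm <= 0) return(mask_vals)
  d <- dim(mask_vals)
  r <- floor(margin_mm / spacing_mm)
  offs <- as.matrix(expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3]))
  phys2 <- (offs[, 1] * spacing_mm[1])^2 + (offs[, 2] * spacing_mm[2])^2 +
           (offs[, 3] * spacing_mm[3])^2
  offs <- offs[phys2 <= margin_mm^2 + 1e-9, , drop = FALSE]
  out <- array(FALSE, dim = d)
  for (i in seq_len(nrow(offs))) {
    o <- offs[i, ]
    # destination ranges for a shift by o
    xs <- max(1, 1 + o[1]):min(d[1], d[1] + o[1])
    ys <- max(1, 1 + o[2]):min(d[2], d[2] + o[2])
    zs <- max(1, 1 + o[3]):min(d[3], d[3] + o[3])
    out[xs, ys, zs] <- out[xs, ys, zs] | mask_vals[xs - o[1], ys - o[2], zs - o[3]]
  }
  out
}

#' Physical Euclidean distance from every voxel to a mask
#'
#' Brute-force distance map used for small grids and as a reference for the
#' dilation-based expansion: for every voxel the minimum center-to-center
#' distance (mm) to any mask voxel.
#'
#' @param mask a `region_mask`.
#' @return numeric array of distances (0 inside the mask).
#' @export
distance_to_mask <- function(mask) {
  d <- dim(mask$values)
  sp <- mask$spacing_mm
  src <- mask_coords(mask)
  if (nrow(src) == 0L) stop("distance_to_mask: empty mask")
  all_idx <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                                   z = seq_len(d[3])))
  sx <- src[, 1] * sp[1]; sy <- src[, 2] * sp[2]; sz <- src[, 3] * sp[3]
  ax <- all_idx[, 1] * sp[1]; ay <- all_idx[, 2] * sp[2]; az <- all_idx[, 3] * sp[3]
  d2 <- outer(ax, sx, "-")^2 + outer(ay, sy, "-")^2 + outer(az, sz, "-")^2
  array(sqrt(apply(d2, 1, min)), dim = d)
}
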