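#' Image volumes and region masks
#'
#' Lightweight containers for 3-D scalar images and binary masks on a regular
#' grid with physical voxel spacing (mm) and an origin offset. These are the
#' currency of the whole pipeline: geometry, entropy maps, habitat clustering
#' and feature extraction all operate on them.
#'
#' @param values 3-D numeric array.
#' @param spacing_mm numeric length-3, physical voxel size per axis (mm).
#' @param origin numeric length-3, physical offset of the first voxel.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing_mm = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("image_volume: `values` must be a 3-D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("image_volume: spacing_mm must be 3 positive finite numbers")
  if (any(!is.finite(values))) stop("image_volume: values must be finite")
  structure(list(values = values, spacing_mm = spacing_mm,
                 origin = as.numeric(origin)),
            class = "image_volume")
}

#' @param values 3-D array coercible to logical/0-1.
#' @rdname image_volume
#' @return `region_mask()` returns an object of class `region_mask` whose
#'   `values` are a logical 3-D array.
#' @export
region_mask <- function(values, spacing_mm = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("region_mask: `values` must be a 3-D array")
  if (is.numeric(values)) {
    u <- unique(as.vector(values))
    if (!all(u %in% c(0, 1))) stop("region_mask: values must be binary (0/1)")
    values <- array(values != 0, dim = dim(values))
  } else if (!is.logical(values)) {
    stop("region_mask: values must be logical or 0/1 numeric")
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("region_mask: spacing_mm must be 3 positive numbers")
  structure(list(values = values, spacing_mm = spacing_mm,
                 origin = as.numeric(origin)),
            class = "region_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume>", paste(dim(x$values), collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing_mm, 4), collapse = "/"), "mm\n")
  invisible(x)
}

#' @export
print.region_mask <- function(x, ...) {
  cat("<region_mask>", paste(dim(x$values), collapse = " x "),
      "voxels,", sum(x$values), "in mask, spacing",
      paste(signif(x$spacing_mm, 4), collapse = "/"), "mm\n")
  invisible(x)
}

#' Number of voxels inside a mask
#' @param mask a `region_mask`.
#' @return integer voxel count.
#' @export
mask_size <- function(mask) sum(mask$values)

stopifnot_aligned <- function(a, b, what = "grids") {
  if (!identical(dim(a$values), dim(b$values)) ||
      max(abs(a$spacing_mm - b$spacing_mm)) > 1e-9)
    stop("misaligned ", what, ": dimensions/spacing differ")
  invisible(TRUE)
}

#' Voxel coordinates (1-based array indices) of mask voxels
#' @param mask a `region_mask`.
#' @return integer matrix with columns x, y, z.
#' @export
mask_coords <- function(mask) {
  which(mask$values, arr.ind = TRUE)
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers around RNifti. Masks are written as uint8 images; reading a
#' mask binarizes at > 0.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume()` an `image_volume`; `read_mask()` a `region_mask`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  image_volume(array(as.numeric(img), dim = dim(img)),
               spacing_mm = RNifti::pixdim(img)[seq_len(3)])
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  region_mask(array(as.numeric(img) > 0, dim = dim(img)),
              spacing_mm = RNifti::pixdim(img)[seq_len(3)])
}

#' @param volume an `image_volume` or `region_mask`.
#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  is_mask <- inherits(volume, "region_mask")
  vals <- if (is_mask) array(as.integer(volume$values), dim = dim(volume$values))
          else volume$values
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- volume$spacing_mm
  RNifti::writeNifti(img, path, datatype = if (is_mask) "uint8" else "double")
  invisible(path)
}

# bounding box of a mask, padded by `pad` voxels and clipped to the grid
mask_bbox <- function(mask, pad = 0L) {
  idx <- mask_coords(mask)
  if (nrow(idx) == 0L) stop("mask_bbox: empty mask")
  d <- dim(mask$values)
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, d)
  list(lo = lo, hi = hi)
}

crop_array <- function(a, bbox) {
  a[bbox$lo[1]:bbox$hi[1], bbox$lo[2]:bbox$hi[2], bbox$lo[3]:bbox$hi[3], drop = FALSE]
}
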