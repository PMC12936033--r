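#' Extract the radiomic feature vector of one region
#'
#' Applies the schema to one image/region pair: shape features on the mask
#' geometry, first-order statistics on the raw in-region intensities, texture
#' features on intensities discretized to the schema's fixed bin count over
#' the region's min-max range, and — when the schema includes wavelets — the
#' first-order and texture blocks recomputed on each of the 8 undecimated
#' Haar sub-band images restricted to the same region (each sub-band
#' rediscretized over its own range).
#'
#' Degenerate regions (constant intensity, or fewer than `min_voxels` voxels)
#' still return a fully dense vector: undefined statistics take their
#' analytic limit where one exists and 0 otherwise, and the vector carries a
#' `"flagged"` attribute naming the region as degenerate.
#'
#' @param volume an [image_volume()].
#' @param region a nonempty [region_mask()] aligned with `volume`.
#' @param schema a [feature_schema()].
#' @return named numeric vector ordered exactly as `schema$feature_names`,
#'   with attributes `schema_version` and `flagged` (logical).
#' @export
extract_features <- function(volume, region, schema = feature_schema()) {
  stopifnot_aligned(volume, region, "volume/region")
  n <- mask_size(region)
  if (n == 0L) stop("extract_features: empty region")
  flagged <- n < schema$min_voxels
  bbox <- mask_bbox(region, pad = 2L)
  img <- crop_array(volume$values, bbox)
  msk <- crop_array(region$values, bbox)
  vv <- prod(volume$spacing_mm)
  ng <- schema$n_bins

  block <- function(values_arr, prefix, include_shape, include_total_energy) {
    x <- values_arr[msk]
    out <- numeric(0)
    if (include_shape && "shape" %in% schema$classes)
      out <- c(out, prefix_names(shape_features(msk, volume$spacing_mm),
                                 prefix, "shape"))
    if ("firstorder" %in% schema$classes)
      out <- c(out, prefix_names(
        firstorder_features(x, vv, ng, include_total_energy), prefix, "firstorder"))
    tex <- intersect(schema$classes, c("glcm", "glrlm", "glszm", "gldm", "ngtdm"))
    if (length(tex)) {
      g <- array(NA_integer_, dim = dim(msk))
      g[msk] <- bin_intensities(x, min(x), max(x), ng)
      for (cl in tex) {
        f <- switch(cl,
                    glcm = glcm_features(g, ng),
                    glrlm = glrlm_features(g, ng),
                    glszm = glszm_features(g, ng),
                    gldm = gldm_features(g, ng),
                    ngtdm = ngtdm_features(g, ng))
        names(f) <- glossary_names(cl)
        out <- c(out, prefix_names(f, prefix, cl))
      }
    }
    out
  }

  out <- block(img, "original", include_shape = TRUE, include_total_energy = TRUE)
  if (schema$wavelet) {
    bands <- wavelet_bands(img)
    for (b in names(bands)) {
      out <- c(out, block(bands[[b]], paste0("wavelet-", b),
                          include_shape = FALSE, include_total_energy = FALSE))
    }
  }
  out <- out[schema$feature_names]
  if (anyNA(out)) {      # degenerate policy net: 0 with flag
    out[is.na(out)] <- 0
    flagged <- TRUE
  }
  names(out) <- schema$feature_names
  attr(out, "schema_version") <- schema$version
  attr(out, "flagged") <- flagged
  out
}

prefix_names <- function(f, prefix, cls) {
  names(f) <- paste0(prefix, "_", cls, "_", names(f))
  f
}

glossary_names <- function(cl) {
  switch(cl, glcm = glcm_feature_names(), glrlm = glrlm_feature_names(),
         glszm = glszm_feature_names(), gldm = gldm_feature_names(),
         ngtdm = c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength"))
}

#' Extract features for a whole cohort
#'
#' One row per subject x region. Region masks smaller than the schema's
#' minimum voxel count are still extracted but flagged in the `flagged`
#' column so downstream selection can exclude them with a logged reason.
#'
#' @param subjects list of subjects; each must have `$id`, `$image`
#'   (an [image_volume()]), `$grade`, `$batch`, and a named list
#'   `$region_masks` of [region_mask()] objects.
#' @param regions character vector naming which of each subject's
#'   `region_masks` to extract (default all of the first subject's).
#' @param schema a [feature_schema()].
#' @return `feature_table` data.frame: metadata columns `subject_id`,
#'   `region`, `grade`, `batch`, `flagged`, then one column per schema
#'   feature.
#' @export
extract_cohort <- function(subjects, regions = NULL, schema = feature_schema()) {
  stopifnot(length(subjects) >= 1)
  if (is.null(regions)) regions <- names(subjects[[1]]$region_masks)
  rows <- list()
  for (s in subjects) {
    for (rg in regions) {
      m <- s$region_masks[[rg]]
      if (is.null(m) || mask_size(m) == 0L) {
        warning("extract_cohort: subject ", s$id, " region ", rg,
                " missing/empty; row flagged with NA features")
        fv <- stats::setNames(rep(NA_real_, length(schema$feature_names)),
                              schema$feature_names)
        fl <- TRUE
      } else {
        fv <- extract_features(s$image, m, schema)
        fl <- attr(fv, "flagged")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s$id, region = rg, grade = s$grade, batch = s$batch,
        flagged = fl, t(as.numeric(fv)))
    }
  }
  out <- do.call(rbind, rows)
  names(out) <- c("subject_id", "region", "grade", "batch", "flagged",
                  schema$feature_names)
  attr(out, "schema_version") <- schema$version
  attr(out, "feature_names") <- schema$feature_names
  class(out) <- c("feature_table", class(out))
  out
}

#' Names of the feature columns of a feature table
#' @param table a `feature_table` (or any data.frame with the metadata
#'   columns first).
#' @return character vector.
#' @export
feature_columns <- function(table) {
  fn <- attr(table, "feature_names")
  if (!is.null(fn)) return(fn)
  setdiff(names(table), c("subject_id", "region", "grade", "batch", "flagged"))
}

#' Write / read a feature table as CSV with a sidecar schema manifest
#'
#' @param table a `feature_table`.
#' @param path CSV path; the manifest goes to `<path>.manifest.json`.
#' @return the path, invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  manifest <- list(schema_version = attr(table, "schema_version"),
                   feature_names = feature_columns(table),
                   n_rows = nrow(table))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE)
  mf <- paste0(path, ".manifest.json")
  if (file.exists(mf)) {
    manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
    attr(out, "schema_version") <- manifest$schema_version
    attr(out, "feature_names") <- manifest$feature_names
  }
  class(out) <- c("feature_table", class(out))
  out
}
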