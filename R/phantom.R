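#' Configuration of the synthetic phantom cohort
#'
#' The generator emulates the structure of a multi-cohort CT grading study:
#' ellipsoidal tumors inside a lung background, each tumor a mixture of two
#' texture-distinct components (a dark "A" core and a brighter "B" shell)
#' whose mixing fraction increases with pathological grade, three acquisition
#' batches that shift extracted features additively and multiplicatively, and
#' 13 clinical features whose Spearman correlation with grade has prescribed
#' signs (the correlation structure reported for density, spiculation,
#' tumor-lung interface and the rest of the standard CT semantic set).
#'
#' @param n_subjects_per_grade subjects per grade (default 50).
#' @param grid_shape voxels per axis (default 36^3).
#' @param spacing_mm physical voxel size (default 1 mm isotropic).
#' @param tumor_radius_range_mm sampling interval for per-axis ellipsoid
#'   radii (default 6-10 mm).
#' @param core_fraction_by_grade named mean fraction of habitat-A voxels per
#'   grade (defaults 0.1 / 0.35 / 0.6); must be strictly increasing.
#' @param core_fraction_sd subject-level SD around the grade mean (0.08).
#' @param habitat_intensity_means intensity levels of components A and B
#'   (HU-like floats, default -80 / 40).
#' @param habitat_texture_scales per-component noise SD (default 20 / 20).
#' @param lung_intensity mean/SD of the lung background (default -700 / 40).
#' @param n_batches number of batches (default 3, >= 2).
#' @param batch_location_shift per-batch additive feature offset, in units of
#'   each feature's SD (first batch is the reference, 0).
#' @param batch_scale_shift per-batch multiplicative factor (reference 1).
#' @param clinical_effect_signs named numeric vector of 13 target Spearman
#'   correlations (sign and rough magnitude) between each clinical feature
#'   and grade.
#' @param habitat_only_signal when TRUE the two component means are shifted
#'   per subject so the whole-tumor mean is constant across grades, and a
#'   random subject-level intensity offset is added: grade then affects only
#'   the habitat mixing, not whole-tumor intensity summaries.
#' @param subject_intensity_jitter_sd SD of that subject-level offset (40).
#' @param seed master random seed.
#' @return list of class `phantom_config`.
#' @export
phantom_config <- function(n_subjects_per_grade = 50L,
                           grid_shape = c(36L, 36L, 36L),
                           spacing_mm = c(1, 1, 1),
                           tumor_radius_range_mm = c(6, 10),
                           core_fraction_by_grade = c(`1` = 0.10, `2` = 0.35, `3` = 0.60),
                           core_fraction_sd = 0.08,
                           habitat_intensity_means = c(A = -80, B = 40),
                           habitat_texture_scales = c(A = 20, B = 20),
                           lung_intensity = c(mean = -700, sd = 40),
                           n_batches = 3L,
                           batch_location_shift = c(0, 0.5, -0.4),
                           batch_scale_shift = c(1, 1.3, 0.8),
                           clinical_effect_signs = default_clinical_signs(),
                           habitat_only_signal = FALSE,
                           subject_intensity_jitter_sd = 40,
                           seed = 1L) {
  cf <- core_fraction_by_grade
  if (length(cf) != 3L || any(cf < 0) || any(cf > 1) || any(diff(cf) <= 0))
    stop("phantom_config: core fractions must lie in [0,1] and strictly increase with grade")
  if (n_batches < 2L) stop("phantom_config: n_batches must be >= 2")
  if (length(batch_location_shift) != n_batches ||
      length(batch_scale_shift) != n_batches)
    stop("phantom_config: batch shift/scale vectors must have n_batches entries")
  if (any(batch_scale_shift <= 0)) stop("phantom_config: scale factors must be > 0")
  if (length(clinical_effect_signs) != 13L || is.null(names(clinical_effect_signs)))
    stop("phantom_config: clinical_effect_signs must be 13 named correlations")
  extent <- grid_shape * rep(spacing_mm, length.out = 3)
  if (max(tumor_radius_range_mm) + 3 + 2 * max(spacing_mm) > min(extent) / 2)
    stop("phantom_config: tumor plus 3 mm margin does not fit in the grid; ",
         "enlarge grid_shape or shrink tumor_radius_range_mm")
  structure(list(
    n_subjects_per_grade = as.integer(n_subjects_per_grade),
    grid_shape = as.integer(grid_shape),
    spacing_mm = rep(as.numeric(spacing_mm), length.out = 3),
    tumor_radius_range_mm = tumor_radius_range_mm,
    core_fraction_by_grade = cf, core_fraction_sd = core_fraction_sd,
    habitat_intensity_means = habitat_intensity_means,
    habitat_texture_scales = habitat_texture_scales,
    lung_intensity = lung_intensity, n_batches = as.integer(n_batches),
    batch_location_shift = batch_location_shift,
    batch_scale_shift = batch_scale_shift,
    clinical_effect_signs = clinical_effect_signs,
    habitat_only_signal = isTRUE(habitat_only_signal),
    subject_intensity_jitter_sd = subject_intensity_jitter_sd,
    seed = as.integer(seed)), class = "phantom_config")
}

#' Default clinical-feature correlation targets
#'
#' Thirteen CT semantic / clinical features with the sign (and approximate
#' magnitude) of their Spearman correlation with grade: density the strongest
#' positive, tumor-lung interface clarity negative, age/position/pleural
#' indentation near zero.
#'
#' @return named numeric vector of length 13.
#' @export
default_clinical_signs <- function() c(
  age = 0.05, size_mm = 0.18, gender = 0.14, smoke = 0.12,
  interface_clear = -0.25, vacuole = -0.13, air_bronchogram = -0.18,
  lobulation = 0.13, spiculation = 0.23, pleural_indentation = 0.03,
  vascular_convergence = 0.08, density = 0.42, position = -0.05)

clinical_feature_types <- function() c(
  age = "continuous", size_mm = "continuous", gender = "binary",
  smoke = "binary", interface_clear = "binary", vacuole = "binary",
  air_bronchogram = "binary", lobulation = "binary", spiculation = "binary",
  pleural_indentation = "binary", vascular_convergence = "binary",
  density = "ordinal3", position = "ordinal7")

#' Sample the clinical feature table for a vector of grades
#'
#' Latent-threshold model: each feature has a grade-loaded latent Gaussian
#' `L = a * z(grade) + sqrt(1 - a^2) * e`, thresholded into binary or ordinal
#' categories (or affinely mapped for continuous features), with loading
#' `a = clamp(1.6 * rho_target, +-0.95)` so the Spearman correlation with
#' grade carries the configured sign.
#'
#' @param grades integer vector of grades (1/2/3).
#' @param signs named target correlations, see [default_clinical_signs()].
#' @param seed integer seed.
#' @return data.frame with 13 clinical columns, one row per grade entry.
#' @export
sample_clinical <- function(grades, signs = default_clinical_signs(), seed = 1L) {
  types <- clinical_feature_types()
  stopifnot(all(names(signs) %in% names(types)))
  n <- length(grades)
  zg <- (grades - mean(grades)) / max(stats::sd(grades), 1e-12)
  with_seed(seed, {
    out <- lapply(names(signs), function(nm) {
      a <- max(min(1.6 * signs[[nm]], 0.95), -0.95)
      lat <- a * zg + sqrt(1 - a^2) * stats::rnorm(n)
      switch(types[[nm]],
             continuous = if (nm == "age") 63 + 8 * lat else exp(log(18) + 0.45 * lat),
             binary = as.integer(lat > 0),
             ordinal3 = as.integer(cut(lat, c(-Inf, stats::qnorm(1 / 3),
                                              stats::qnorm(2 / 3), Inf))),
             ordinal7 = as.integer(cut(lat, c(-Inf, stats::qnorm((1:6) / 7), Inf))))
    })
    names(out) <- names(signs)
    as.data.frame(out)
  })
}

#' Generate a synthetic phantom cohort
#'
#' Deterministic given `config$seed`. Each subject gets: an ellipsoidal tumor
#' (GTV) centered with a small random jitter inside a box-shaped lung mask; a
#' ground-truth habitat labeling (an inner ellipsoid of component A scaled so
#' its voxel fraction matches the subject's grade-dependent core fraction,
#' component B elsewhere in the GTV); Gaussian textures per component and for
#' the lung background; a batch id (balanced across grades); and 13 clinical
#' features from [sample_clinical()].
#'
#' @param config a [phantom_config()].
#' @return list of `phantom_subject` lists with elements `id`, `image`,
#'   `gtv_mask`, `lung_mask`, `true_habitat` (integer array: 0 outside GTV,
#'   1 = A, 2 = B), `grade`, `batch`, `clinical`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  d <- config$grid_shape
  sp <- config$spacing_mm
  n_per <- config$n_subjects_per_grade
  grades <- rep(1:3, each = n_per)
  n <- length(grades)
  # balanced batch assignment within grade, order randomized
  batches <- with_seed(derive_seed(config$seed, "batches"), {
    unlist(lapply(1:3, function(g)
      sample(rep_len(seq_len(config$n_batches), n_per))))
  })
  clinical <- sample_clinical(grades, config$clinical_effect_signs,
                              seed = derive_seed(config$seed, "clinical"))
  # physical voxel-center coordinates
  cx <- (seq_len(d[1]) - 0.5) * sp[1]
  cy <- (seq_len(d[2]) - 0.5) * sp[2]
  cz <- (seq_len(d[3]) - 0.5) * sp[3]
  lung_vals <- array(FALSE, dim = d)
  lung_vals[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- TRUE

  mu <- config$habitat_intensity_means
  tex <- config$habitat_texture_scales
  mu_bar <- mean(mu)

  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    g <- grades[i]
    s <- with_seed(derive_seed(config$seed, paste0("subject", i)), {
      r <- stats::runif(3, config$tumor_radius_range_mm[1],
                        config$tumor_radius_range_mm[2])
      extent <- d * sp
      slack <- pmax(extent / 2 - r - 3 - 2 * max(sp), 0)
      ctr <- extent / 2 + stats::runif(3, -1, 1) * pmin(slack, 1.5)
      fmean <- config$core_fraction_by_grade[[g]]
      f <- if (fmean %in% c(0, 1)) fmean else
        min(max(stats::rnorm(1, fmean, config$core_fraction_sd), 0.02), 0.98)
      e2 <- outer(outer((cx - ctr[1])^2 / r[1]^2, (cy - ctr[2])^2 / r[2]^2, "+"),
                  (cz - ctr[3])^2 / r[3]^2, "+")
      gtv <- e2 <= 1
      if (!any(gtv)) stop("generate_cohort: empty tumor for subject ", i)
      # inner ellipsoid scaled so the A-voxel fraction ~ f
      core <- if (f >= 1) gtv else if (f <= 0) array(FALSE, dim = d) else
        e2 <= f^(2 / 3)
      habitat <- array(0L, dim = d)
      habitat[gtv] <- 2L
      habitat[core] <- 1L
      mu_a <- mu[["A"]]; mu_b <- mu[["B"]]
      sd_a <- tex[["A"]]; sd_b <- tex[["B"]]
      off <- 0
      draw_a <- draw_b <- function(n, m, s) stats::rnorm(n, m, s)
      if (config$habitat_only_signal) {
        # whole-tumor intensity summaries must carry no usable grade signal:
        # center the mixture mean at a fixed level regardless of the mixing
        # fraction, and add per-subject nuisance in component separation,
        # texture scale and noise skewness (inter-patient appearance
        # variability that per-subject clustering adapts to but pooled
        # whole-tumor histogram statistics do not)
        f_real <- sum(core) / sum(gtv)
        sep <- (mu_b - mu_a) * stats::runif(1, 0.6, 1.6)
        mu_a <- mu_bar - (1 - f_real) * sep
        mu_b <- mu_bar + f_real * sep
        sd_a <- sd_a * stats::runif(1, 0.7, 1.5)
        sd_b <- sd_b * stats::runif(1, 0.7, 1.5)
        mk_skewed <- function() {
          shape <- stats::runif(1, 1.5, 8)
          sgn <- sample(c(-1, 1), 1)
          function(n, m, s)
            m + sgn * s * (stats::rgamma(n, shape) - shape) / sqrt(shape)
        }
        draw_a <- mk_skewed(); draw_b <- mk_skewed()
        off <- stats::rnorm(1, 0, config$subject_intensity_jitter_sd)
      }
      img <- array(stats::rnorm(prod(d), config$lung_intensity[["mean"]],
                                config$lung_intensity[["sd"]]), dim = d)
      img[!lung_vals] <- stats::rnorm(sum(!lung_vals), 150, 30)
      nb <- habitat == 2L; na_ <- habitat == 1L
      img[nb] <- draw_b(sum(nb), mu_b, sd_b)
      img[na_] <- draw_a(sum(na_), mu_a, sd_a)
      img <- img + off
      list(id = sprintf("S%04d", i),
           image = image_volume(img, sp),
           gtv_mask = region_mask(gtv, sp),
           lung_mask = region_mask(lung_vals, sp),
           true_habitat = habitat,
           grade = g, batch = batches[i],
           clinical = as.numeric(clinical[i, ]))
    })
    names(s$clinical) <- names(clinical)
    class(s) <- "phantom_subject"
    subjects[[i]] <- s
  }
  subjects
}

#' Clinical table of a generated cohort
#' @param subjects result of [generate_cohort()].
#' @return data.frame with `subject_id`, `grade`, `batch` and the 13 clinical
#'   columns.
#' @export
cohort_clinical_table <- function(subjects) {
  cl <- do.call(rbind, lapply(subjects, function(s) as.data.frame(t(s$clinical))))
  data.frame(subject_id = vapply(subjects, `[[`, "", "id"),
             grade = vapply(subjects, `[[`, 0L, "grade"),
             batch = vapply(subjects, `[[`, 0L, "batch"), cl)
}

#' Write a phantom cohort to disk (NIfTI triplets + cohort CSV)
#' @param subjects result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(subjects, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in subjects) {
    write_volume(s$image, file.path(dir, paste0(s$id, "_image.nii.gz")))
    write_volume(s$gtv_mask, file.path(dir, paste0(s$id, "_gtv.nii.gz")))
    write_volume(s$lung_mask, file.path(dir, paste0(s$id, "_lung.nii.gz")))
  }
  utils::write.csv(cohort_clinical_table(subjects),
                   file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(dir)
}

#' Inject known batch effects into a feature table
#'
#' Affine per-feature, per-batch corruption `value * scale(b,g) + shift(b,g)`
#' built from the configured per-batch parameters: the multiplicative factor
#' acts on the variance around the feature's pre-injection mean, and the
#' additive offset is the configured location shift expressed in units of the
#' feature's pre-injection SD (so shifts are comparable across features of
#' very different scales). Concretely
#' `shift(b,g) = loc_b * sd_g + mean_g * (1 - scale_b)`, which displaces the
#' batch mean by exactly `loc_b * sd_g` and multiplies the batch SD by
#' `scale_b`. The planted ground truth is attached as the `batch_truth`
#' attribute: `location` (the B x G mean displacements, what a harmonizer
#' should recover), `shift` (the literal additive constants) and `scale`.
#'
#' @param table a `feature_table`.
#' @param config a [phantom_config()] supplying the per-batch shift/scale.
#' @return the modified table with attribute `batch_truth`.
#' @export
inject_batch_effects <- function(table, config) {
  fc <- feature_columns(table)
  b <- table$batch
  bad <- which(!b %in% seq_len(config$n_batches))
  if (length(bad))
    stop("inject_batch_effects: unknown batch id '", b[bad[1]], "' in row ", bad[1])
  sds <- vapply(fc, function(g) stats::sd(table[[g]]), 0)
  sds[!is.finite(sds)] <- 0
  mus <- vapply(fc, function(g) mean(table[[g]]), 0)
  location <- outer(config$batch_location_shift, sds)          # B x G
  scale <- matrix(config$batch_scale_shift, config$n_batches, length(fc))
  shift <- location + outer(1 - config$batch_scale_shift, mus)
  colnames(location) <- colnames(shift) <- colnames(scale) <- fc
  for (j in seq_along(fc)) {
    g <- fc[j]
    table[[g]] <- table[[g]] * scale[b, j] + shift[b, j]
  }
  attr(table, "batch_truth") <- list(location = location, shift = shift,
                                     scale = scale)
  table
}
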