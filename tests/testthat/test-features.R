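test_that("the full schema declares exactly 851 uniquely named features", {
  sch <- feature_schema()
  expect_length(sch$feature_names, 851)
  expect_false(anyDuplicated(sch$feature_names) > 0)
  # class bookkeeping: 13 + 19 + 75 original, 8 x 93 wavelet
  orig <- grep("^original_", sch$feature_names, value = TRUE)
  wav <- grep("^wavelet-", sch$feature_names, value = TRUE)
  expect_length(orig, 107)
  expect_length(wav, 744)
  expect_length(grep("^wavelet-LLL_", wav), 93)
})

test_that("first-order statistics match direct-formula oracles", {
  # kurtosis of {1,1,1,5}: fourth standardized moment (Pearson convention)
  fo <- firstorder_features(c(1, 1, 1, 5))
  expect_equal(fo[["Kurtosis"]], 21 / 9)
  expect_equal(fo[["Skewness"]], (sum((c(1, 1, 1, 5) - 2)^3) / 4) / 3^1.5)
  set.seed(10)
  for (rep in 1:10) {
    x <- rnorm(sample(20:200, 1), sample(-50:50, 1), runif(1, 0.5, 30))
    fo <- firstorder_features(x, voxel_volume = 2)
    or <- oracle_firstorder(x)
    expect_equal(fo[["Mean"]], or$mean, tolerance = 1e-12)
    expect_equal(fo[["Variance"]], or$variance, tolerance = 1e-12)
    expect_equal(fo[["Skewness"]], or$skewness, tolerance = 1e-10)
    expect_equal(fo[["Kurtosis"]], or$kurtosis, tolerance = 1e-10)
    expect_equal(fo[["Energy"]], or$energy, tolerance = 1e-10)
    expect_equal(fo[["TotalEnergy"]], 2 * or$energy, tolerance = 1e-10)
    expect_equal(fo[["Entropy"]], or$entropy, tolerance = 1e-10)
    expect_equal(fo[["Uniformity"]], or$uniformity, tolerance = 1e-12)
    expect_equal(fo[["RootMeanSquared"]], or$rms, tolerance = 1e-12)
    expect_equal(fo[["MeanAbsoluteDeviation"]], or$mad, tolerance = 1e-12)
  }
})

test_that("GLCM features agree with a naive pair-enumeration oracle on random regions", {
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0), c(1, -1, 1))
  for (seed in 1:25) {
    fx <- random_region_fixture(seed)
    x <- fx$volume$values[fx$mask$values]
    g <- array(NA_integer_, dim = fx$dims)
    g[fx$mask$values] <- habicat:::bin_intensities(x, min(x), max(x), fx$ng)
    for (k in seq_len(nrow(dirs))) {
      P_or <- oracle_glcm(g, fx$ng, dirs[k, ])
      P_im <- habicat:::glcm_matrix(g, fx$ng, dirs[k, ])
      expect_equal(P_im, P_or, tolerance = 1e-12)
    }
    # feature-level check against features computed from the oracle matrices
    f_or <- rowMeans(vapply(seq_len(nrow(habicat:::directions_13())), function(k)
      habicat:::glcm_features_single(
        oracle_glcm(g, fx$ng, habicat:::directions_13()[k, ])), numeric(24)))
    f_im <- habicat:::glcm_features(g, fx$ng)
    rel <- abs(f_im - f_or) / pmax(abs(f_or), 1e-9)
    expect_lt(max(rel), 1e-6)
  }
})

test_that("GLSZM LargeAreaLowGrayLevelEmphasis matches a hand-computed zone matrix", {
  # single-slice 4x4 region, 3 gray levels:
  #   1 1 2 3
  #   1 2 2 3
  #   3 3 1 1
  #   3 1 1 2
  # 26-connected zones: level 1 {(1,1),(2,1),(1,2)} size 3,
  #   level 2 {(3,1),(2,2),(3,2)} size 3, level 3 {(4,1),(4,2)} size 2,
  #   level 3 {(1,3),(2,3),(1,4)} size 3, level 1 {(3,3),(4,3),(2,4),(3,4)}
  #   size 4, level 2 {(4,4)} size 1
  m <- matrix(c(1, 1, 2, 3,
                1, 2, 2, 3,
                3, 3, 1, 1,
                3, 1, 1, 2), nrow = 4, byrow = TRUE)
  g <- array(NA_integer_, c(4, 4, 1))
  g[, , 1] <- m   # column-major fill: g[x, y, 1] = m[x, y]
  z <- habicat:::glszm_zones(g)
  z <- z[order(z$level, z$size), ]
  expect_equal(z$level, c(1, 1, 2, 2, 3, 3))
  expect_equal(z$size, c(3, 4, 1, 3, 2, 3))
  # LALGLE = sum_ij P(i,j) j^2 / i^2 / Nz, by hand over the 6 zones
  by_hand <- (3^2 / 1 + 4^2 / 1 + 1 / 4 + 3^2 / 4 + 2^2 / 9 + 3^2 / 9) / 6
  f <- habicat:::glszm_features(g, 3L)
  expect_equal(unname(f["LargeAreaLowGrayLevelEmphasis"]), by_hand,
               tolerance = 1e-12)
  # zone percentage: 6 zones / 16 voxels
  expect_equal(unname(f["ZonePercentage"]), 6 / 16)
})

test_that("GLRLM runs match a hand-enumerated single-row example", {
  # one row: 1 1 1 2 2 3 1 -> runs along x: (1,3) (2,2) (3,1) (1,1)
  g <- array(NA_integer_, c(7, 1, 1))
  g[, 1, 1] <- c(1L, 1L, 1L, 2L, 2L, 3L, 1L)
  P <- habicat:::glrlm_matrix(g, 3L, c(1L, 0L, 0L))
  expect_equal(P[1, 3], 1)  # one run of level 1 length 3
  expect_equal(P[2, 2], 1)
  expect_equal(P[3, 1], 1)
  expect_equal(P[1, 1], 1)
  expect_equal(sum(P), 4)
  # gaps break runs: masking the middle voxel splits a run
  g2 <- array(NA_integer_, c(5, 1, 1))
  g2[, 1, 1] <- c(1L, 1L, NA, 1L, 1L)
  P2 <- habicat:::glrlm_matrix(g2, 1L, c(1L, 0L, 0L))
  expect_equal(P2[1, 2], 2)
})

test_that("constant-intensity cube has the analytic shape and zero-texture signature", {
  d <- c(14, 14, 14)
  img <- image_volume(array(0, d))
  img$values[4:9, 4:9, 4:9] <- 7
  msk <- region_mask(img$values == 7)
  fv <- extract_features(img, msk, reduced_schema())
  expect_equal(fv[["original_shape_Sphericity"]],
               pi^(1 / 3) * 6^(2 / 3) / 6, tolerance = 1e-12)
  expect_equal(fv[["original_shape_VoxelVolume"]], 216)
  expect_equal(fv[["original_shape_SurfaceArea"]], 6 * 36)
  expect_equal(fv[["original_firstorder_Entropy"]], 0, tolerance = 1e-12)
  expect_equal(fv[["original_glcm_Contrast"]], 0)
  expect_equal(fv[["original_firstorder_Variance"]], 0)
  # maximum 3D diameter of a 6-voxel cube: body diagonal of 5-voxel span
  expect_equal(fv[["original_shape_Maximum3DDiameter"]], sqrt(75))
})

test_that("features are invariant to region translation and intensity shift", {
  set.seed(33)
  d <- c(16, 16, 16)
  base <- array(rnorm(prod(d), 40, 15), d)
  msk1 <- array(FALSE, d); msk1[3:8, 3:9, 3:8] <- TRUE
  img1 <- image_volume(base)
  sch <- feature_schema(wavelet = FALSE)   # original-image block
  f1 <- extract_features(img1, region_mask(msk1), sch)
  # translate region and its contents by (4, 3, 5)
  img2v <- array(rnorm(prod(d), 40, 15), d)
  img2v[7:12, 6:12, 8:13] <- base[3:8, 3:9, 3:8]
  msk2 <- array(FALSE, d); msk2[7:12, 6:12, 8:13] <- TRUE
  f2 <- extract_features(image_volume(img2v), region_mask(msk2), sch)
  expect_equal(unclass(f1), unclass(f2), tolerance = 1e-9,
               ignore_attr = TRUE)
  # intensity shift leaves every discretized texture feature unchanged
  f3 <- extract_features(image_volume(base + 500), region_mask(msk1), sch)
  tex <- grep("glcm|glrlm|glszm|gldm|ngtdm", sch$feature_names, value = TRUE)
  expect_equal(f1[tex], f3[tex], tolerance = 1e-9)
})

test_that("wavelet sub-bands behave like separable Haar filters", {
  set.seed(2)
  a <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  b <- wavelet_bands(a)
  expect_named(b, c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH"))
  # constant image: every band with any H vanishes, LLL = 2^(3/2) * const
  cst <- wavelet_bands(array(3, c(4, 4, 4)))
  expect_equal(max(abs(cst$HHH)), 0)
  expect_equal(max(abs(cst$LLH)), 0)
  expect_equal(cst$LLL[1, 1, 1], 3 * 2^(3 / 2))
  # energy conservation of the 1-D pair: L^2 + H^2 = x_i^2 + x_{i+1}^2 pairwise
  x <- a[, 1, 1]
  L <- habicat:::haar_axis(a, 1, "L")[, 1, 1]
  H <- habicat:::haar_axis(a, 1, "H")[, 1, 1]
  xs <- c(x[-1], x[length(x)])
  expect_equal(L^2 + H^2, x^2 + xs^2, tolerance = 1e-12)
})

test_that("cohort extraction yields subjects x regions x 851 with deterministic rows", {
  subs <- generate_cohort(test_phantom_config(n_per = 1L, seed = 21L))
  subs <- lapply(subs, function(s) {
    s$region_masks <- list(WVOI = s$gtv_mask,
                           H1 = region_mask(s$true_habitat == 2L, s$image$spacing_mm),
                           H2 = region_mask(s$true_habitat == 1L, s$image$spacing_mm))
    s
  })
  tab <- extract_cohort(subs, schema = feature_schema())
  expect_equal(nrow(tab), 3 * 3)
  expect_length(feature_columns(tab), 851)
  expect_false(anyNA(tab[, feature_columns(tab)]))
  # identical duplicate subject gives identical rows
  dup <- subs[c(1, 1)]
  dup[[2]]$id <- "copy"
  tab2 <- extract_cohort(dup, schema = reduced_schema())
  expect_equal(unname(as.matrix(tab2[1:3, feature_columns(tab2)])),
               unname(as.matrix(tab2[4:6, feature_columns(tab2)])))
  # shuffled subject order gives the same table up to row order
  tab3 <- extract_cohort(rev(subs), schema = reduced_schema())
  tab4 <- extract_cohort(subs, schema = reduced_schema())
  key <- function(t) t[order(t$subject_id, t$region), c("subject_id", "region",
                                                        feature_columns(t))]
  expect_equal(key(tab3), key(tab4), ignore_attr = TRUE)
})

test_that("small regions are flagged and CSV round trip preserves the table", {
  d <- c(8, 8, 8)
  img <- image_volume(array(rnorm(prod(d)), d))
  m <- array(FALSE, d); m[4, 4, 4:6] <- TRUE
  fv <- extract_features(img, region_mask(m), reduced_schema())
  expect_true(attr(fv, "flagged"))
  expect_false(anyNA(fv))
  subs <- list(list(id = "a", image = img, grade = 1L, batch = 1L,
                    region_masks = list(WVOI = region_mask(m))))
  tab <- extract_cohort(subs, schema = reduced_schema())
  expect_true(tab$flagged[1])
  tmp <- tempfile(fileext = ".csv")
  write_feature_table(tab, tmp)
  back <- read_feature_table(tmp)
  expect_equal(feature_columns(back), feature_columns(tab))
  expect_equal(as.matrix(back[, feature_columns(back)]),
               as.matrix(tab[, feature_columns(tab)]), tolerance = 1e-12)
})
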