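# Independent brute-force oracles and small fixture builders. Everything here
# is deliberately naive (loops, direct formulas) and shares no code with the
# package's vectorized implementations.

# naive symmetric GLCM for one direction by explicit voxel loops
oracle_glcm <- function(g, ng, o) {
  d <- dim(g)
  P <- matrix(0, ng, ng)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- g[x, y, z]
    if (is.na(a)) next
    nx <- x + o[1]; nyy <- y + o[2]; nz <- z + o[3]
    if (nx < 1 || nx > d[1] || nyy < 1 || nyy > d[2] || nz < 1 || nz > d[3]) next
    b <- g[nx, nyy, nz]
    if (is.na(b)) next
    P[a, b] <- P[a, b] + 1
    P[b, a] <- P[b, a] + 1
  }
  P
}

# direct-formula first-order statistics (population moments, Pearson kurtosis)
oracle_firstorder <- function(x, n_bins = 25L) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  # histogram over [min, max] with n_bins equal bins
  lo <- min(x); hi <- max(x)
  if (hi > lo) {
    b <- pmin(floor((x - lo) / (hi - lo) * n_bins) + 1, n_bins)
  } else b <- rep(1, n)
  p <- as.numeric(table(factor(b, levels = 1:n_bins))) / n
  list(mean = m, variance = m2, sd = sqrt(m2),
       skewness = if (m2 > 0) (sum((x - m)^3) / n) / m2^1.5 else 0,
       kurtosis = if (m2 > 0) (sum((x - m)^4) / n) / m2^2 else 0,
       energy = sum(x^2),
       entropy = -sum(p * log2(p + 2.2e-16)),
       uniformity = sum(p^2),
       rms = sqrt(sum(x^2) / n),
       mad = sum(abs(x - m)) / n)
}

# brute-force silhouette: textbook definition, O(n^2) loops
oracle_silhouette <- function(X, labels) {
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    di <- sqrt(rowSums((X - matrix(X[i, ], n, ncol(X), byrow = TRUE))^2))
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(di[own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(di[labels == l]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

oracle_davies_bouldin <- function(X, labels) {
  ks <- sort(unique(labels))
  cen <- lapply(ks, function(k) colMeans(X[labels == k, , drop = FALSE]))
  sc <- vapply(seq_along(ks), function(j) {
    pts <- X[labels == ks[j], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2, cen[[j]])^2)))
  }, 0)
  mean(vapply(seq_along(ks), function(i) {
    max(vapply(setdiff(seq_along(ks), i), function(j) {
      (sc[i] + sc[j]) / sqrt(sum((cen[[i]] - cen[[j]])^2))
    }, 0))
  }, 0))
}

# trapezoidal ROC integration as a second AUC estimator
oracle_auc_trapezoid <- function(scores, y) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(scores[y == 1] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[y == 0] >= t), 0)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nc2 <- choose(sum(tab), 2)
  expected <- ai * bj / nc2
  (nij - expected) / ((ai + bj) / 2 - expected)
}

# tiny random image+region pair for feature cross-checks
random_region_fixture <- function(seed, dmax = 9L, ng = 8L) {
  set.seed(seed)
  d <- sample(4:dmax, 3, replace = TRUE)
  img <- array(rnorm(prod(d), 50, 20), dim = d)
  msk <- array(runif(prod(d)) < 0.7, dim = d)
  if (sum(msk) < 8) msk[sample(prod(d), 8)] <- TRUE
  list(volume = habicat::image_volume(img),
       mask = habicat::region_mask(msk), dims = d, ng = ng)
}

# super-voxel table from 2-D points (for clustering metric tests)
sv_from_points <- function(x1, x2, raw = x1) {
  df <- data.frame(x = seq_along(x1), y = 1L, z = 1L,
                   intensity = raw, entropy = x2,
                   z_intensity = as.numeric(scale(x1)),
                   z_entropy = as.numeric(scale(x2)))
  attr(df, "grid_dim") <- c(length(x1), 1L, 1L)
  class(df) <- c("supervoxel_table", class(df))
  df
}

# two well-separated gaussian blobs as a super-voxel table
two_gaussian_sv <- function(n_per = 120L, sep = 4, seed = 1L) {
  set.seed(seed)
  x1 <- c(rnorm(n_per, 0), rnorm(n_per, sep))
  x2 <- c(rnorm(n_per, 0), rnorm(n_per, sep))
  sv_from_points(x1, x2)
}

# small phantom config for fast tests
test_phantom_config <- function(n_per = 10L, seed = 1L, ...) {
  habicat::phantom_config(n_subjects_per_grade = n_per,
                          grid_shape = c(28L, 28L, 28L),
                          tumor_radius_range_mm = c(5, 8),
                          seed = seed, ...)
}

# phantoms whose lung mask equals the GTV, so the WVOI is exactly the tumor
# (used to probe habitat recovery without the peritumoral ring population)
tumor_only_subject <- function(subject) {
  subject$lung_mask <- subject$gtv_mask
  subject
}

reduced_schema <- function() {
  habicat::feature_schema(classes = c("shape", "firstorder", "glcm"),
                          wavelet = FALSE)
}
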