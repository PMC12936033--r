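#' Entropy-map configuration
#'
#' @param n_bins number of equal-width intensity bins over the WVOI-wide
#'   min-max range (default 25, the common CT choice).
#' @param epsilon small positive constant added inside the log so empty and
#'   single-bin histograms behave (default `.Machine$double.eps`, about
#'   2.2e-16).
#' @param kernel_radius_voxels half-width of the cubic neighborhood used for
#'   the voxel-wise histogram (default 1, i.e. a 3x3x3 kernel).
#' @return list of class `entropy_config`.
#' @export
entropy_config <- function(n_bins = 25L, epsilon = .Machine$double.eps,
                           kernel_radius_voxels = 1L) {
  stopifnot(n_bins >= 2, epsilon > 0, kernel_radius_voxels >= 1)
  structure(list(n_bins = as.integer(n_bins), epsilon = epsilon,
                 kernel_radius_voxels = as.integer(kernel_radius_voxels)),
            class = "entropy_config")
}

# bin intensities into 1..n_bins equal-width bins over [lo, hi]
bin_intensities <- function(x, lo, hi, n_bins) {
  if (hi <= lo) return(rep(1L, length(x)))   # constant region: one bin
  b <- floor((x - lo) / (hi - lo) * n_bins) + 1L
  pmin(pmax(as.integer(b), 1L), n_bins)
}

#' Voxel-wise first-order entropy map
#'
#' For every voxel of the WVOI, forms the histogram of intensities in its
#' cubic kernel neighborhood (restricted to WVOI voxels) using `n_bins`
#' equal-width bins spanning the WVOI-wide intensity range shared by all
#' kernels, normalizes it to probabilities p(i), and computes the Shannon
#' entropy in bits,
#'   H = -sum_i p(i) * log2(p(i) + epsilon).
#' A constant WVOI yields entropies ~ 0 everywhere.
#'
#' @param volume an [image_volume()].
#' @param wvoi [region_mask()] of the whole volume of interest.
#' @param cfg an [entropy_config()].
#' @return list of class `entropy_map`: `values` (numeric array, NA outside
#'   the WVOI), `config`.
#' @export
entropy_map <- function(volume, wvoi, cfg = entropy_config()) {
  stopifnot_aligned(volume, wvoi, "volume/wvoi")
  if (!any(wvoi$values)) stop("entropy_map: empty WVOI")
  d <- dim(volume$values)
  inside <- wvoi$values
  v <- volume$values[inside]
  bins_full <- array(NA_integer_, dim = d)
  bins_full[inside] <- bin_intensities(v, min(v), max(v), cfg$n_bins)

  n_in <- sum(inside)
  row_of <- array(NA_integer_, dim = d)
  row_of[inside] <- seq_len(n_in)
  counts <- matrix(0L, nrow = n_in, ncol = cfg$n_bins)
  r <- cfg$kernel_radius_voxels
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
    if (abs(dx) >= d[1] || abs(dy) >= d[2] || abs(dz) >= d[3]) next
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
    ctr <- array(FALSE, dim = d); ctr[xs, ys, zs] <- TRUE
    ctr <- ctr & inside
    nb_bin <- array(NA_integer_, dim = d)
    nb_bin[xs, ys, zs] <- bins_full[xs - dx, ys - dy, zs - dz]
    sel <- ctr & !is.na(nb_bin)
    if (!any(sel)) next
    ij <- cbind(row_of[sel], nb_bin[sel])
    counts[ij] <- counts[ij] + 1L
  }
  p <- counts / rowSums(counts)
  ent <- -rowSums(p * log2(p + cfg$epsilon))
  vals <- array(NA_real_, dim = d)
  vals[inside] <- ent
  structure(list(values = vals, config = cfg), class = "entropy_map")
}

#' Build the super-voxel table for habitat clustering
#'
#' One row per WVOI voxel with its raw gray-level intensity and voxel-wise
#' first-order entropy, plus both channels z-standardized across the WVOI
#' (zero-variance channels map to 0). The standardized columns feed K-means;
#' the raw intensity column is kept for ranking habitats by brightness.
#'
#' @param volume an [image_volume()].
#' @param emap an [entropy_map()] computed on the same WVOI.
#' @param wvoi the WVOI [region_mask()].
#' @return data.frame of class `supervoxel_table` with columns `x`, `y`, `z`,
#'   `intensity`, `entropy`, `z_intensity`, `z_entropy`; attributes
#'   `standardization` (means/sds) and `dim`.
#' @export
build_supervoxels <- function(volume, emap, wvoi) {
  stopifnot_aligned(volume, wvoi, "volume/wvoi")
  idx <- mask_coords(wvoi)
  inten <- volume$values[idx]
  ent <- emap$values[idx]
  if (anyNA(ent)) stop("build_supervoxels: entropy map does not cover the WVOI")
  zstd <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  out <- data.frame(x = idx[, 1], y = idx[, 2], z = idx[, 3],
                    intensity = inten, entropy = ent,
                    z_intensity = zstd(inten), z_entropy = zstd(ent))
  attr(out, "standardization") <- list(
    mean = c(intensity = mean(inten), entropy = mean(ent)),
    sd = c(intensity = stats::sd(inten), entropy = stats::sd(ent)))
  attr(out, "grid_dim") <- dim(volume$values)
  class(out) <- c("supervoxel_table", class(out))
  out
}

#' Cluster super-voxels into habitats
#'
#' K-means (k-means++ style multiple random restarts via `nstart`) on the
#' standardized (intensity, entropy) channels. Clusters are relabeled by
#' descending mean raw intensity so habitat 1 is always the brightest; ties
#' break by original cluster index.
#'
#' @param sv a [build_supervoxels()] table.
#' @param k number of clusters (>= 2).
#' @param seed integer seed; all restarts derive from it.
#' @param nstart random restarts (default 10).
#' @return list of class `habitat_labeling`: `k`, `labels` (per row of `sv`),
#'   `cluster_mean_intensity`, `seed`.
#' @export
cluster_habitats <- function(sv, k = 2L, seed = 1L, nstart = 10L) {
  stopifnot(k >= 2)
  X <- as.matrix(sv[, c("z_intensity", "z_entropy")])
  if (nrow(X) < k) stop("cluster_habitats: fewer super-voxels (", nrow(X),
                        ") than clusters (", k, ")")
  km <- with_seed(seed, suppressWarnings(
    stats::kmeans(X, centers = k, nstart = nstart, iter.max = 100L)))
  mean_int <- vapply(seq_len(k), function(j) mean(sv$intensity[km$cluster == j]), 0)
  ord <- order(-mean_int, seq_len(k))   # brightest first, ties by index
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  structure(list(k = as.integer(k), labels = relabel[km$cluster],
                 cluster_mean_intensity = mean_int[ord], seed = seed),
            class = "habitat_labeling")
}

#' Habitat labeling as a label volume
#'
#' @param labeling a [cluster_habitats()] result.
#' @param sv the super-voxel table it was fit on.
#' @return integer array (0 outside the WVOI, habitat index inside).
#' @export
habitat_label_volume <- function(labeling, sv) {
  d <- attr(sv, "grid_dim")
  out <- array(0L, dim = d)
  out[cbind(sv$x, sv$y, sv$z)] <- labeling$labels
  out
}

#' Mean silhouette score
#'
#' Standard silhouette over Euclidean distances; singleton-cluster points get
#' silhouette 0 (logged via a `singletons` attribute).
#'
#' @param X numeric matrix of points.
#' @param labels integer cluster labels.
#' @return mean silhouette in `[-1, 1]`.
#' @export
silhouette_mean <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  ks <- sort(unique(labels))
  if (length(ks) < 2L) stop("silhouette_mean: need >= 2 clusters")
  D <- as.matrix(stats::dist(X))
  sizes <- table(factor(labels, levels = ks))
  s <- numeric(n)
  # mean distance from each point to each cluster
  md <- vapply(ks, function(kk) rowMeans(D[, labels == kk, drop = FALSE]), numeric(n))
  for (i in seq_len(n)) {
    own <- match(labels[i], ks)
    ni <- sizes[[own]]
    if (ni <= 1L) { s[i] <- 0; next }             # singleton guard
    a <- md[i, own] * ni / (ni - 1)               # exclude self
    b <- min(md[i, -own])
    s[i] <- (b - a) / max(a, b)
  }
  out <- mean(s)
  attr(out, "singletons") <- sum(sizes == 1L)
  out
}

#' Davies-Bouldin index
#'
#' Lower is better. Coincident clusters (zero centroid separation) return a
#' large sentinel (1e12) so a degenerate solution is never preferred.
#'
#' @inheritParams silhouette_mean
#' @return nonnegative scalar.
#' @export
davies_bouldin <- function(X, labels) {
  X <- as.matrix(X)
  ks <- sort(unique(labels))
  K <- length(ks)
  if (K < 2L) stop("davies_bouldin: need >= 2 clusters")
  cen <- t(vapply(ks, function(kk) colMeans(X[labels == kk, , drop = FALSE]),
                  numeric(ncol(X))))
  sc <- vapply(seq_len(K), function(j) {
    pts <- X[labels == ks[j], , drop = FALSE]
    mean(sqrt(rowSums((pts - matrix(cen[j, ], nrow(pts), ncol(X), byrow = TRUE))^2)))
  }, 0)
  r <- numeric(K)
  for (i in seq_len(K)) {
    rij <- vapply(setdiff(seq_len(K), i), function(j) {
      sep <- sqrt(sum((cen[i, ] - cen[j, ])^2))
      if (sep == 0) 1e12 else (sc[i] + sc[j]) / sep
    }, 0)
    r[i] <- max(rij)
  }
  mean(pmin(r, 1e12))
}

#' Select the number of habitats across a cohort
#'
#' Clusters every subject's super-voxel table at each candidate k, computes
#' the per-subject mean silhouette and Davies-Bouldin index (on a random
#' subsample of at most `max_metric_points` voxels for tractability), averages
#' them over the cohort, and picks the k with the best (highest) mean
#' silhouette. When silhouette and DB disagree, silhouette wins and the
#' disagreement is recorded in the returned table's `disagreement` attribute.
#'
#' @param sv_list list of super-voxel tables (one per subject).
#' @param candidates integer vector of candidate k (default 2:4).
#' @param seed integer seed.
#' @param max_metric_points subsample cap for the O(n^2) metrics.
#' @return list: `k` (selected), `metrics` (data.frame k, silhouette, db),
#'   `labelings` (per subject, at the selected k).
#' @export
select_k <- function(sv_list, candidates = 2:4, seed = 1L,
                     max_metric_points = 1000L) {
  stopifnot(length(candidates) >= 1)
  res <- lapply(candidates, function(k) {
    per <- vapply(seq_along(sv_list), function(i) {
      sv <- sv_list[[i]]
      lab <- cluster_habitats(sv, k = k, seed = derive_seed(seed, paste0("k", k, "s", i)))
      X <- as.matrix(sv[, c("z_intensity", "z_entropy")])
      l <- lab$labels
      if (nrow(X) > max_metric_points) {
        keep <- with_seed(derive_seed(seed, paste0("sub", k, "s", i)),
                          sample.int(nrow(X), max_metric_points))
        # keep all clusters represented
        if (length(unique(l[keep])) < k) keep <- seq_len(nrow(X))
        X <- X[keep, , drop = FALSE]; l <- l[keep]
      }
      c(sil = as.numeric(silhouette_mean(X, l)), db = davies_bouldin(X, l))
    }, c(sil = 0, db = 0))
    c(silhouette = mean(per["sil", ]), db = mean(per["db", ]))
  })
  metrics <- data.frame(k = candidates,
                        silhouette = vapply(res, `[[`, 0, "silhouette"),
                        db = vapply(res, `[[`, 0, "db"))
  k_sil <- metrics$k[which.max(metrics$silhouette)]
  k_db <- metrics$k[which.min(metrics$db)]
  attr(metrics, "disagreement") <- k_sil != k_db
  if (k_sil != k_db)
    message("select_k: silhouette prefers k=", k_sil, " but DB prefers k=", k_db,
            "; using silhouette")
  labelings <- lapply(seq_along(sv_list), function(i)
    cluster_habitats(sv_list[[i]], k = k_sil,
                     seed = derive_seed(seed, paste0("k", k_sil, "s", i))))
  list(k = k_sil, metrics = metrics, labelings = labelings)
}
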