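# Gray-level texture matrices and their features.
#
# All families operate on a cropped integer gray-level array `g` (NA outside
# the region) produced by fixed-bin-count discretization over the region's
# intensity range, with 26-connectivity neighborhoods (13 unique 3-D
# directions and their opposites). GLCM and GLRLM are computed per direction
# and their feature values averaged across the 13 directions; GLSZM, GLDM
# and NGTDM are single-matrix families by construction.

# the 13 unique 3-D direction offsets (lexicographically positive half of 26)
directions_13 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- apply(g, 1, function(o) {
    nz <- which(o != 0)
    length(nz) > 0 && o[nz[1]] > 0
  })
  unname(g[keep, , drop = FALSE])
}

# gray-level pairs (a = center, b = neighbor at offset o) with both in-region
neighbor_pairs <- function(g, o) {
  d <- dim(g)
  if (any(abs(o) >= d)) return(list(a = integer(0), b = integer(0)))
  xs <- max(1, 1 + o[1]):min(d[1], d[1] + o[1])
  ys <- max(1, 1 + o[2]):min(d[2], d[2] + o[2])
  zs <- max(1, 1 + o[3]):min(d[3], d[3] + o[3])
  a <- g[xs, ys, zs]
  b <- g[xs - o[1], ys - o[2], zs - o[3]]
  ok <- !is.na(a) & !is.na(b)
  list(a = a[ok], b = b[ok])
}

# ---- GLCM --------------------------------------------------------------

glcm_matrix <- function(g, ng, o) {
  pr <- neighbor_pairs(g, o)
  cnt <- matrix(tabulate((pr$b - 1L) * ng + pr$a, ng * ng), ng, ng)
  cnt + t(cnt)    # symmetric co-occurrence
}

glcm_features_single <- function(P) {
  ng <- nrow(P)
  s <- sum(P)
  if (s == 0) return(stats::setNames(rep(0, 24), glcm_feature_names()))
  p <- P / s
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum((1:ng) * px); muy <- sum((1:ng) * py)
  sx <- sqrt(sum(((1:ng) - mux)^2 * px)); sy <- sqrt(sum(((1:ng) - muy)^2 * py))
  # diagonal / cross-diagonal distributions
  kx <- 0:(ng - 1)
  pxmy <- vapply(kx, function(k) sum(p[abs(i - j) == k]), 0)
  ks <- 2:(2 * ng)
  pxpy <- vapply(ks, function(k) sum(p[(i + j) == k]), 0)
  da <- sum(kx * pxmy)
  hxy <- -sum(p * log2(p + EPS_LOG))
  hx <- -sum(px * log2(px + EPS_LOG)); hy <- -sum(py * log2(py + EPS_LOG))
  pxy <- px %o% py
  hxy1 <- -sum(p * log2(pxy + EPS_LOG))
  hxy2 <- -sum(pxy * log2(pxy + EPS_LOG))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0
  corr <- if (sx > 0 && sy > 0) (sum(i * j * p) - mux * muy) / (sx * sy) else 1
  # MCC: sqrt of second-largest eigenvalue of Q
  nzr <- which(px > 0)
  mcc <- if (length(nzr) < 2L) 1 else {
    pr <- p[nzr, nzr, drop = FALSE]
    # Q(a,b) = sum_k p(a,k) p(b,k) / (px(a) py(k))
    Q <- sweep(pr, 1, px[nzr], "/") %*% t(sweep(pr, 2, py[nzr], "/"))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, min(ev[2], 1)))
  }
  c(Autocorrelation = sum(i * j * p),
    ClusterProminence = sum((i + j - mux - muy)^4 * p),
    ClusterShade = sum((i + j - mux - muy)^3 * p),
    ClusterTendency = sum((i + j - mux - muy)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pxmy * log2(pxmy + EPS_LOG)),
    DifferenceVariance = sum((kx - da)^2 * pxmy),
    Id = sum(pxmy / (1 + kx)),
    Idm = sum(pxmy / (1 + kx^2)),
    Idmn = sum(pxmy / (1 + (kx / ng)^2)),
    Idn = sum(pxmy / (1 + kx / ng)),
    Imc1 = imc1, Imc2 = imc2,
    InverseVariance = if (ng > 1) sum(pxmy[-1] / kx[-1]^2) else 0,
    JointAverage = mux,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MaximumProbability = max(p),
    MCC = mcc,
    SumAverage = sum(ks * pxpy),
    SumEntropy = -sum(pxpy * log2(pxpy + EPS_LOG)),
    SumSquares = sum((i - mux)^2 * p))
}

glcm_features <- function(g, ng) {
  dirs <- directions_13()
  f <- vapply(seq_len(nrow(dirs)), function(k)
    glcm_features_single(glcm_matrix(g, ng, dirs[k, ])), numeric(24))
  rowMeans(f)
}

# ---- GLRLM -------------------------------------------------------------

# run-length matrix for one direction: rows gray level, cols run length
glrlm_matrix <- function(g, ng, o) {
  d <- dim(g)
  idx <- which(!is.na(g), arr.ind = TRUE)
  gv <- g[!is.na(g)]
  ax <- which(o != 0)[1]                 # parameter axis: unit step in t
  t <- idx[, ax] * o[ax]                 # increases by 1 along the direction
  line <- idx - outer(t, o)              # constant along the direction
  M <- max(d) * 3 + 2
  key <- ((line[, 1] + M) * (2 * M) + (line[, 2] + M)) * (2 * M) + (line[, 3] + M)
  ord <- order(key, t)
  gk <- gv[ord]; kk <- key[ord]; tt <- t[ord]
  n <- length(gk)
  if (n == 0L) return(matrix(0, ng, 1))
  newrun <- c(TRUE, kk[-1] != kk[-n] | tt[-1] != tt[-n] + 1 | gk[-1] != gk[-n])
  run_id <- cumsum(newrun)
  len <- tabulate(run_id)
  lev <- gk[newrun]
  lmax <- max(len)
  matrix(tabulate((len - 1L) * ng + lev, ng * lmax), ng, lmax)
}

glrlm_features_single <- function(P, np) {
  ng <- nrow(P); lmax <- ncol(P)
  nr <- sum(P)
  if (nr == 0) return(stats::setNames(rep(0, 16), glrlm_feature_names()))
  i <- row(P); l <- col(P)
  p <- P / nr
  mu_i <- sum(i * p); mu_l <- sum(l * p)
  c(ShortRunEmphasis = sum(P / l^2) / nr,
    LongRunEmphasis = sum(P * l^2) / nr,
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nr,
    GrayLevelNonUniformityNormalized = sum(rowSums(P)^2) / nr^2,
    RunLengthNonUniformity = sum(colSums(P)^2) / nr,
    RunLengthNonUniformityNormalized = sum(colSums(P)^2) / nr^2,
    RunPercentage = nr / np,
    GrayLevelVariance = sum((i - mu_i)^2 * p),
    RunVariance = sum((l - mu_l)^2 * p),
    RunEntropy = -sum(p * log2(p + EPS_LOG)),
    LowGrayLevelRunEmphasis = sum(P / i^2) / nr,
    HighGrayLevelRunEmphasis = sum(P * i^2) / nr,
    ShortRunLowGrayLevelEmphasis = sum(P / (i^2 * l^2)) / nr,
    ShortRunHighGrayLevelEmphasis = sum(P * i^2 / l^2) / nr,
    LongRunLowGrayLevelEmphasis = sum(P * l^2 / i^2) / nr,
    LongRunHighGrayLevelEmphasis = sum(P * i^2 * l^2) / nr)
}

glrlm_features <- function(g, ng) {
  np <- sum(!is.na(g))
  dirs <- directions_13()
  f <- vapply(seq_len(nrow(dirs)), function(k)
    glrlm_features_single(glrlm_matrix(g, ng, dirs[k, ]), np), numeric(16))
  rowMeans(f)
}

# ---- GLSZM -------------------------------------------------------------

# size-zone matrix: zones are 26-connected components of equal gray level
glszm_zones <- function(g) {
  d <- dim(g)
  in_reg <- !is.na(g)
  n <- sum(in_reg)
  row_of <- array(NA_integer_, dim = d)
  row_of[in_reg] <- seq_len(n)
  dirs <- directions_13()
  ea <- integer(0); eb <- integer(0)
  for (k in seq_len(nrow(dirs))) {
    o <- dirs[k, ]
    if (any(abs(o) >= d)) next
    xs <- max(1, 1 + o[1]):min(d[1], d[1] + o[1])
    ys <- max(1, 1 + o[2]):min(d[2], d[2] + o[2])
    zs <- max(1, 1 + o[3]):min(d[3], d[3] + o[3])
    a <- g[xs, ys, zs]; b <- g[xs - o[1], ys - o[2], zs - o[3]]
    ra <- row_of[xs, ys, zs]
    rb_full <- array(row_of[xs - o[1], ys - o[2], zs - o[3]],
                     dim = dim(ra))
    ok <- !is.na(a) & !is.na(b) & a == b
    ea <- c(ea, ra[ok]); eb <- c(eb, rb_full[ok])
  }
  gr <- igraph::make_graph(edges = rbind(ea, eb), n = n, directed = FALSE)
  memb <- igraph::components(gr)$membership
  lev <- g[in_reg]
  data.frame(level = lev[!duplicated(memb)][order(unique(memb))],
             size = as.integer(table(memb)))
}

glszm_matrix <- function(g, ng) {
  z <- glszm_zones(g)
  smax <- max(z$size)
  matrix(tabulate((z$size - 1L) * ng + z$level, ng * smax), ng, smax)
}

glszm_features <- function(g, ng) {
  P <- glszm_matrix(g, ng)
  np <- sum(!is.na(g))
  nz <- sum(P)
  nm <- glszm_feature_names()
  if (nz == 0) return(stats::setNames(rep(0, 16), nm))
  i <- row(P); j <- col(P)
  p <- P / nz
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  stats::setNames(c(
    sum(P / j^2) / nz,                       # SmallAreaEmphasis
    sum(P * j^2) / nz,                       # LargeAreaEmphasis
    sum(rowSums(P)^2) / nz,                  # GrayLevelNonUniformity
    sum(rowSums(P)^2) / nz^2,                # GrayLevelNonUniformityNormalized
    sum(colSums(P)^2) / nz,                  # SizeZoneNonUniformity
    sum(colSums(P)^2) / nz^2,                # SizeZoneNonUniformityNormalized
    nz / np,                                 # ZonePercentage
    sum((i - mu_i)^2 * p),                   # GrayLevelVariance
    sum((j - mu_j)^2 * p),                   # ZoneVariance
    -sum(p * log2(p + EPS_LOG)),             # ZoneEntropy
    sum(P / i^2) / nz,                       # LowGrayLevelZoneEmphasis
    sum(P * i^2) / nz,                       # HighGrayLevelZoneEmphasis
    sum(P / (i^2 * j^2)) / nz,               # SmallAreaLowGrayLevelEmphasis
    sum(P * i^2 / j^2) / nz,                 # SmallAreaHighGrayLevelEmphasis
    sum(P * j^2 / i^2) / nz,                 # LargeAreaLowGrayLevelEmphasis
    sum(P * i^2 * j^2) / nz), nm)            # LargeAreaHighGrayLevelEmphasis
}

# ---- GLDM --------------------------------------------------------------

# dependence counts: number of 26-neighbors (in region) with the same level
# (alpha = 0); dependence size j = count + 1 (the center itself)
gldm_matrix <- function(g, ng) {
  d <- dim(g)
  dep <- array(0L, dim = d)
  dirs <- directions_13()
  for (k in seq_len(nrow(dirs))) {
    o <- dirs[k, ]
    if (any(abs(o) >= d)) next
    xs <- max(1, 1 + o[1]):min(d[1], d[1] + o[1])
    ys <- max(1, 1 + o[2]):min(d[2], d[2] + o[2])
    zs <- max(1, 1 + o[3]):min(d[3], d[3] + o[3])
    a <- g[xs, ys, zs]; b <- g[xs - o[1], ys - o[2], zs - o[3]]
    eq <- !is.na(a) & !is.na(b) & a == b
    inc <- array(0L, dim = dim(a)); inc[eq] <- 1L
    dep[xs, ys, zs] <- dep[xs, ys, zs] + inc
    # mirrored offset increments the neighbor's count
    dep[xs - o[1], ys - o[2], zs - o[3]] <-
      dep[xs - o[1], ys - o[2], zs - o[3]] + inc
  }
  in_reg <- !is.na(g)
  jv <- dep[in_reg] + 1L
  iv <- g[in_reg]
  jmax <- max(jv)
  matrix(tabulate((jv - 1L) * ng + iv, ng * jmax), ng, jmax)
}

gldm_features <- function(g, ng) {
  P <- gldm_matrix(g, ng)
  nz <- sum(P)
  nm <- gldm_feature_names()
  if (nz == 0) return(stats::setNames(rep(0, 14), nm))
  i <- row(P); j <- col(P)
  p <- P / nz
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  stats::setNames(c(
    sum(P / j^2) / nz,                       # SmallDependenceEmphasis
    sum(P * j^2) / nz,                       # LargeDependenceEmphasis
    sum(rowSums(P)^2) / nz,                  # GrayLevelNonUniformity
    sum(colSums(P)^2) / nz,                  # DependenceNonUniformity
    sum(colSums(P)^2) / nz^2,                # DependenceNonUniformityNormalized
    sum((i - mu_i)^2 * p),                   # GrayLevelVariance
    sum((j - mu_j)^2 * p),                   # DependenceVariance
    -sum(p * log2(p + EPS_LOG)),             # DependenceEntropy
    sum(P / i^2) / nz,                       # LowGrayLevelEmphasis
    sum(P * i^2) / nz,                       # HighGrayLevelEmphasis
    sum(P / (i^2 * j^2)) / nz,               # SmallDependenceLowGrayLevelEmphasis
    sum(P * i^2 / j^2) / nz,                 # SmallDependenceHighGrayLevelEmphasis
    sum(P * j^2 / i^2) / nz,                 # LargeDependenceLowGrayLevelEmphasis
    sum(P * i^2 * j^2) / nz), nm)            # LargeDependenceHighGrayLevelEmphasis
}

# ---- NGTDM -------------------------------------------------------------

ngtdm_features <- function(g, ng) {
  d <- dim(g)
  gz <- g; gz[is.na(gz)] <- 0L
  nb_sum <- array(0, dim = d); nb_cnt <- array(0L, dim = d)
  dirs <- directions_13()
  for (k in seq_len(nrow(dirs))) {
    o <- dirs[k, ]
    if (any(abs(o) >= d)) next
    xs <- max(1, 1 + o[1]):min(d[1], d[1] + o[1])
    ys <- max(1, 1 + o[2]):min(d[2], d[2] + o[2])
    zs <- max(1, 1 + o[3]):min(d[3], d[3] + o[3])
    b_in <- !is.na(g[xs - o[1], ys - o[2], zs - o[3]])
    a_in <- !is.na(g[xs, ys, zs])
    bv <- gz[xs - o[1], ys - o[2], zs - o[3]]
    av <- gz[xs, ys, zs]
    nb_sum[xs, ys, zs] <- nb_sum[xs, ys, zs] + ifelse(b_in, bv, 0)
    nb_cnt[xs, ys, zs] <- nb_cnt[xs, ys, zs] + as.integer(b_in)
    nb_sum[xs - o[1], ys - o[2], zs - o[3]] <-
      nb_sum[xs - o[1], ys - o[2], zs - o[3]] + ifelse(a_in, av, 0)
    nb_cnt[xs - o[1], ys - o[2], zs - o[3]] <-
      nb_cnt[xs - o[1], ys - o[2], zs - o[3]] + as.integer(a_in)
  }
  valid <- !is.na(g) & nb_cnt > 0
  iv <- g[valid]
  abar <- nb_sum[valid] / nb_cnt[valid]
  nvp <- sum(valid)
  nm <- c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")
  if (nvp == 0) return(stats::setNames(rep(0, 5), nm))
  n_i <- tabulate(iv, ng)
  s_i <- vapply(seq_len(ng), function(i) sum(abs(i - abar[iv == i])), 0)
  p_i <- n_i / nvp
  nzl <- which(p_i > 0)
  ngp <- length(nzl)
  sum_ps <- sum(p_i * s_i)
  coarseness <- if (sum_ps > 0) 1 / sum_ps else 1e6
  contrast <- if (ngp > 1) {
    (sum(outer(p_i[nzl], p_i[nzl]) * outer(nzl, nzl, "-")^2) /
       (ngp * (ngp - 1))) * (sum(s_i) / nvp)
  } else 0
  ip <- nzl * p_i[nzl]
  busy_den <- sum(abs(outer(ip, ip, "-")))
  busyness <- if (busy_den > 0) sum_ps / busy_den else 0
  pm <- outer(p_i[nzl], p_i[nzl], "+")
  sm <- outer(p_i[nzl] * s_i[nzl], p_i[nzl] * s_i[nzl], "+")
  complexity <- sum(abs(outer(nzl, nzl, "-")) * sm / pm) / nvp
  strength <- if (sum(s_i) > 0) sum(pm * outer(nzl, nzl, "-")^2) / sum(s_i) else 0
  stats::setNames(c(coarseness, contrast, busyness, complexity, strength), nm)
}
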