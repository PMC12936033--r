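#' Stratified train/test split
#'
#' Deterministic given the seed; per class, `round(ratio * n_class)` subjects
#' go to the training set (so class proportions are preserved within one
#' subject per stratum).
#'
#' @param labels vector of class labels (one per subject).
#' @param ratio training fraction (default 0.7).
#' @param seed integer seed.
#' @param ids optional subject ids (default `seq_along(labels)`).
#' @return list of class `split_plan`: `train`, `test` (ids), `ratio`, `seed`.
#' @export
make_split <- function(labels, ratio = 0.7, seed = 1L, ids = seq_along(labels)) {
  stopifnot(length(labels) == length(ids))
  tab <- table(labels)
  if (length(tab) < 2L) stop("make_split: need >= 2 classes")
  if (any(tab < 2L)) stop("make_split: every class needs >= 2 members")
  if (ratio <= 0 || ratio >= 1) stop("make_split: ratio must be in (0, 1)")
  train <- with_seed(seed, {
    unlist(lapply(names(tab), function(cl) {
      members <- ids[labels == cl]
      n_tr <- max(1L, min(length(members) - 1L, round(ratio * length(members))))
      sample(members, n_tr)
    }), use.names = FALSE)
  })
  structure(list(train = sort(train), test = sort(setdiff(ids, train)),
                 ratio = ratio, seed = seed),
            class = "split_plan")
}

#' Fit / apply outlier clipping and z-score standardization
#'
#' Fitted on training rows only: per feature, values are clipped to
#' `[Q1 - 3 IQR, Q3 + 3 IQR]` and then z-scored with the post-clip training
#' mean and SD. Zero-SD features are dropped (recorded in `dropped`).
#'
#' @param X numeric matrix / data.frame of training rows.
#' @return list of class `preprocess_params`: `lower`, `upper`, `center`,
#'   `scale`, `features`, `dropped`.
#' @export
preprocess_fit <- function(X) {
  X <- as.matrix(X)
  q1 <- apply(X, 2, stats::quantile, 0.25, names = FALSE, type = 7)
  q3 <- apply(X, 2, stats::quantile, 0.75, names = FALSE, type = 7)
  iqr <- q3 - q1
  lower <- q1 - 3 * iqr; upper <- q3 + 3 * iqr
  Xc <- pmin(pmax(X, matrix(lower, nrow(X), ncol(X), byrow = TRUE)),
             matrix(upper, nrow(X), ncol(X), byrow = TRUE))
  center <- colMeans(Xc)
  scale <- apply(Xc, 2, stats::sd)
  keep <- is.finite(scale) & scale > 0
  structure(list(lower = lower[keep], upper = upper[keep],
                 center = center[keep], scale = scale[keep],
                 features = colnames(X)[keep],
                 dropped = colnames(X)[!keep]),
            class = "preprocess_params")
}

#' @param params a `preprocess_params`.
#' @rdname preprocess_fit
#' @export
preprocess_apply <- function(params, X) {
  X <- as.matrix(as.data.frame(X)[, params$features, drop = FALSE])
  n <- nrow(X); p <- ncol(X)
  Xc <- pmin(pmax(X, matrix(params$lower, n, p, byrow = TRUE)),
             matrix(params$upper, n, p, byrow = TRUE))
  sweep(sweep(Xc, 2, params$center), 2, params$scale, "/")
}

#' SMOTE minority oversampling
#'
#' Synthetic minority samples are drawn on segments between a minority point
#' and one of its k nearest minority neighbors:
#' `x_new = x_i + u (x_nn - x_i)`, `u ~ U(0, 1)`. Classes are exactly
#' balanced afterward. If the minority class has `<= k` members, k is reduced
#' with a warning.
#'
#' @param X numeric matrix of rows.
#' @param y binary labels (two levels).
#' @param k_neighbors neighbors considered (default 5).
#' @param seed integer seed.
#' @return list: `X` (original + synthetic rows), `y`, `synthetic` (logical).
#' @export
smote <- function(X, y, k_neighbors = 5L, seed = 1L) {
  X <- as.matrix(X)
  tab <- table(y)
  stopifnot(length(tab) == 2L)
  if (tab[1] == tab[2])
    return(list(X = X, y = y, synthetic = rep(FALSE, nrow(X))))
  minority <- names(tab)[which.min(tab)]
  Xm <- X[y == minority, , drop = FALSE]
  n_min <- nrow(Xm)
  n_new <- max(tab) - n_min
  k <- k_neighbors
  if (n_min <= k) {
    k <- n_min - 1L
    warning("smote: minority count ", n_min, " <= k; using k = ", k)
  }
  if (k < 1L) stop("smote: minority class too small to interpolate")
  D <- as.matrix(stats::dist(Xm))
  diag(D) <- Inf
  nn <- matrix(0L, n_min, k)
  for (r in seq_len(n_min)) nn[r, ] <- order(D[r, ])[seq_len(k)]
  synth <- with_seed(seed, {
    i <- sample.int(n_min, n_new, replace = TRUE)
    j <- nn[cbind(i, sample.int(k, n_new, replace = TRUE))]
    u <- stats::runif(n_new)
    Xm[i, , drop = FALSE] + u * (Xm[j, , drop = FALSE] - Xm[i, , drop = FALSE])
  })
  list(X = rbind(X, synth),
       y = c(y, rep(minority, n_new)),
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, n_new)))
}

#' mRMR feature ranking
#'
#' Greedy maximum-relevance / minimum-redundancy ranking with the quotient
#' scheme: relevance is the one-way F statistic of the feature against the
#' binary label, redundancy the mean absolute Pearson correlation with the
#' already-selected set, and each step picks the feature maximizing
#' relevance / redundancy. Deterministic; ties break by column order.
#'
#' @param X numeric matrix.
#' @param y binary labels.
#' @param m number of features to rank (capped at `ncol(X)`).
#' @return character vector of ranked feature names.
#' @export
mrmr_select <- function(X, y, m = 30L) {
  X <- as.matrix(X)
  m <- min(m, ncol(X))
  y <- as.integer(factor(y)) - 1L
  n <- nrow(X)
  n1 <- sum(y == 1); n0 <- n - n1
  rel <- apply(X, 2, function(x) {
    m1 <- mean(x[y == 1]); m0 <- mean(x[y == 0]); mt <- mean(x)
    ssb <- n1 * (m1 - mt)^2 + n0 * (m0 - mt)^2
    ssw <- sum((x[y == 1] - m1)^2) + sum((x[y == 0] - m0)^2)
    if (ssw <= 0) return(if (ssb > 0) Inf else 0)
    (ssb / 1) / (ssw / (n - 2))
  })
  sdx <- apply(X, 2, stats::sd)
  ranked <- character(0)
  remaining <- colnames(X)
  # first pick: pure relevance
  first <- remaining[which.max(rel[remaining])]
  ranked <- first; remaining <- setdiff(remaining, first)
  while (length(ranked) < m && length(remaining)) {
    red <- vapply(remaining, function(f) {
      if (sdx[f] == 0) return(1)
      cors <- vapply(ranked, function(r) {
        if (sdx[r] == 0) return(0)
        abs(stats::cor(X[, f], X[, r]))
      }, 0)
      mean(cors)
    }, 0)
    score <- rel[remaining] / pmax(red, 1e-6)
    nxt <- remaining[which.max(score)]
    ranked <- c(ranked, nxt); remaining <- setdiff(remaining, nxt)
  }
  ranked
}

#' LASSO feature selection by cross-validated penalized logistic regression
#'
#' L1-penalized logistic regression over a lambda path; lambda is chosen by
#' K-fold cross-validated binomial deviance on the training rows (folds drawn
#' from the seed). Selected features are the nonzero coefficients at the
#' chosen lambda. If every lambda zeroes all coefficients, the smallest
#' lambda is used with a warning.
#'
#' @param X numeric matrix (training rows).
#' @param y binary labels.
#' @param folds CV folds (default 5).
#' @param seed integer seed.
#' @param lambda optional lambda path (default glmnet's).
#' @return list: `selected` (names), `lambda`, `fit` (the glmnet fit),
#'   `coef` (named coefficients at the chosen lambda).
#' @export
lasso_select <- function(X, y, folds = 5L, seed = 1L, lambda = NULL) {
  X <- as.matrix(X)
  yb <- as.integer(factor(y)) - 1L
  stopifnot(folds >= 2L)
  foldid <- with_seed(seed, sample(rep_len(seq_len(folds), nrow(X))))
  cv <- glmnet::cv.glmnet(X, yb, family = "binomial", alpha = 1,
                          foldid = foldid, lambda = lambda,
                          type.measure = "deviance", standardize = FALSE)
  lam <- cv$lambda.min
  co <- stats::coef(cv, s = lam)[, 1]
  sel <- names(co)[co != 0 & names(co) != "(Intercept)"]
  if (!length(sel)) {
    lam <- min(cv$lambda)
    co <- stats::coef(cv, s = lam)[, 1]
    sel <- names(co)[co != 0 & names(co) != "(Intercept)"]
    warning("lasso_select: all coefficients zero at cross-validated lambda; ",
            "falling back to the smallest lambda")
  }
  list(selected = sel, lambda = lam, fit = cv, coef = co[c("(Intercept)", sel)])
}

#' Train one classifier of the two-step architecture
#'
#' Pipeline on the training rows only: outlier clip + z-score
#' ([preprocess_fit()]), SMOTE balancing, mRMR filter (top `mrmr_m`), LASSO
#' selection, then a final logistic regression with a mild CV-tuned L2
#' penalty on the selected features. The decision threshold is Youden's J on
#' the training ROC. When `selected_features` is given (the combined
#' classifier), mRMR and LASSO are skipped and the union pool is used as is.
#'
#' @param X_train,y_train training design and binary labels.
#' @param seed integer seed (SMOTE, CV folds).
#' @param mrmr_m mRMR pool size (default 30).
#' @param folds CV folds (default 5).
#' @param smote_cv `"fold"` applies SMOTE inside each CV fold during lambda
#'   tuning (leakage-safe default); `"train"` applies it once to the whole
#'   training set before tuning.
#' @param selected_features optional preselected feature pool.
#' @param name classifier name.
#' @return list of class `trained_classifier`: `name`, `preprocess`,
#'   `selected`, `intercept`, `coef`, `threshold`, `seed`.
#' @export
train_classifier <- function(X_train, y_train, seed = 1L, mrmr_m = 30L,
                             folds = 5L, smote_cv = c("fold", "train"),
                             selected_features = NULL, name = "clf") {
  smote_cv <- match.arg(smote_cv)
  X_train <- as.matrix(X_train)
  pp <- preprocess_fit(X_train)
  Z <- preprocess_apply(pp, X_train)
  y <- as.integer(factor(y_train)) - 1L

  if (is.null(selected_features)) {
    pool <- mrmr_select(Z, y, m = mrmr_m)
    las <- lasso_cv_smote(Z[, pool, drop = FALSE], y, folds = folds,
                          seed = derive_seed(seed, "lasso"),
                          smote_cv = smote_cv,
                          smote_seed = derive_seed(seed, "smote"))
    sel <- las$selected
  } else {
    sel <- intersect(selected_features, pp$features)
    if (!length(sel)) stop("train_classifier: empty preselected feature pool")
  }

  sm <- smote(Z[, sel, drop = FALSE], y, seed = derive_seed(seed, "smote-final"))
  fit <- ridge_logistic(sm$X, as.integer(sm$y), folds = folds,
                        seed = derive_seed(seed, "ridge"))
  scores <- as.numeric(stats::plogis(fit$intercept +
                                       Z[, sel, drop = FALSE] %*% fit$coef))
  thr <- youden_threshold(scores, y)
  structure(list(name = name, preprocess = pp, selected = sel,
                 intercept = fit$intercept,
                 coef = stats::setNames(as.numeric(fit$coef), sel),
                 lambda = fit$lambda, threshold = thr, seed = seed),
            class = "trained_classifier")
}

# LASSO lambda tuning with SMOTE applied inside each CV fold (or once on the
# whole training set), then selection at the best lambda on the SMOTEd train.
lasso_cv_smote <- function(Z, y, folds, seed, smote_cv, smote_seed) {
  if (length(unique(y)) < 2L) stop("lasso_cv_smote: one class only")
  if (smote_cv == "train" || min(table(y)) == max(table(y))) {
    sm <- smote(Z, y, seed = smote_seed)
    return(lasso_select(sm$X, sm$y, folds = folds, seed = seed))
  }
  sm_full <- smote(Z, y, seed = smote_seed)
  path_fit <- glmnet::glmnet(sm_full$X, as.integer(sm_full$y), family = "binomial",
                             alpha = 1, standardize = FALSE)
  lambda <- path_fit$lambda
  foldid <- with_seed(seed, sample(rep_len(seq_len(folds), length(y))))
  dev <- matrix(NA_real_, folds, length(lambda))
  for (f in seq_len(folds)) {
    tr <- foldid != f
    if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) next
    smf <- smote(Z[tr, , drop = FALSE], y[tr],
                 seed = derive_seed(smote_seed, paste0("fold", f)))
    fit <- glmnet::glmnet(smf$X, as.integer(smf$y), family = "binomial",
                          alpha = 1, lambda = lambda, standardize = FALSE)
    p <- stats::predict(fit, Z[!tr, , drop = FALSE], type = "response")
    yy <- y[!tr]
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    dev[f, seq_len(ncol(p))] <-
      colMeans(-2 * (yy * log(p) + (1 - yy) * log(1 - p)))
  }
  mean_dev <- colMeans(dev, na.rm = TRUE)
  lam <- lambda[which.min(mean_dev)]
  co <- as.numeric(stats::coef(path_fit, s = lam))
  nms <- rownames(stats::coef(path_fit, s = lam))
  sel <- nms[co != 0 & nms != "(Intercept)"]
  if (!length(sel)) {
    lam <- min(lambda)
    co <- as.numeric(stats::coef(path_fit, s = lam))
    sel <- nms[co != 0 & nms != "(Intercept)"]
    warning("lasso_cv_smote: falling back to smallest lambda")
  }
  list(selected = sel, lambda = lam, fit = path_fit)
}

# final logistic regression with a mild L2 penalty tuned by CV
ridge_logistic <- function(X, y, folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  if (ncol(X) == 1L) X2 <- cbind(X, 0) else X2 <- X   # glmnet needs >= 2 cols
  lambda <- 10^seq(-4, 1, length.out = 30)
  foldid <- with_seed(seed, sample(rep_len(seq_len(folds), nrow(X))))
  cv <- glmnet::cv.glmnet(X2, y, family = "binomial", alpha = 0,
                          lambda = lambda, foldid = foldid,
                          type.measure = "deviance", standardize = FALSE)
  co <- stats::coef(cv, s = cv$lambda.min)[, 1]
  list(intercept = unname(co[1]), coef = unname(co[1 + seq_len(ncol(X))]),
       lambda = cv$lambda.min)
}

# Youden's J optimal threshold on a training ROC
youden_threshold <- function(scores, y) {
  cuts <- sort(unique(scores))
  if (length(cuts) == 1L) return(cuts[1])
  mids <- (cuts[-1] + cuts[-length(cuts)]) / 2
  j <- vapply(mids, function(t) {
    sens <- mean(scores[y == 1] > t)
    spec <- mean(scores[y == 0] <= t)
    sens + spec - 1
  }, 0)
  mids[which.max(j)]
}

#' Predict with a trained classifier
#'
#' @param classifier a [train_classifier()] result.
#' @param X new rows (must contain every selected feature; preprocessing
#'   reuses the stored training parameters).
#' @return list: `prob`, `label` (1 where prob > threshold).
#' @export
predict_classifier <- function(classifier, X) {
  X <- as.data.frame(X)
  missing_f <- setdiff(classifier$preprocess$features, names(X))
  if (length(missing_f))
    stop("predict_classifier: missing feature column '", missing_f[1], "'")
  Z <- preprocess_apply(classifier$preprocess, X)
  eta <- classifier$intercept +
    as.numeric(Z[, classifier$selected, drop = FALSE] %*% classifier$coef)
  prob <- stats::plogis(eta)
  list(prob = prob, label = as.integer(prob > classifier$threshold))
}

#' Train the two-step grading architecture
#'
#' Step 1 ("model1") separates Grade 3 (positive) from Grades 1-2; step 2
#' ("model2"), fitted on Grade 1/2 subjects only, separates Grade 1
#' (positive) from Grade 2. For each step four classifiers are trained:
#' whole-volume radiomics (`wvoi`), habitat radiomics (`habitats`, the H1 +
#' H2 columns), clinical (`clinical`), and the combined `total` whose
#' candidate pool is exactly the union of the features the first three
#' selected (no further selection).
#'
#' @param features_wide data.frame: one row per subject with prefixed
#'   radiomic columns (`WVOI_*`, `H1_*`, `H2_*`), clinical columns, and
#'   `subject_id`, `grade` metadata.
#' @param clinical_cols names of the clinical columns.
#' @param ratio train fraction (default 0.7), `folds` CV folds, `mrmr_m`
#'   mRMR pool size, `seed` master seed.
#' @param smote_cv see [train_classifier()].
#' @inheritParams train_classifier
#' @return list of class `two_step_models`: per step, `classifiers` (list of
#'   four), `split` (a [make_split()] plan on subject ids), `label` (named
#'   binary vector).
#' @export
train_two_step <- function(features_wide, clinical_cols, ratio = 0.7,
                           folds = 5L, mrmr_m = 30L, seed = 1L,
                           smote_cv = "fold") {
  tables <- if (is.data.frame(features_wide))
    list(model1 = features_wide, model2 = features_wide) else features_wide
  stopifnot(all(c("model1", "model2") %in% names(tables)))
  for (tb in tables)
    stopifnot(all(c("subject_id", "grade") %in% names(tb)))
  rad_cols <- setdiff(names(tables$model1),
                      c("subject_id", "grade", "batch", "flagged", clinical_cols))
  groups <- list(
    wvoi = grep("^WVOI_", rad_cols, value = TRUE),
    habitats = grep("^H[12]_", rad_cols, value = TRUE),
    clinical = clinical_cols)
  out <- list()
  for (stp in c("model1", "model2")) {
    tb <- tables[[stp]]
    rows <- if (stp == "model1") rep(TRUE, nrow(tb)) else tb$grade %in% c(1, 2)
    df <- tb[rows, , drop = FALSE]
    y <- if (stp == "model1") as.integer(df$grade == 3) else
      as.integer(df$grade == 1)
    split <- make_split(y, ratio = ratio, ids = df$subject_id,
                        seed = derive_seed(seed, paste0(stp, "-split")))
    tr <- df$subject_id %in% split$train
    clfs <- list()
    for (gname in names(groups)) {
      cols <- groups[[gname]]
      clfs[[gname]] <- train_classifier(
        df[tr, cols, drop = FALSE], y[tr],
        seed = derive_seed(seed, paste0(stp, "-", gname)),
        mrmr_m = mrmr_m, folds = folds, smote_cv = smote_cv,
        name = paste0("Clf_", gname))
    }
    pool <- unique(unlist(lapply(clfs, `[[`, "selected")))
    if (!length(pool)) stop("train_two_step: empty combined feature pool for ", stp)
    clfs$total <- train_classifier(
      df[tr, unique(unlist(groups)), drop = FALSE], y[tr],
      seed = derive_seed(seed, paste0(stp, "-total")),
      folds = folds, smote_cv = smote_cv,
      selected_features = pool, name = "Clf_total")
    out[[stp]] <- list(classifiers = clfs, split = split,
                       label = stats::setNames(y, df$subject_id),
                       pool = pool)
  }
  class(out) <- "two_step_models"
  out
}

#' Serialize a trained classifier to JSON
#' @param classifier a `trained_classifier`.
#' @param path file path.
#' @export
write_classifier <- function(classifier, path) {
  ser <- classifier
  ser$preprocess <- lapply(classifier$preprocess, function(x) x)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
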