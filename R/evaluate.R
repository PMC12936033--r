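#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' Ties count one half. Equivalent to trapezoidal integration of the
#' empirical ROC curve.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (0/1 or two-level factor).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(factor(labels)) - 1L
  if (length(unique(y)) < 2L) stop("roc_auc: both classes must be present")
  pos <- scores[y == 1]; neg <- scores[y == 0]
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# DeLong structural components: V10 (per positive), V01 (per negative)
delong_components <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  m <- length(pos); n <- length(neg)
  # psi(x, y) = 1 if x > y, 0.5 if equal, 0 otherwise
  v10 <- vapply(pos, function(x) (sum(x > neg) + 0.5 * sum(x == neg)) / n, 0)
  v01 <- vapply(neg, function(yv) (sum(pos > yv) + 0.5 * sum(pos == yv)) / m, 0)
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

#' DeLong variance, confidence interval and paired comparison
#'
#' Implements the structural-components estimator of the variance of one AUC
#' and of the covariance of two correlated AUCs measured on the same
#' subjects. For a single score vector it returns the AUC, its standard
#' error and a 95% Wald interval clipped to `[0, 1]`; for a pair it adds the
#' AUC difference and a two-sided p-value from the normal reference.
#' Comparing a score vector with itself gives delta = 0, p = 1. A degenerate
#' zero variance with a nonzero difference yields p = NA with a warning.
#'
#' @param scores_a numeric scores.
#' @param scores_b optional second score vector on the same subjects.
#' @param labels binary labels.
#' @param conf confidence level (default 0.95).
#' @return list: `auc` (or `auc_a`, `auc_b`, `delta`), `var`, `se`, `ci`,
#'   and for the paired form `p_value`.
#' @export
delong <- function(scores_a, scores_b = NULL, labels, conf = 0.95) {
  y <- as.integer(factor(labels)) - 1L
  if (length(unique(y)) < 2L) stop("delong: both classes must be present")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ca <- delong_components(scores_a, y)
  var_a <- stats::var(ca$v10) / ca$m + stats::var(ca$v01) / ca$n
  if (is.null(scores_b)) {
    se <- sqrt(var_a)
    ci <- pmin(pmax(ca$auc + c(-1, 1) * z * se, 0), 1)
    return(list(auc = ca$auc, var = var_a, se = se, ci = ci))
  }
  stopifnot(length(scores_b) == length(scores_a))
  cb <- delong_components(scores_b, y)
  var_b <- stats::var(cb$v10) / cb$m + stats::var(cb$v01) / cb$n
  cov_ab <- stats::cov(ca$v10, cb$v10) / ca$m + stats::cov(ca$v01, cb$v01) / ca$n
  delta <- ca$auc - cb$auc
  var_d <- var_a + var_b - 2 * cov_ab
  if (!is.finite(var_d)) {          # a class with a single member
    warning("delong: too few subjects for a variance estimate; p = NA")
    return(list(auc_a = ca$auc, auc_b = cb$auc, delta = delta,
                var_a = var_a, var_b = var_b, cov = cov_ab, se = NA_real_,
                ci = c(NA_real_, NA_real_), p_value = NA_real_))
  }
  if (var_d <= .Machine$double.eps) {
    if (abs(delta) < 1e-12) {
      p <- 1
    } else {
      warning("delong: degenerate zero variance; p-value undefined")
      p <- NA_real_
    }
    se_d <- 0
  } else {
    se_d <- sqrt(var_d)
    p <- 2 * stats::pnorm(-abs(delta) / se_d)
  }
  list(auc_a = ca$auc, auc_b = cb$auc, delta = delta,
       var_a = var_a, var_b = var_b, cov = cov_ab, se = se_d,
       ci = pmin(pmax(delta + c(-1, 1) * z * c(se_d, se_d), -1), 1),
       p_value = p)
}

#' Sensitivity, specificity and balanced accuracy at a threshold
#'
#' The threshold must come from training data; scores strictly above it are
#' called positive. BACC = (SENS + SPEC) / 2 exactly.
#'
#' @param scores numeric scores; `labels` binary; `threshold` decision cut.
#' @return named vector `sens`, `spec`, `bacc`.
#' @export
operating_metrics <- function(scores, labels, threshold) {
  y <- as.integer(factor(labels)) - 1L
  pred <- as.integer(scores > threshold)
  sens <- sum(pred == 1 & y == 1) / sum(y == 1)
  spec <- sum(pred == 0 & y == 0) / sum(y == 0)
  c(sens = sens, spec = spec, bacc = (sens + spec) / 2)
}

#' Balanced accuracy from sensitivity and specificity
#' @param sens,spec operating characteristics in `[0, 1]`.
#' @return their mean.
#' @export
balanced_accuracy <- function(sens, spec) (sens + spec) / 2

#' Exact SHAP attributions for a linear logistic model
#'
#' For a linear model in log-odds space the Shapley values are exact and
#' cheap: `phi_j(x) = coef_j * (z_j - mean(z_j))` with the mean taken over
#' the analyzed rows, and `base + sum_j phi_j` reproduces the model log-odds
#' exactly.
#'
#' @param classifier a [train_classifier()] model.
#' @param X rows to attribute.
#' @return list: `phi` (rows x features), `base` (mean log-odds), `summary`
#'   (features ranked by mean absolute contribution).
#' @export
shap_linear <- function(classifier, X) {
  Z <- preprocess_apply(classifier$preprocess, as.data.frame(X))
  Zs <- Z[, classifier$selected, drop = FALSE]
  mu <- colMeans(Zs)
  phi <- sweep(Zs, 2, mu) * matrix(classifier$coef, nrow(Zs),
                                   length(classifier$coef), byrow = TRUE)
  colnames(phi) <- classifier$selected
  base <- classifier$intercept + sum(classifier$coef * mu)
  imp <- sort(colMeans(abs(phi)), decreasing = TRUE)
  list(phi = phi, base = base,
       summary = data.frame(feature = names(imp), mean_abs_phi = as.numeric(imp)))
}

#' Spearman screen of clinical features against grade
#'
#' Tie-corrected Spearman rank correlation with asymptotic p-values, one row
#' per clinical column.
#'
#' @param clinical data.frame of clinical columns.
#' @param grades ordinal grade vector.
#' @return data.frame `feature`, `rho`, `p_value`.
#' @export
clinical_spearman <- function(clinical, grades) {
  out <- lapply(names(clinical), function(nm) {
    ct <- suppressWarnings(
      stats::cor.test(clinical[[nm]], grades, method = "spearman",
                      exact = FALSE))
    data.frame(feature = nm, rho = unname(ct$estimate), p_value = ct$p.value)
  })
  do.call(rbind, out)
}

#' Evaluate the two-step models on train and test splits
#'
#' Builds the full performance report: per step and classifier, AUC with
#' DeLong 95% CI, sensitivity/specificity at the training-derived threshold,
#' and balanced accuracy, on both splits; plus the pairwise DeLong p-value
#' matrix between classifiers on the test set.
#'
#' @param models a [train_two_step()] result.
#' @param features_wide the same wide feature table used for training.
#' @return list of class `evaluation_report`: `metrics` (data.frame),
#'   `delong_p` (per step, symmetric matrix with unit diagonal).
#' @export
evaluate_two_step <- function(models, features_wide) {
  tables <- if (is.data.frame(features_wide))
    list(model1 = features_wide, model2 = features_wide) else features_wide
  metrics <- list()
  delong_p <- list()
  for (stp in names(models)) {
    mod <- models[[stp]]
    tb <- tables[[stp]]
    ids <- names(mod$label)
    df <- tb[match(ids, tb$subject_id), , drop = FALSE]
    test_scores <- list()
    for (split_name in c("train", "test")) {
      keep <- ids %in% mod$split[[split_name]]
      y <- mod$label[keep]
      for (cn in names(mod$classifiers)) {
        clf <- mod$classifiers[[cn]]
        pr <- predict_classifier(clf, df[keep, , drop = FALSE])
        dl <- delong(pr$prob, labels = y)
        om <- operating_metrics(pr$prob, y, clf$threshold)
        metrics[[length(metrics) + 1L]] <- data.frame(
          model = stp, classifier = cn, split = split_name,
          auc = dl$auc, ci_lower = dl$ci[1], ci_upper = dl$ci[2],
          sens = om[["sens"]], spec = om[["spec"]], bacc = om[["bacc"]])
        if (split_name == "test") test_scores[[cn]] <- pr$prob
      }
    }
    keep <- ids %in% mod$split$test
    y <- mod$label[keep]
    cns <- names(test_scores)
    P <- matrix(1, length(cns), length(cns), dimnames = list(cns, cns))
    for (i in seq_along(cns)) for (j in seq_along(cns)) {
      if (j <= i) next
      p <- delong(test_scores[[i]], test_scores[[j]], labels = y)$p_value
      P[i, j] <- P[j, i] <- p
    }
    delong_p[[stp]] <- P
  }
  structure(list(metrics = do.call(rbind, metrics), delong_p = delong_p),
            class = "evaluation_report")
}

#' Write an evaluation report (CSV metrics + JSON DeLong matrices)
#' @param report an `evaluation_report`.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- report$metrics
  num <- c("auc", "ci_lower", "ci_upper", "sens", "spec", "bacc")
  m[num] <- lapply(m[num], function(x) round_half_up(x, 2))
  utils::write.csv(m, file.path(dir, "performance.csv"), row.names = FALSE)
  jsonlite::write_json(lapply(report$delong_p, function(P)
    as.data.frame(P)), file.path(dir, "delong_p.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# half-up decimal rounding (reporting convention)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
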