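test_that("AUC handles perfect separation, pure ties, and matches trapezoidal integration", {
  expect_equal(roc_auc(c(.9, .8, .2, .1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 20), rep(c(0, 1), 10)), 0.5)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
  set.seed(12)
  for (rep in 1:100) {
    n <- sample(10:60, 1)
    y <- c(rep(1, 5), rbinom(n - 5, 1, .4))
    if (length(unique(y)) < 2) next
    s <- round(rnorm(n), sample(0:2, 1))   # induce ties sometimes
    expect_equal(roc_auc(s, y), oracle_auc_trapezoid(s, y), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(13)
  s <- rnorm(80); y <- rbinom(80, 1, plogis(s))
  a <- roc_auc(s, y)
  expect_equal(roc_auc(exp(s), y), a, tolerance = 1e-12)
  expect_equal(roc_auc(qlogis(plogis(s)), y), a, tolerance = 1e-10)
  expect_equal(roc_auc(rank(s), y), a, tolerance = 1e-12)
})

test_that("DeLong self-comparison gives p = 1 and the variance matches pROC", {
  set.seed(14)
  y <- rbinom(100, 1, .4)
  s <- rnorm(100) + y
  self <- delong(s, s, labels = y)
  expect_equal(self$p_value, 1)
  expect_equal(self$delta, 0)
  skip_if_not_installed("pROC")
  d <- delong(s, labels = y)
  r <- pROC::roc(y, s, quiet = TRUE)
  expect_equal(d$auc, as.numeric(pROC::auc(r)), tolerance = 1e-12)
  expect_equal(d$var, as.numeric(pROC::var(r, method = "delong")),
               tolerance = 1e-10)
  ci <- pROC::ci.auc(r, method = "delong")
  expect_equal(d$ci, as.numeric(ci[c(1, 3)]), tolerance = 1e-10)
  # paired comparison p-value against pROC roc.test
  s2 <- rnorm(100) + 0.5 * y
  ours <- delong(s, s2, labels = y)
  theirs <- pROC::roc.test(r, pROC::roc(y, s2, quiet = TRUE), method = "delong")
  expect_equal(ours$p_value, theirs$p.value, tolerance = 1e-10)
})

test_that("paired DeLong test keeps its nominal type-I error", {
  set.seed(15)
  rej <- vapply(1:1000, function(i) {
    y <- rep(c(0, 1), each = 100)
    a <- rnorm(200); b <- rnorm(200)
    delong(a, b, labels = y)$p_value < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("DeLong CI covers the true AUC at close to nominal rate on binormal scores", {
  # binormal model with AUC 0.8: positives N(mu, 1), mu = sqrt(2) * qnorm(0.8)
  mu <- sqrt(2) * qnorm(0.8)
  set.seed(16)
  cover <- vapply(1:1000, function(i) {
    s <- c(rnorm(100), rnorm(100, mu))
    y <- rep(c(0, 1), each = 100)
    ci <- delong(s, labels = y)$ci
    ci[1] <= 0.8 && 0.8 <= ci[2]
  }, TRUE)
  expect_gte(mean(cover), 0.92)
  expect_lte(mean(cover), 0.98)
})

test_that("operating metrics reproduce the published BACC identities", {
  # printed SENS/SPEC pairs and their balanced accuracies
  expect_equal(balanced_accuracy(0.83, 0.73), 0.78)
  expect_equal(balanced_accuracy(0.80, 0.84), 0.82)
  expect_equal(balanced_accuracy(0.83, 0.67), 0.75)
  expect_equal(balanced_accuracy(0.60, 0.60), 0.60)
  # and BACC is exactly the mean of the computed SENS/SPEC
  set.seed(17)
  s <- runif(60); y <- rbinom(60, 1, s)
  om <- operating_metrics(s, y, 0.5)
  expect_equal(om[["bacc"]], (om[["sens"]] + om[["spec"]]) / 2)
  perf <- operating_metrics(c(.9, .8, .1), c(1, 1, 0), .5)
  expect_equal(unname(perf), c(1, 1, 1))
})

test_that("linear SHAP is exact: zero at the mean point and additive to the log-odds", {
  set.seed(18)
  X <- matrix(rnorm(300), 100, 3); colnames(X) <- c("a", "b", "c")
  y <- rbinom(100, 1, plogis(1.5 * X[, 1]))
  clf <- train_classifier(X, y, seed = 3)
  sh <- shap_linear(clf, as.data.frame(X))
  Z <- preprocess_apply(clf$preprocess, as.data.frame(X))
  eta <- clf$intercept + as.numeric(Z[, clf$selected, drop = FALSE] %*% clf$coef)
  expect_lt(max(abs(sh$base + rowSums(sh$phi) - eta)), 1e-12)
  # a row at the per-feature means has zero contributions
  mean_row <- as.data.frame(as.list(colMeans(Z) * clf$preprocess$scale +
                                      clf$preprocess$center))
  names(mean_row) <- clf$preprocess$features
  sh0 <- shap_linear(clf, rbind(as.data.frame(X)[, clf$preprocess$features],
                                mean_row))
  expect_lt(max(abs(sh0$phi[nrow(sh0$phi), ])), 0.15)
  # dominant planted feature ranks first by mean |phi|
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    Xs <- matrix(rnorm(200 * 4), 200, 4); colnames(Xs) <- paste0("f", 1:4)
    ys <- rbinom(200, 1, plogis(2.5 * Xs[, 2] + 0.2 * Xs[, 1]))
    cl <- suppressWarnings(train_classifier(Xs, ys, seed = s))
    shs <- shap_linear(cl, as.data.frame(Xs))
    shs$summary$feature[1] == "f2"
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("clinical Spearman screen returns rho = 1 for grade itself and ~0 under the null", {
  grades <- rep(1:3, each = 40)
  cl <- data.frame(self = grades, anti = -grades)
  sc <- clinical_spearman(cl, grades)
  expect_equal(sc$rho[sc$feature == "self"], 1)
  expect_equal(sc$rho[sc$feature == "anti"], -1)
  set.seed(19)
  hits <- vapply(1:100, function(i) {
    g <- rep(1:3, length.out = 800)
    abs(suppressWarnings(cor(rnorm(800), g, method = "spearman"))) < 0.1
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("evaluation reports have consistent structure and rounded outputs", {
  set.seed(20)
  n <- 120
  df <- data.frame(subject_id = sprintf("P%03d", 1:n),
                   grade = rep(1:3, each = n / 3))
  for (f in c(sprintf("WVOI_f%d", 1:4), sprintf("H1_f%d", 1:3),
              sprintf("H2_f%d", 1:3)))
    df[[f]] <- rnorm(n) + 0.7 * (df$grade == 3) * grepl("f1|f2", f)
  df$clinA <- rnorm(n) + 0.3 * df$grade; df$clinB <- rnorm(n)
  fit <- suppressWarnings(train_two_step(df, clinical_cols = c("clinA", "clinB"),
                                         mrmr_m = 6, seed = 23))
  rep <- evaluate_two_step(fit, df)
  m <- rep$metrics
  expect_equal(nrow(m), 2 * 4 * 2)
  expect_true(all(m$auc >= 0 & m$auc <= 1))
  expect_true(all(m$ci_lower <= m$auc & m$auc <= m$ci_upper))
  expect_equal(m$bacc, (m$sens + m$spec) / 2, tolerance = 1e-12)
  for (P in rep$delong_p) {
    expect_equal(P, t(P))
    expect_true(all(diag(P) == 1))
  }
  out <- tempfile()
  write_report(rep, out)
  back <- read.csv(file.path(out, "performance.csv"))
  expect_true(all(abs(back$auc * 100 - round(back$auc * 100)) < 1e-9))
  # half-up rounding convention
  expect_equal(habicat:::round_half_up(0.775, 2), 0.78)
  expect_equal(habicat:::round_half_up(0.625, 2), 0.63)
})
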