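test_that("stratified splits preserve class proportions and are deterministic", {
  set.seed(1)
  y <- c(rep(1, 30), rep(0, 70))
  sp <- make_split(y, ratio = 0.7, seed = 4)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_equal(sort(c(sp$train, sp$test)), 1:100)
  n_pos_test <- sum(y[sp$test] == 1)
  expect_true(abs(n_pos_test - 9) <= 1)
  expect_identical(make_split(y, ratio = 0.7, seed = 4), sp)
  expect_false(identical(make_split(y, ratio = 0.7, seed = 5)$train, sp$train))
  expect_error(make_split(y, ratio = 1.0), "ratio")
  expect_error(make_split(rep(1, 10), ratio = 0.7), "2 classes")
  expect_error(make_split(c(1, rep(0, 9)), ratio = 0.7), ">= 2 members")
})

test_that("preprocessing clips outliers to the IQR fence and z-scores with train parameters", {
  set.seed(2)
  x <- rnorm(200)
  x[1] <- 1e6
  X <- cbind(a = x, b = rnorm(200, 5, 2), const = rep(3, 200))
  pp <- preprocess_fit(X)
  expect_equal(pp$dropped, "const")
  q <- quantile(x, c(.25, .75), names = FALSE)
  expect_equal(unname(pp$upper["a"]), q[2] + 3 * (q[2] - q[1]))
  Z <- preprocess_apply(pp, X)
  expect_equal(unname(colMeans(Z)), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(Z, 2, sd)), c(1, 1), tolerance = 1e-10)
  # test rows are transformed with TRAIN parameters, not their own
  Xt <- cbind(a = rnorm(50, 10), b = rnorm(50, 20), const = rep(3, 50))
  Zt <- preprocess_apply(pp, Xt)
  expect_gt(mean(Zt[, "b"]), 2)   # stays off-center under train scaling
})

test_that("SMOTE balances classes with synthetic points on minority segments", {
  set.seed(3)
  X <- matrix(rnorm(80), 40, 2)
  y <- c(rep(1, 10), rep(0, 30))
  sm <- smote(X, y, seed = 9)
  expect_equal(as.integer(table(sm$y)), c(30L, 30L))
  expect_equal(sum(sm$synthetic), 20)
  # convexity: synthetic points lie on segments between two minority points
  Xm <- X[y == 1, ]
  for (i in which(sm$synthetic)) {
    p <- sm$X[i, ]
    on_segment <- any(vapply(seq_len(9), function(a) {
      any(vapply((a + 1):10, function(b) {
        v <- Xm[b, ] - Xm[a, ]; w <- p - Xm[a, ]
        t <- sum(w * v) / sum(v * v)
        t >= -1e-9 && t <= 1 + 1e-9 && sqrt(sum((w - t * v)^2)) < 1e-8
      }, TRUE))
    }, TRUE))
    expect_true(on_segment)
  }
  # 1-D minority {0, 1} with k = 1: synthetics stay inside [0, 1]
  X1 <- matrix(c(0, 1, 5, 6, 7, 8, 9, 10), ncol = 1)
  expect_warning(sm1 <- smote(X1, c(1, 1, 0, 0, 0, 0, 0, 0), k_neighbors = 5),
                 "using k = 1")
  expect_true(all(sm1$X[sm1$synthetic, 1] >= 0 & sm1$X[sm1$synthetic, 1] <= 1))
})

test_that("mRMR never ranks an exact duplicate second and finds planted signal first", {
  set.seed(4)
  n <- 500
  X <- matrix(rnorm(n * 10), n, 10)
  colnames(X) <- paste0("f", 1:10)
  y <- rbinom(n, 1, plogis(2 * X[, 1] + X[, 2]))
  Xd <- cbind(X, dup = X[, 1])
  r <- mrmr_select(Xd, y, m = 3)
  expect_equal(sum(r[1:2] %in% c("f1", "dup")), 1)  # duplicate blocked at rank 2
  # single informative + 9 noise: informative first in >= 95% of seeds
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    Xs <- matrix(rnorm(500 * 10), 500, 10)
    colnames(Xs) <- paste0("g", 1:10)
    ys <- rbinom(500, 1, plogis(1.5 * Xs[, 7]))
    mrmr_select(Xs, ys, m = 1)[1] == "g7"
  }, TRUE)
  expect_gte(mean(hits), 0.95)
  # m = total features gives a permutation of all
  expect_setequal(mrmr_select(X, y, m = 10), colnames(X))
  # constant features are never selected before informative ones
  Xc <- cbind(X[, 1:3], konst = rep(1, n))
  colnames(Xc) <- c("f1", "f2", "f3", "konst")
  expect_false("konst" %in% mrmr_select(Xc, y, m = 3))
})

test_that("LASSO selection respects penalty limits and recovers planted features", {
  set.seed(5)
  n <- 400
  X <- matrix(rnorm(n * 20), n, 20); colnames(X) <- paste0("f", 1:20)
  y <- rbinom(n, 1, plogis(1.5 * X[, 1] - 1.2 * X[, 2] + X[, 3]))
  # lambda -> infinity: nothing survives (fallback warning fires)
  expect_warning(big <- lasso_select(X, y, seed = 1, lambda = c(50, 40)),
                 "all coefficients zero")
  # lambda ~ 0 reduces to the unpenalized logistic fit
  sm <- X[, 1:3]
  fit_glm <- glm(y ~ sm, family = binomial)
  las0 <- lasso_select(sm, y, seed = 1, lambda = c(0.01, 1e-5, 1e-6))
  expect_equal(unname(las0$coef[-1]), unname(coef(fit_glm)[-1]), tolerance = 1e-2)
})

test_that("prediction is a logistic closed form with exact threshold semantics", {
  set.seed(6)
  X <- matrix(rnorm(600), 200, 3); colnames(X) <- c("a", "b", "c")
  y <- rbinom(200, 1, plogis(2 * X[, 1]))
  clf <- train_classifier(X, y, seed = 2)
  pr <- predict_classifier(clf, as.data.frame(X))
  # all-zero standardized features give plogis(intercept)
  mid <- as.data.frame(t(clf$preprocess$center))
  expect_equal(predict_classifier(clf, mid)$prob,
               unname(plogis(clf$intercept)), tolerance = 1e-10)
  # monotone in a positive-coefficient feature
  j <- names(which(clf$coef > 0))[1]
  if (!is.na(j)) {
    grid <- as.data.frame(matrix(rep(clf$preprocess$center, 5), 5, byrow = TRUE))
    names(grid) <- clf$preprocess$features
    grid[[j]] <- seq(min(X[, j]), max(X[, j]), length.out = 5)
    expect_false(is.unsorted(predict_classifier(clf, grid)$prob))
  }
  # hard label flips exactly at the stored threshold
  expect_equal(pr$label, as.integer(pr$prob > clf$threshold))
  expect_error(predict_classifier(clf, data.frame(a = 1, b = 2)), "missing feature")
})

test_that("no test-set information leaks into training", {
  set.seed(7)
  n <- 120
  df <- data.frame(subject_id = sprintf("P%03d", 1:n),
                   grade = rep(1:3, each = n / 3))
  for (f in sprintf("WVOI_f%d", 1:6)) df[[f]] <- rnorm(n) + 0.8 * (df$grade == 3)
  for (f in sprintf("H1_f%d", 1:4)) df[[f]] <- rnorm(n) + 0.8 * (df$grade == 3)
  for (f in sprintf("H2_f%d", 1:4)) df[[f]] <- rnorm(n)
  df$clinA <- rnorm(n) + 0.3 * df$grade
  df$clinB <- rnorm(n)
  fit1 <- suppressWarnings(train_two_step(df, clinical_cols = c("clinA", "clinB"),
                                          mrmr_m = 8, seed = 31))
  # perturbing a step's own test rows must leave that step's models untouched
  # (each step has its own split, so perturb per step)
  num <- setdiff(names(df), c("subject_id", "grade"))
  for (stp in c("model1", "model2")) {
    df2 <- df
    rows <- df2$subject_id %in% fit1[[stp]]$split$test
    df2[rows, num] <- df2[rows, num] + 100
    fit2 <- suppressWarnings(train_two_step(df2, clinical_cols = c("clinA", "clinB"),
                                            mrmr_m = 8, seed = 31))
    for (cn in names(fit1[[stp]]$classifiers)) {
      expect_equal(fit1[[stp]]$classifiers[[cn]]$coef,
                   fit2[[stp]]$classifiers[[cn]]$coef, tolerance = 1e-12)
      expect_equal(fit1[[stp]]$classifiers[[cn]]$threshold,
                   fit2[[stp]]$classifiers[[cn]]$threshold, tolerance = 1e-12)
    }
  }
  # reproducibility: same seed, same models
  fit3 <- train_two_step(df, clinical_cols = c("clinA", "clinB"),
                         mrmr_m = 8, seed = 31)
  expect_equal(fit1$model1$classifiers$total$coef,
               fit3$model1$classifiers$total$coef, tolerance = 0)
})

test_that("the combined classifier pool is exactly the union of the three selections", {
  set.seed(8)
  n <- 150
  df <- data.frame(subject_id = sprintf("P%03d", 1:n),
                   grade = rep(1:3, each = n / 3))
  for (f in sprintf("WVOI_f%d", 1:5)) df[[f]] <- rnorm(n) + (df$grade == 3)
  for (f in sprintf("H1_f%d", 1:5)) df[[f]] <- rnorm(n) + 0.6 * (df$grade == 3)
  for (f in sprintf("H2_f%d", 1:5)) df[[f]] <- rnorm(n)
  df$clinA <- rnorm(n) + 0.4 * df$grade
  df$clinB <- rnorm(n)
  fit <- train_two_step(df, clinical_cols = c("clinA", "clinB"), seed = 13)
  for (stp in c("model1", "model2")) {
    sel_union <- unique(unlist(lapply(
      fit[[stp]]$classifiers[c("wvoi", "habitats", "clinical")], `[[`, "selected")))
    expect_setequal(fit[[stp]]$pool, sel_union)
    expect_true(all(fit[[stp]]$classifiers$total$selected %in% sel_union))
  }
})

test_that("a pipeline trained on pure noise stays near chance on CV-style data", {
  set.seed(9)
  n <- 150
  df <- data.frame(subject_id = sprintf("P%03d", 1:n),
                   grade = sample(rep(1:3, each = n / 3)))
  for (f in c(sprintf("WVOI_f%d", 1:8), sprintf("H1_f%d", 1:4),
              sprintf("H2_f%d", 1:4))) df[[f]] <- rnorm(n)
  df$clinA <- rnorm(n); df$clinB <- rnorm(n)
  fit <- train_two_step(df, clinical_cols = c("clinA", "clinB"),
                        mrmr_m = 10, seed = 17)
  rep <- evaluate_two_step(fit, df)
  test_auc <- subset(rep$metrics, split == "test")$auc
  expect_true(all(test_auc > 0.2 & test_auc < 0.8))
  expect_true(mean(test_auc > 0.35 & test_auc < 0.65) >= 0.5)
})
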