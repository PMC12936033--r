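# helper: synthetic multi-batch feature table with heterogeneous feature scales
make_batch_table <- function(n = 300, G = 25, seed = 1, grade_effect = 0,
                             n_batches = 3) {
  set.seed(seed)
  tb <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                   grade = sample(1:3, n, TRUE),
                   batch = sample(seq_len(n_batches), n, TRUE))
  sds <- exp(runif(G, -1, 2))
  X <- sapply(seq_len(G), function(j)
    rnorm(n, 10 * j, sds[j]) + grade_effect * sds[j] * (tb$grade - 2))
  colnames(X) <- paste0("f", seq_len(G))
  tb <- cbind(tb, X)
  attr(tb, "feature_names") <- colnames(X)
  tb
}

test_that("a single reference batch fits to identity adjustments", {
  tb <- make_batch_table(60, G = 5, n_batches = 1)
  m <- fit_combat(tb)
  expect_true(all(m$gamma_star == 0))
  expect_true(all(m$delta_star == 1))
  out <- apply_combat(m, tb)
  expect_equal(as.matrix(out[, m$usable]), as.matrix(tb[, m$usable]),
               tolerance = 1e-12)
})

test_that("without EB, a pure location shift is recovered as a method-of-moments mean", {
  tb <- make_batch_table(800, G = 10, seed = 3, n_batches = 2)
  fc <- feature_columns(tb)
  shifted <- tb
  for (g in fc) shifted[[g]][shifted$batch == 2] <-
      shifted[[g]][shifted$batch == 2] + 10
  m <- fit_combat(shifted, reference_batch = 1, eb = FALSE)
  # gamma on the standardized scale, mapped back to raw units
  est_raw <- m$gamma_hat["2", ] * m$sigma[m$usable]
  expect_equal(unname(est_raw), rep(10, 10), tolerance = 1.5)
  # and with balanced batches this reduces to location-scale standardization
  out <- apply_combat(m, shifted)
  for (g in fc) {
    z_ref <- (shifted[[g]][shifted$batch == 1] - m$alpha[g]) / m$sigma[g]
    x2 <- shifted[[g]][shifted$batch == 2]
    z2 <- (x2 - m$alpha[g]) / m$sigma[g]
    closed <- ((z2 - mean(z2)) / sd(z2)) * m$sigma[g] + m$alpha[g]
    expect_equal(out[[g]][shifted$batch == 2], closed, tolerance = 1e-10)
  }
})

test_that("planted batch shifts are recovered with r >= 0.95 and batch variance drops >= 10-fold", {
  tb <- make_batch_table(300, G = 40, seed = 7)   # ~100 per batch
  cfg <- test_phantom_config(n_per = 100L,
                             batch_location_shift = c(0, 0.8, -0.6),
                             batch_scale_shift = c(1, 1.4, 0.7))
  tb2 <- inject_batch_effects(tb, cfg)
  truth <- attr(tb2, "batch_truth")
  m <- fit_combat(tb2, reference_batch = 1)
  for (b in c("2", "3")) {
    est_raw <- m$gamma_star[b, ] * m$sigma[m$usable]
    expect_gte(cor(est_raw, truth$location[as.integer(b), m$usable]), 0.95)
  }
  before <- batch_variance_fraction(tb2)
  after <- batch_variance_fraction(apply_combat(m, tb2))
  expect_gte(before / after, 10)
})

test_that("reference rows pass through unchanged and harmonization has a fixed point", {
  tb <- inject_batch_effects(make_batch_table(240, G = 15, seed = 9),
                             test_phantom_config(n_per = 80L))
  m <- fit_combat(tb, reference_batch = 1)
  out <- apply_combat(m, tb)
  ref <- tb$batch == 1
  expect_lt(max(abs(as.matrix(out[ref, m$usable]) -
                      as.matrix(tb[ref, m$usable]))), 1e-10)
  # refit on harmonized data: applying the new model changes nothing material
  m2 <- fit_combat(out, reference_batch = 1)
  out2 <- apply_combat(m2, out)
  rel <- abs(as.matrix(out2[, m$usable]) - as.matrix(out[, m$usable])) /
    (abs(as.matrix(out[, m$usable])) + 1)
  expect_lt(max(rel), 0.05)
  expect_error(apply_combat(m, transform(tb, batch = 9)), "unseen batch")
})

test_that("harmonization preserves a planted grade effect within 20% relative", {
  tb <- make_batch_table(360, G = 20, seed = 13, grade_effect = 0.8)
  tb2 <- inject_batch_effects(tb, test_phantom_config(n_per = 120L))
  m <- fit_combat(tb2, reference_batch = 1)
  out <- apply_combat(m, tb2)
  eff <- function(t) {
    vapply(feature_columns(tb), function(g) {
      x <- t[[g]]
      (mean(x[t$grade == 3]) - mean(x[t$grade == 1])) / sd(x)
    }, 0)
  }
  e_clean <- eff(tb)           # effect before any batch corruption
  e_harm <- eff(out)
  expect_lt(median(abs(e_harm - e_clean) / abs(e_clean)), 0.2)
})

test_that("zero-variance features are passed through with a warning", {
  tb <- make_batch_table(90, G = 4, seed = 5)
  tb$f1 <- 7
  expect_warning(m <- fit_combat(tb, reference_batch = 1), "zero-variance")
  expect_true("f1" %in% m$skipped)
  out <- apply_combat(m, tb)
  expect_true(all(out$f1 == 7))
})

test_that("the in-package EB fit agrees with the canonical reference implementation", {
  skip_if_not_installed("sva")
  tb <- inject_batch_effects(make_batch_table(150, G = 12, seed = 17),
                             test_phantom_config(n_per = 50L))
  fc <- feature_columns(tb)
  m <- fit_combat(tb, reference_batch = 1)
  ours <- as.matrix(apply_combat(m, tb)[, fc])
  theirs <- t(suppressMessages(
    sva::ComBat(t(as.matrix(tb[, fc])), batch = tb$batch, ref.batch = 1)))
  # same estimator family: agreement to a few percent of each feature's scale
  scl <- matrix(apply(ours, 2, sd), nrow(ours), ncol(ours), byrow = TRUE)
  expect_lt(max(abs(ours - theirs) / scl), 0.1)
  expect_gt(cor(as.numeric(ours), as.numeric(theirs)), 0.999)
})

test_that("combat model serialization round trips", {
  tb <- make_batch_table(90, G = 6, seed = 19)
  m <- fit_combat(tb, reference_batch = 1)
  tmp <- tempfile(fileext = ".json")
  write_combat_model(m, tmp)
  m2 <- read_combat_model(tmp)
  expect_equal(unname(m2$gamma_star), unname(m$gamma_star), tolerance = 1e-12)
  out1 <- apply_combat(m, tb)
  m2$usable <- m$usable
  out2 <- apply_combat(m2, tb)
  expect_equal(out1[, m$usable], out2[, m$usable], tolerance = 1e-10)
})
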