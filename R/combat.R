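#' Fit reference-batch ComBat harmonization
#'
#' Location-scale empirical-Bayes batch harmonization with a reference batch:
#' every feature is standardized against the reference batch's mean and
#' standard deviation, per-batch location (gamma) and scale (delta^2) shifts
#' are estimated on that standardized scale, and — when `eb = TRUE` — shrunk
#' toward batch-level priors by the parametric EB scheme (normal prior on
#' gamma, inverse-gamma on delta^2, moment-matched hyperparameters,
#' fixed-point iteration to 1e-8). No biological covariates are adjusted.
#' The reference batch's adjustments are fixed at gamma* = 0, delta* = 1, so
#' reference rows pass through unchanged.
#'
#' Zero-variance features (within any batch or in the reference) are passed
#' through unharmonized and recorded in the model's `skipped` field.
#'
#' @param table a `feature_table` (rows carry a `batch` column), or a plain
#'   data.frame together with `batch_ids`.
#' @param batch_ids optional vector overriding `table$batch`.
#' @param reference_batch id of the reference batch (default: largest batch).
#' @param eb enable empirical-Bayes shrinkage (default TRUE).
#' @param features columns to harmonize (default [feature_columns()]).
#' @return list of class `combat_model`: `alpha`, `sigma` (reference
#'   mean/SD per feature), `gamma_star`, `delta_star` (batch x feature),
#'   `gamma_hat`, `delta_hat`, `batches`, `reference_batch`, `eb`,
#'   `hyper` (EB hyperparameters per batch), `skipped`.
#' @export
fit_combat <- function(table, batch_ids = NULL, reference_batch = NULL,
                       eb = TRUE, features = NULL) {
  b <- if (is.null(batch_ids)) table$batch else batch_ids
  if (is.null(b)) stop("fit_combat: no batch ids")
  fc <- if (is.null(features)) feature_columns(table) else features
  batches <- sort(unique(b))
  if (length(batches) < 2L) {
    if (is.null(reference_batch)) reference_batch <- batches[1]
  }
  if (any(table(b) < 2L)) stop("fit_combat: every batch needs >= 2 rows")
  if (is.null(reference_batch))
    reference_batch <- batches[which.max(tabulate(match(b, batches)))]
  if (!reference_batch %in% batches) stop("fit_combat: unknown reference batch")
  X <- as.matrix(table[, fc, drop = FALSE])
  ref <- b == reference_batch

  alpha <- colMeans(X[ref, , drop = FALSE])
  sigma <- apply(X[ref, , drop = FALSE], 2, stats::sd)
  within_sd_ok <- vapply(fc, function(g) {
    all(tapply(X[, g], b, stats::sd) > 0)
  }, TRUE)
  usable <- is.finite(sigma) & sigma > 0 & within_sd_ok
  skipped <- fc[!usable]
  if (length(skipped))
    warning("fit_combat: ", length(skipped),
            " zero-variance feature(s) passed through unharmonized")
  fu <- fc[usable]
  Z <- sweep(sweep(X[, fu, drop = FALSE], 2, alpha[fu]), 2, sigma[fu], "/")

  B <- length(batches); G <- length(fu)
  gamma_hat <- matrix(0, B, G, dimnames = list(batches, fu))
  delta_hat <- matrix(1, B, G, dimnames = list(batches, fu))
  for (k in seq_len(B)) {
    rows <- b == batches[k]
    gamma_hat[k, ] <- colMeans(Z[rows, , drop = FALSE])
    delta_hat[k, ] <- apply(Z[rows, , drop = FALSE], 2, stats::var)
  }

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  hyper <- list()
  if (eb) {
    for (k in seq_len(B)) {
      if (batches[k] == reference_batch) next
      n_k <- sum(b == batches[k])
      gh <- gamma_hat[k, ]; dh <- delta_hat[k, ]
      g_bar <- mean(gh); t2 <- stats::var(gh)
      # inverse-gamma moment matching (the canonical aprior/bprior)
      m <- mean(dh); s2 <- stats::var(dh)
      a_prior <- (2 * s2 + m^2) / s2
      b_prior <- (m * s2 + m^3) / s2
      g_new <- gh; d_new <- dh
      rows <- which(b == batches[k])
      for (it in seq_len(500L)) {
        g_old <- g_new; d_old <- d_new
        g_new <- (n_k * t2 * gh + d_new * g_bar) / (n_k * t2 + d_new)
        sse <- colSums((Z[rows, , drop = FALSE] -
                          matrix(g_new, n_k, G, byrow = TRUE))^2)
        d_new <- (b_prior + 0.5 * sse) / (n_k / 2 + a_prior - 1)
        if (max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                abs(d_new - d_old) / (abs(d_old) + 1e-12)) < 1e-8) break
      }
      gamma_star[k, ] <- g_new
      delta_star[k, ] <- d_new
      hyper[[as.character(batches[k])]] <-
        list(gamma_bar = g_bar, tau2 = t2, a_prior = a_prior, b_prior = b_prior)
    }
  }
  kref <- match(reference_batch, batches)
  gamma_star[kref, ] <- 0
  delta_star[kref, ] <- 1
  structure(list(alpha = alpha, sigma = sigma, gamma_star = gamma_star,
                 delta_star = pmax(delta_star, 1e-12),
                 gamma_hat = gamma_hat, delta_hat = delta_hat,
                 batches = batches, reference_batch = reference_batch,
                 eb = eb, hyper = hyper, features = fc, usable = fu,
                 skipped = skipped),
            class = "combat_model")
}

#' Apply a fitted ComBat model
#'
#' Non-reference rows are adjusted on the standardized scale by
#' `(z - gamma*) / sqrt(delta*)` and mapped back to the reference scale;
#' reference-batch rows are returned exactly unchanged. Unseen batch ids are
#' an error (no extrapolation).
#'
#' @param model a [fit_combat()] model.
#' @param table a feature table whose feature columns match the model.
#' @param batch_ids optional override of `table$batch`.
#' @return the harmonized table.
#' @export
apply_combat <- function(model, table, batch_ids = NULL) {
  b <- if (is.null(batch_ids)) table$batch else batch_ids
  unseen <- setdiff(unique(b), model$batches)
  if (length(unseen))
    stop("apply_combat: unseen batch id(s): ", paste(unseen, collapse = ", "))
  fu <- model$usable
  missing_f <- setdiff(fu, names(table))
  if (length(missing_f))
    stop("apply_combat: table lacks feature(s): ", missing_f[1])
  X <- as.matrix(table[, fu, drop = FALSE])
  Z <- sweep(sweep(X, 2, model$alpha[fu]), 2, model$sigma[fu], "/")
  k <- match(b, model$batches)
  Zadj <- (Z - model$gamma_star[k, , drop = FALSE]) /
    sqrt(model$delta_star[k, , drop = FALSE])
  Xadj <- sweep(sweep(Zadj, 2, model$sigma[fu], "*"), 2, model$alpha[fu], "+")
  nonref <- b != model$reference_batch
  for (j in seq_along(fu)) {
    col <- table[[fu[j]]]
    col[nonref] <- Xadj[nonref, j]
    table[[fu[j]]] <- col
  }
  table
}

#' Serialize / restore a ComBat model as JSON
#' @param model a `combat_model`.
#' @param path file path.
#' @return `path` (write) or the restored model (read).
#' @export
write_combat_model <- function(model, path) {
  ser <- unclass(model)
  ser$alpha <- as.list(ser$alpha)
  ser$sigma <- as.list(ser$sigma)
  ser$gamma_star <- as.data.frame(ser$gamma_star)
  ser$delta_star <- as.data.frame(ser$delta_star)
  ser$gamma_hat <- as.data.frame(ser$gamma_hat)
  ser$delta_hat <- as.data.frame(ser$delta_hat)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_combat_model
#' @export
read_combat_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("gamma_star", "delta_star", "gamma_hat", "delta_hat"))
    m[[nm]] <- as.matrix(m[[nm]])
  for (nm in c("alpha", "sigma")) m[[nm]] <- unlist(m[[nm]])
  class(m) <- "combat_model"
  m
}

#' Fraction of feature variance explained by batch
#'
#' One-way ANOVA variance decomposition per feature (between-batch sum of
#' squares over total), averaged across features. Used to quantify how much
#' batch signal harmonization removed.
#'
#' @param table feature table.
#' @param features columns to assess (default all feature columns).
#' @return mean fraction in `[0, 1]`.
#' @export
batch_variance_fraction <- function(table, features = NULL) {
  fc <- if (is.null(features)) feature_columns(table) else features
  b <- factor(table$batch)
  fr <- vapply(fc, function(g) {
    x <- table[[g]]
    tot <- sum((x - mean(x))^2)
    if (tot == 0) return(0)
    means <- tapply(x, b, mean)
    betw <- sum(tabulate(b) * (means - mean(x))^2)
    betw / tot
  }, 0)
  mean(fr)
}
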