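#' Configuration for tabular LIME explanations
#'
#' Stores the perturbation statistics (per-feature training mean and
#' standard deviation), the neighborhood size, the exponential proximity
#' kernel width and the surrogate complexity budget.
#'
#' Perturbed rows are drawn feature-wise from `Normal(mean_j, sd_j)` of
#' the training data (global sampling; locality enters only through the
#' kernel weights `exp(-D(x, z)^2 / sigma^2)` with `D` Euclidean on
#' standardized features).  The complexity control is a hard cap of
#' `n_features` non-zero surrogate weights.
#'
#' @param train Data frame of training features (label / `record_id`
#'   columns ignored) from which means and standard deviations are taken.
#' @param n_samples Neighborhood size (>= number of features + 2).
#' @param kernel_width Kernel width `sigma`; default `0.75 * sqrt(M)` on
#'   the standardized distance scale.
#' @param n_features Complexity budget `K`: max surrogate features kept.
#' @param seed Seed for the neighborhood sampling.
#' @param ridge Ridge penalty used in the selection fit (and as fallback
#'   if the weighted refit is singular).
#' @return An object of class `lime_config`.
#' @export
lime_config <- function(train, n_samples = 5000, kernel_width = NULL,
                        n_features = NULL, seed = NULL, ridge = 1e-4) {
  feats <- setdiff(names(train), c("label", "record_id"))
  x <- as.matrix(as.data.frame(train)[feats])
  storage.mode(x) <- "double"
  M <- ncol(x)
  kernel_width <- kernel_width %||% (0.75 * sqrt(M))
  n_features <- n_features %||% min(10L, M)
  stopifnot(
    kernel_width > 0, n_features >= 1, n_features <= M,
    n_samples >= M + 2
  )
  structure(
    list(
      features = feats,
      mean = colMeans(x, na.rm = TRUE),
      sd = apply(x, 2, stats::sd, na.rm = TRUE),
      n_samples = as.integer(n_samples),
      kernel_width = kernel_width,
      n_features = as.integer(n_features),
      seed = seed,
      ridge = ridge
    ),
    class = "lime_config"
  )
}

#' Sample a LIME perturbation neighborhood
#'
#' Draws `n_samples` rows, each feature independently from the training
#' Normal (zero-sd features stay constant), with the explained instance
#' itself as the first row, and attaches the exponential kernel weights.
#'
#' @param x Numeric feature vector (or one-row data frame) being
#'   explained.
#' @param config A [lime_config()].
#' @return A list with `samples` (matrix `n_samples x M`) and `weights`
#'   (`exp(-D^2 / sigma^2)`, 1 for `x` itself).
#' @export
perturb_neighborhood <- function(x, config) {
  stopifnot(inherits(config, "lime_config"))
  if (is.data.frame(x)) x <- drop(as.matrix(x[config$features]))
  M <- length(config$mean)
  stopifnot(length(x) == M)
  x[!is.finite(x)] <- config$mean[!is.finite(x)]
  with_local_seed(config$seed, {
    z <- matrix(
      rnorm(config$n_samples * M,
        mean = rep(config$mean, each = config$n_samples),
        sd = rep(config$sd, each = config$n_samples)
      ),
      nrow = config$n_samples
    )
    colnames(z) <- config$features
    z[1, ] <- x
    sd_safe <- ifelse(config$sd == 0, 1, config$sd)
    zs <- sweep(sweep(z, 2, config$mean), 2, sd_safe, "/")
    xs <- (x - config$mean) / sd_safe
    d2 <- rowSums(sweep(zs, 2, xs)^2)
    list(samples = z, weights = exp(-d2 / config$kernel_width^2))
  })
}

# Weighted ridge regression with unpenalized intercept; returns
# c(intercept, coefs).
wls_ridge <- function(x, y, w, lambda) {
  xx <- cbind(1, x)
  pen <- diag(c(0, rep(lambda, ncol(x))), ncol(xx))
  xtw <- t(xx * w)
  drop(solve(xtw %*% xx + pen, xtw %*% y))
}

#' LIME explanation of a prediction
#'
#' Fits a kernel-weighted sparse linear surrogate to the black-box output
#' on a sampled neighborhood of `x`: features are ranked by the magnitude
#' of their standardized coefficients in a weighted ridge fit on all
#' features, the top `n_features` are kept, and the surrogate is refit by
#' weighted least squares on the selected support (ridge fallback if
#' singular).  One explanation per model output (class probability).
#'
#' @param predict_fn Function mapping a feature matrix to a numeric
#'   vector or a matrix with one column per class.
#' @param x Instance to explain (numeric vector or one-row data frame).
#' @param config A [lime_config()].
#' @return An object of class `lime_explanation`: tibble `weights`
#'   (output, feature, weight), plus `intercept`, `loss` (kernel-weighted
#'   squared error of the surrogate), and `local_pred` (surrogate value
#'   at `x`) per output.
#' @export
lime_explain <- function(predict_fn, x, config) {
  stopifnot(inherits(config, "lime_config"))
  if (is.data.frame(x)) x <- drop(as.matrix(x[config$features]))
  x[!is.finite(x)] <- config$mean[!is.finite(x)]
  nb <- perturb_neighborhood(x, config)
  z <- nb$samples
  w <- nb$weights
  f <- predict_as_matrix(predict_fn, z)
  outputs <- colnames(f) %||% paste0("output", seq_len(ncol(f)))

  sd_safe <- ifelse(config$sd == 0, 1, config$sd)
  zs <- sweep(sweep(z, 2, config$mean), 2, sd_safe, "/")

  res <- lapply(seq_len(ncol(f)), function(k) {
    y <- f[, k]
    # selection pass: standardized ridge, rank by |coefficient|
    b_sel <- wls_ridge(zs, y, w, config$ridge)[-1]
    keep <- order(-abs(b_sel),
      feature_tiebreak_index(config$features)
    )[seq_len(config$n_features)]
    keep <- sort(keep)
    # faithful refit on the selected support, original scale
    fit <- tryCatch(
      wls_ridge(z[, keep, drop = FALSE], y, w, 0),
      error = function(e) {
        wls_ridge(z[, keep, drop = FALSE], y, w, config$ridge)
      }
    )
    pred <- drop(cbind(1, z[, keep, drop = FALSE]) %*% fit)
    weights <- stats::setNames(numeric(length(config$features)),
      config$features
    )
    weights[keep] <- fit[-1]
    list(
      weights = weights,
      intercept = fit[1],
      loss = sum(w * (y - pred)^2),
      local_pred = fit[1] + sum(fit[-1] * x[keep])
    )
  })

  weights_tbl <- purrr::map2_dfr(res, outputs, function(r, out) {
    tibble::tibble(
      output = out,
      feature = config$features,
      weight = unname(r$weights)
    )
  })
  structure(
    list(
      weights = weights_tbl,
      intercept = stats::setNames(
        vapply(res, `[[`, numeric(1), "intercept"), outputs
      ),
      loss = stats::setNames(
        vapply(res, `[[`, numeric(1), "loss"), outputs
      ),
      local_pred = stats::setNames(
        vapply(res, `[[`, numeric(1), "local_pred"), outputs
      ),
      x = x, outputs = outputs, n_features = config$n_features
    ),
    class = "lime_explanation"
  )
}

#' @export
print.lime_explanation <- function(x, ...) {
  cat("LIME explanation,", length(x$outputs), "output(s), up to",
    x$n_features, "features each\n")
  nz <- dplyr::filter(x$weights, .data$weight != 0)
  print(nz, n = 20)
  invisible(x)
}
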