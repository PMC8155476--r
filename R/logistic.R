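#' Fit a (ridge-penalized) binary logistic model by IRLS
#'
#' Maximizes the Bernoulli log-likelihood
#' `sum(y * log(p) + (1 - y) * log(1 - p))` with `p = 1 / (1 + exp(-f))`
#' and linear score `f(x) = b0 + b' x`, minus an optional L2 penalty
#' `lambda / 2 * ||b||^2` on the non-intercept coefficients, via
#' iteratively reweighted least squares.  Features are standardized
#' internally (stored center/scale), so coefficient magnitudes are
#' comparable across features — the property coefficient-based importance
#' relies on.
#'
#' @param data Data frame of numeric features plus a label column.
#' @param label Name of the label column.
#' @param positive Level treated as the positive class (`y = 1`); default
#'   the second factor level.
#' @param lambda L2 penalty on the standardized scale.
#' @param tol Convergence tolerance on the max absolute coefficient
#'   change.
#' @param max_iter Iteration cap; non-convergence is flagged in
#'   `$converged`, not an error.
#' @return An object of class `af_logit` with standardized-scale
#'   coefficients (`$coef`, `$intercept`), scaling parameters, the
#'   training log-likelihood `$llf` and the convergence flag.
#' @export
#' @examples
#' d <- data.frame(x = rnorm(100), label = rep(c("a", "b"), 50))
#' fit_logistic(d)
fit_logistic <- function(data, label = "label", positive = NULL,
                         lambda = 0, tol = 1e-8, max_iter = 100) {
  sp <- split_features(data, label)
  if (nlevels(sp$y) != 2) {
    stop("fit_logistic needs exactly two classes; got ",
      nlevels(sp$y),
      call. = FALSE
    )
  }
  positive <- positive %||% levels(sp$y)[2]
  y <- as.numeric(sp$y == positive)
  center <- colMeans(sp$x)
  scale_ <- apply(sp$x, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  xs <- cbind(1, sweep(sweep(sp$x, 2, center), 2, scale_, "/"))
  k <- ncol(xs)
  pen <- diag(c(0, rep(lambda, k - 1)), k)

  b <- numeric(k)
  b[1] <- stats::qlogis(max(min(mean(y), 1 - 1e-6), 1e-6))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(xs %*% b)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    xtw <- t(xs * w)
    b_new <- tryCatch(
      drop(solve(xtw %*% xs + pen, xtw %*% z)),
      error = function(e) b
    )
    if (max(abs(b_new - b)) < tol) {
      b <- b_new
      converged <- TRUE
      break
    }
    b <- b_new
  }
  eta <- drop(xs %*% b)
  p <- stats::plogis(eta)
  llf <- sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300)))
  structure(
    list(
      intercept = unname(b[1]),
      coef = stats::setNames(b[-1], sp$features),
      center = center, scale = scale_, impute = sp$impute,
      llf = llf, lambda = lambda,
      converged = converged, scaled = TRUE,
      classes = levels(sp$y), positive = positive,
      features = sp$features
    ),
    class = "af_logit"
  )
}

#' @export
predict.af_logit <- function(object, newdata,
                             type = c("prob", "link", "class"), ...) {
  type <- match.arg(type)
  x <- feature_matrix(newdata, object$features, object$impute)
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  eta <- unname(drop(xs %*% object$coef)) + object$intercept
  if (type == "link") {
    return(eta)
  }
  p_pos <- stats::plogis(eta)
  neg <- setdiff(object$classes, object$positive)
  p <- matrix(c(1 - p_pos, p_pos),
    ncol = 2,
    dimnames = list(NULL, c(neg, object$positive))
  )
  p <- p[, object$classes, drop = FALSE]
  finish_prediction(p, if (type == "class") "class" else "prob",
    object$classes
  )
}

#' Fit one-vs-rest logistic models for a multi-class problem
#'
#' One penalized binary logistic fit per class (that class against the
#' rest), sharing the feature standardization convention of
#' [fit_logistic()].  Class probabilities are the normalized one-vs-rest
#' positive-class probabilities.
#'
#' @inheritParams fit_logistic
#' @return An object of class `af_logit_ovr` (a list of `af_logit` fits).
#' @export
fit_logistic_ovr <- function(data, label = "label", lambda = 1e-4,
                             tol = 1e-8, max_iter = 100) {
  y <- as_rhythm_factor(data[[label]])
  fits <- lapply(levels(y), function(cl) {
    d <- data
    d[[label]] <- factor(ifelse(y == cl, cl, "rest"),
      levels = c("rest", cl)
    )
    fit_logistic(d,
      label = label, positive = cl, lambda = lambda,
      tol = tol, max_iter = max_iter
    )
  })
  names(fits) <- levels(y)
  structure(
    list(fits = fits, classes = levels(y),
      features = fits[[1]]$features),
    class = "af_logit_ovr"
  )
}

#' @export
predict.af_logit_ovr <- function(object, newdata,
                                 type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- vapply(
    object$fits,
    function(f) {
      pr <- predict(f, newdata, type = "prob")
      pr[[f$positive]]
    },
    numeric(nrow(as.data.frame(newdata)))
  )
  p <- matrix(p, ncol = length(object$fits),
    dimnames = list(NULL, object$classes)
  )
  p <- p / pmax(rowSums(p), 1e-300)
  finish_prediction(p, type, object$classes)
}
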