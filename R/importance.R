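# Build the canonical ranking object from a named score vector: a tibble
# (method, feature, score, rank) sorted by descending score, ties broken by
# the registry index.
new_ranking <- function(method, scores, per_class = NULL, extra = NULL) {
  stopifnot(!is.null(names(scores)), all(is.finite(scores)))
  tie <- feature_tiebreak_index(names(scores))
  ord <- order(-scores, tie)
  out <- tibble::tibble(
    method = method,
    feature = names(scores)[ord],
    score = unname(scores[ord]),
    rank = seq_along(scores)
  )
  if (!is.null(extra)) {
    out <- dplyr::bind_cols(out, tibble::as_tibble(extra)[ord, , drop = FALSE])
  }
  attr(out, "per_class") <- per_class
  class(out) <- c("importance_ranking", class(out))
  out
}

#' Coefficient-based importance from one-vs-rest logistic models
#'
#' Per-class importance is the absolute standardized coefficient of each
#' feature in that class's one-vs-rest logistic fit; the overall score is
#' the mean over classes.  Requires models fitted on standardized features
#' (which [fit_logistic()] always does); models without stored scaling are
#' rejected.
#'
#' @param model An `af_logit_ovr` (or single `af_logit`) fit.
#' @return An `importance_ranking` tibble (method, feature, score, rank)
#'   with the per-class score matrix in `attr(, "per_class")`.
#' @export
lr_importance <- function(model) {
  if (inherits(model, "af_logit")) {
    model <- structure(
      list(fits = list(model), classes = model$positive),
      class = "af_logit_ovr"
    )
  }
  stopifnot(inherits(model, "af_logit_ovr"))
  ok <- vapply(model$fits, function(f) isTRUE(f$scaled), logical(1))
  if (!all(ok)) {
    stop("lr_importance needs models fitted on standardized features",
      call. = FALSE
    )
  }
  per_class <- vapply(
    model$fits, function(f) abs(f$coef),
    numeric(length(model$fits[[1]]$coef))
  )
  per_class <- matrix(per_class,
    ncol = length(model$fits),
    dimnames = list(names(model$fits[[1]]$coef), model$classes)
  )
  new_ranking("LR", rowMeans(per_class), per_class = per_class)
}

#' Impurity-decrease (Gini) importance of a fitted forest
#'
#' Accumulates the recorded Gini impurity decrease of every split of every
#' tree, per splitting feature.  The default score weights each node's
#' decrease by its sample fraction `n(node) / n(root)` (mean decrease in
#' impurity); the unweighted raw sum is reported alongside as
#' `score_raw`, and `score_normalized` rescales the default to sum to 1.
#'
#' @param forest A [fit_forest()] model (or single [fit_tree()]).
#' @param weighted Use the node-fraction weighting for the main score.
#' @return An `importance_ranking` tibble with extra columns `score_raw`
#'   and `score_normalized`.
#' @export
gini_importance <- function(forest, weighted = TRUE) {
  trees <- if (inherits(forest, "af_tree")) {
    list(forest$nodes)
  } else if (inherits(forest, "rhythm_forest")) {
    forest$trees
  } else {
    stop("gini_importance needs a native tree or forest", call. = FALSE)
  }
  feats <- forest$features
  raw <- wtd <- stats::setNames(numeric(length(feats)), feats)
  for (tr in trees) {
    internal <- which(tr$feature >= 0)
    if (length(internal) == 0) next
    f <- tr$feature[internal] + 1L
    d <- tr$delta[internal]
    w <- d * tr$n[internal] / tr$n[1]
    for (i in seq_along(internal)) {
      raw[f[i]] <- raw[f[i]] + d[i]
      wtd[f[i]] <- wtd[f[i]] + w[i]
    }
  }
  score <- if (weighted) wtd else raw
  norm <- if (sum(score) > 0) score / sum(score) else score
  new_ranking("Gini", score,
    extra = list(score_raw = unname(raw), score_normalized = unname(norm))
  )
}

#' Permutation importance
#'
#' For each feature, permutes its column in the evaluation data
#' `n_repeats` times and records the resulting increase in zero-one loss
#' (equivalently, the mean decrease in accuracy), reported per sample and
#' averaged over repeats.  The evaluation set is either held-out rows
#' passed via `data` (default) or, for native forests with
#' `oob = TRUE`, each tree's out-of-bag rows on the training data.
#'
#' @param model A fitted classifier supporting
#'   `predict(model, newdata, type = "class")`.
#' @param data Evaluation data frame (features + label column).
#' @param label Name of the label column.
#' @param n_repeats Number of permutations per feature.
#' @param seed Seed for the permutations.
#' @param oob Use out-of-bag evaluation (native forests only); `data`
#'   must then be the training data.
#' @return An `importance_ranking` tibble; scores are mean per-sample
#'   accuracy decreases.
#' @export
permutation_importance <- function(model, data, label = "label",
                                   n_repeats = 10, seed = NULL,
                                   oob = FALSE) {
  if (n_repeats < 1) stop("n_repeats must be >= 1", call. = FALSE)
  sp <- split_features(data, label)
  feats <- sp$features

  if (oob) {
    if (!inherits(model, "rhythm_forest")) {
      stop("oob evaluation is only available for native forests",
        call. = FALSE
      )
    }
    predict_cls <- function(x) oob_predict(model, x)
  } else {
    predict_cls <- function(x) {
      as.character(predict(model, x, type = "class"))
    }
  }

  y <- as.character(sp$y)
  base_err <- err_rate(predict_cls(sp$x), y)
  scores <- with_local_seed(seed, {
    vapply(seq_along(feats), function(j) {
      mean(vapply(seq_len(n_repeats), function(rep) {
        xp <- sp$x
        xp[, j] <- xp[sample.int(nrow(xp)), j]
        err_rate(predict_cls(xp), y) - base_err
      }, numeric(1)))
    }, numeric(1))
  })
  new_ranking("PT", stats::setNames(scores, feats))
}

err_rate <- function(pred, y) mean(pred != y, na.rm = TRUE)

# Out-of-bag class predictions of a native forest: each row is voted on
# only by trees whose bootstrap missed it.  Rows in every bag get NA.
oob_predict <- function(forest, x) {
  l <- length(forest$classes)
  acc <- matrix(0, nrow(x), l)
  cnt <- numeric(nrow(x))
  for (t in seq_along(forest$trees)) {
    rows <- forest$oob[[t]]
    if (length(rows) == 0) next
    p <- cpp_tree_proba(forest$trees[[t]], x[rows, , drop = FALSE])
    acc[rows, ] <- acc[rows, ] + p
    cnt[rows] <- cnt[rows] + 1
  }
  out <- rep(NA_character_, nrow(x))
  has <- cnt > 0
  out[has] <- forest$classes[max.col(acc[has, , drop = FALSE],
    ties.method = "first"
  )]
  out
}

#' Global Shapley importance from attribution matrices
#'
#' Reduces per-class Shapley attribution matrices (instances x features)
#' to one global ranking: the per-class score of a feature is the mean
#' attribution magnitude over instances, and the overall score averages
#' the per-class scores over the classes.  `reduce = "signed"` averages
#' raw attributions instead of magnitudes (sign cancellation possible;
#' kept for comparison).
#'
#' @param attributions A named list, one numeric matrix per class
#'   (instances in rows, features in columns), or the result of
#'   [tree_shap_batch()].
#' @param reduce `"absolute"` (default) or `"signed"`.
#' @return An `importance_ranking` tibble with the per-class score matrix
#'   in `attr(, "per_class")`.
#' @export
shap_global <- function(attributions, reduce = c("absolute", "signed")) {
  reduce <- match.arg(reduce)
  if (inherits(attributions, "af_attribution_batch")) {
    attributions <- attributions$per_class
  }
  stopifnot(is.list(attributions), length(attributions) >= 1)
  feats <- colnames(attributions[[1]])
  dims_ok <- vapply(
    attributions,
    function(m) identical(colnames(m), feats),
    logical(1)
  )
  if (!all(dims_ok)) stop("attribution matrices disagree on features")
  per_class <- vapply(
    attributions,
    function(m) {
      if (reduce == "absolute") colMeans(abs(m)) else colMeans(m)
    },
    numeric(length(feats))
  )
  per_class <- matrix(per_class,
    ncol = length(attributions),
    dimnames = list(feats, names(attributions))
  )
  new_ranking("SHAP", rowMeans(per_class), per_class = per_class)
}

#' Take the top-m features of a ranking
#'
#' @param ranking An `importance_ranking`.
#' @param m Number of features, `1 <= m <= nrow(ranking)`.
#' @return Character vector of the first `m` feature names in rank order.
#' @export
select_top <- function(ranking, m) {
  stopifnot(inherits(ranking, "importance_ranking"))
  if (m < 1 || m > nrow(ranking)) {
    stop("m must lie in 1..", nrow(ranking), call. = FALSE)
  }
  ranking$feature[seq_len(m)]
}
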