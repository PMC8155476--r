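#' Confusion matrix in the fixed rhythm-class order
#'
#' Rows are true classes, columns predicted classes, both in (N, A, O, ~)
#' order (or the factor's own levels for non-rhythm problems).  Entries
#' may be fractional, as in fold-averaged matrices.
#'
#' @param truth,estimate Label vectors (factors or characters).
#' @param classes Optional class order; defaults to the union's canonical
#'   order.
#' @return An `af_confusion` matrix.
#' @export
confusion_matrix <- function(truth, estimate, classes = NULL) {
  truth <- as.character(truth)
  estimate <- as.character(estimate)
  classes <- classes %||% levels(as_rhythm_factor(c(truth, estimate)))
  m <- table(
    factor(truth, levels = classes),
    factor(estimate, levels = classes)
  )
  m <- matrix(as.numeric(m), length(classes),
    dimnames = list(true = classes, predicted = classes)
  )
  structure(m, class = c("af_confusion", "matrix"))
}

#' @rdname confusion_matrix
#' @param m A square numeric matrix (true x predicted).
#' @export
as_confusion <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m), all(m >= 0))
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- rhythm_classes()[seq_len(nrow(m))]
  }
  structure(m, class = c("af_confusion", "matrix"))
}

#' Per-class TP / FP / FN / TN decomposition
#'
#' @param cm An `af_confusion` matrix.
#' @return A tibble with one row per class and columns `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion_counts <- function(cm) {
  cm <- as_confusion(cm)
  total <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tibble::tibble(
    class = rownames(cm),
    tp = unname(tp), fp = unname(fp), fn = unname(fn),
    tn = unname(total - tp - fp - fn)
  )
}

#' Micro-averaged precision, recall and F-score
#'
#' Counts are pooled over classes before the ratio is taken:
#' `P = sum(TP) / sum(TP + FP)`, `R = sum(TP) / sum(TP + FN)`,
#' `F = 2PR / (P + R)`.  For single-label multi-class data the three
#' coincide (total diagonal over total count).
#'
#' @param cm An `af_confusion` matrix.
#' @return A one-row tibble with `p_micro`, `r_micro`, `f_micro`.
#' @export
micro_scores <- function(cm) {
  cm <- as_confusion(cm)
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  cc <- confusion_counts(cm)
  p <- sum(cc$tp) / sum(cc$tp + cc$fp)
  r <- sum(cc$tp) / sum(cc$tp + cc$fn)
  tibble::tibble(p_micro = p, r_micro = r, f_micro = 2 * p * r / (p + r))
}

#' Macro-averaged precision, recall and F-score
#'
#' Per-class precision and recall are averaged over classes, and the
#' macro F is the harmonic mean of the two averages,
#' `F_M = 2 P_M R_M / (P_M + R_M)` (not the mean of per-class F-scores;
#' see [f_mean()] for that aggregate).  A class with an undefined 0/0
#' ratio contributes 0, with a warning.
#'
#' @param cm An `af_confusion` matrix.
#' @param quiet Suppress the 0/0 warning.
#' @return A one-row tibble with `p_macro`, `r_macro`, `f_macro`.
#' @export
macro_scores <- function(cm, quiet = FALSE) {
  pc <- per_class_f(cm, quiet = quiet)
  p <- mean(pc$precision)
  r <- mean(pc$recall)
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  tibble::tibble(p_macro = p, r_macro = r, f_macro = f)
}

#' Per-class precision, recall and F-score
#'
#' `F_i = 2 P_i R_i / (P_i + R_i)` per class; 0/0 ratios are scored 0
#' (warned once per call unless `quiet`).
#'
#' @inheritParams macro_scores
#' @return A tibble with `class`, `precision`, `recall`, `f`.
#' @export
per_class_f <- function(cm, quiet = FALSE) {
  cc <- confusion_counts(cm)
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  if (!quiet && any(cc$tp + cc$fp == 0 | cc$tp + cc$fn == 0)) {
    warning("0/0 precision or recall scored as 0", call. = FALSE)
  }
  p <- safe_div(cc$tp, cc$tp + cc$fp)
  r <- safe_div(cc$tp, cc$tp + cc$fn)
  tibble::tibble(
    class = cc$class, precision = p, recall = r,
    f = ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  )
}

#' Arithmetic mean of per-class F-scores
#'
#' The challenge-style aggregate: the plain mean of the per-class
#' F-scores (distinct from the macro F of [macro_scores()], which is the
#' harmonic mean of macro precision and recall).
#'
#' @param x An `af_confusion` matrix, or a numeric vector of per-class
#'   F-scores.
#' @param quiet Passed to [per_class_f()].
#' @return A single number.
#' @export
f_mean <- function(x, quiet = FALSE) {
  if (is.numeric(x) && is.null(dim(x))) {
    return(mean(x))
  }
  mean(per_class_f(x, quiet = quiet)$f)
}

#' Full score set of a confusion matrix
#'
#' @inheritParams macro_scores
#' @return One-row tibble: `f_micro`, `p_macro`, `r_macro`, `f_macro`,
#'   one `f_<class>` column per class, and `f_mean`.
#' @export
score_set <- function(cm, quiet = TRUE) {
  pc <- per_class_f(cm, quiet = quiet)
  fs <- stats::setNames(as.list(pc$f), paste0("f_", tolower(pc$class)))
  names(fs) <- sub("f_~", "f_p", names(fs), fixed = TRUE)
  dplyr::bind_cols(
    micro_scores(cm)["f_micro"],
    macro_scores(cm, quiet = quiet),
    tibble::as_tibble(fs),
    tibble::tibble(f_mean = mean(pc$f))
  )
}

#' One-vs-rest ROC AUC per class
#'
#' AUC via the midrank Mann-Whitney statistic (equivalent to the area
#' under the empirical ROC with tie-handling by trapezoids).
#'
#' @param scores Matrix or data frame of class scores (columns named by
#'   class).
#' @param truth True labels.
#' @return A tibble with `class` and `auc`.
#' @export
roc_auc <- function(scores, truth) {
  scores <- as.matrix(as.data.frame(scores))
  truth <- as.character(truth)
  if (length(unique(truth)) < 2) {
    stop("roc_auc needs at least two observed classes", call. = FALSE)
  }
  aucs <- vapply(colnames(scores), function(cl) {
    pos <- truth == cl
    n1 <- sum(pos)
    n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) {
      return(NA_real_)
    }
    r <- rank(scores[, cl])
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  tibble::tibble(class = colnames(scores), auc = unname(aucs))
}

# Stratified fold assignment: within each class, shuffled indices are
# dealt round-robin over k folds, so per-class fold sizes differ by <= 1.
stratified_folds <- function(y, k) {
  y <- as.factor(y)
  if (any(table(y) < k)) {
    stop("every class needs at least k members for stratified ", k,
      "-fold assignment",
      call. = FALSE
    )
  }
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated stratified k-fold cross-validation
#'
#' Stratified, seeded fold assignment; per-fold fit, class prediction and
#' scoring; aggregation by the elementwise mean of fold confusion
#' matrices and the mean of fold scores.
#'
#' @param data Data frame of features plus label column.
#' @param model_fn Classifier factory `function(data, label)` returning a
#'   model supporting `predict(model, newdata, type = "class")` (and
#'   `type = "prob"` if `keep_scores`).
#' @param label Name of the label column.
#' @param k Number of folds.
#' @param repeats Number of repetitions.
#' @param seed Seed for fold assignment (one derived seed per repeat).
#' @param keep_scores Also collect held-out class-probability scores (for
#'   ROC/AUC).
#' @return A `cv_report`: list with `scores` (per-fold score tibble),
#'   `mean_confusion` (fold-averaged `af_confusion`), `summary` (mean of
#'   fold scores), `folds`, and optionally `held_out` scores.
#' @export
crossval <- function(data, model_fn, label = "label", k = 10, repeats = 1,
                     seed = NULL, keep_scores = FALSE) {
  y <- as_rhythm_factor(data[[label]])
  folds <- with_local_seed(seed, {
    lapply(seq_len(repeats), function(r) stratified_folds(y, k))
  })
  per_fold <- list()
  cms <- list()
  held <- list()
  for (r in seq_len(repeats)) {
    for (fold in seq_len(k)) {
      test_idx <- which(folds[[r]] == fold)
      train <- data[-test_idx, , drop = FALSE]
      test <- data[test_idx, , drop = FALSE]
      model <- model_fn(train, label)
      pred <- predict(model, test, type = "class")
      cm <- confusion_matrix(y[test_idx], pred, classes = levels(y))
      cms[[length(cms) + 1]] <- cm
      per_fold[[length(per_fold) + 1]] <- dplyr::bind_cols(
        tibble::tibble(repeat_ = r, fold = fold),
        score_set(cm)
      )
      if (keep_scores) {
        held[[length(held) + 1]] <- dplyr::bind_cols(
          tibble::tibble(
            repeat_ = r, fold = fold,
            truth = as.character(y[test_idx])
          ),
          predict(model, test, type = "prob")
        )
      }
    }
  }
  scores <- dplyr::bind_rows(per_fold)
  mean_cm <- as_confusion(Reduce(`+`, cms) / length(cms))
  out <- list(
    scores = scores,
    mean_confusion = mean_cm,
    summary = dplyr::summarise(
      scores,
      dplyr::across(-c("repeat_", "fold"), mean)
    ),
    folds = folds,
    k = k, repeats = repeats, seed = seed, classes = levels(y)
  )
  if (keep_scores) out$held_out <- dplyr::bind_rows(held)
  structure(out, class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(
    "Cross-validation report:", x$k, "folds x", x$repeats,
    "repeat(s)\n"
  )
  print(x$summary)
  invisible(x)
}

#' Paired Wilcoxon signed-rank comparison of fold scores
#'
#' Zero differences are dropped; the exact null distribution is used for
#' up to 25 informative pairs (without ties), the normal approximation
#' beyond.  All-zero differences are a degenerate case and raise an
#' error.
#'
#' @param scores_a,scores_b Equal-length paired fold scores.
#' @return A tibble with `statistic`, `p_value`, `n_used`.
#' @export
wilcoxon_paired <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b))
  d <- scores_a - scores_b
  d <- d[d != 0]
  if (length(d) == 0) {
    stop("all paired differences are zero; comparison is degenerate",
      call. = FALSE
    )
  }
  if (length(d) < 5) {
    warning("fewer than 5 informative pairs; test has little power",
      call. = FALSE
    )
  }
  exact <- length(d) <= 25 && !any(duplicated(abs(d))) && !any(d == 0)
  ht <- suppressWarnings(stats::wilcox.test(d, exact = exact))
  tibble::tibble(
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    n_used = length(d)
  )
}

#' Incremental feature-selection curve
#'
#' Refits and cross-validates the classifier on the top-m features of a
#' ranking for each `m`, reusing identical fold assignments (same seed)
#' across all `m`, so the `m = k_features` endpoint coincides exactly
#' with the full-feature run.
#'
#' @param ranking An `importance_ranking` covering all feature columns of
#'   `data`.
#' @param data Data frame of features plus label.
#' @param model_fn Classifier factory as in [crossval()].
#' @param label Label column name.
#' @param k,repeats,seed Cross-validation settings, shared across `m`.
#' @param m_values Subset sizes to evaluate (default `1:n_features`).
#' @return An `fs_curve` tibble: `m`, `f_micro`, `f_macro`, `f_mean` and
#'   the per-class F columns, one row per subset size.
#' @export
feature_selection_curve <- function(ranking, data, model_fn,
                                    label = "label", k = 10, repeats = 1,
                                    seed = NULL, m_values = NULL) {
  feats <- setdiff(names(data), c(label, "record_id"))
  if (!setequal(ranking$feature, feats)) {
    stop("ranking must cover exactly the feature columns of `data`",
      call. = FALSE
    )
  }
  m_values <- m_values %||% seq_along(feats)
  rows <- lapply(m_values, function(m) {
    # keep the data's own column order so the m = k endpoint is the
    # full-feature run, byte for byte
    sel <- select_top(ranking, m)
    cols <- c(feats[feats %in% sel], label)
    cv <- crossval(data[cols], model_fn,
      label = label, k = k,
      repeats = repeats, seed = seed
    )
    dplyr::bind_cols(tibble::tibble(m = m), cv$summary)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("fs_curve", class(out))
  out
}
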