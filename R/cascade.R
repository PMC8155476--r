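#' Fit a cascaded multi-class classifier
#'
#' Three binary classifiers peel the four rhythm classes off one at a
#' time: stage 1 is trained on all rows (N vs rest), stage 2 on the non-N
#' rows (A vs rest), stage 3 on the rows labelled O or ~ (O vs ~).
#' Prediction routes through the stages: N if stage 1 says so, else A if
#' stage 2 says so, else stage 3 decides between O and ~.  A stage whose
#' training rows contain a single class degenerates to a constant
#' classifier for that class.
#'
#' @param data Data frame of features plus a 4-class label column.
#' @param label Name of the label column.
#' @param learner Binary-classifier factory: a function
#'   `function(data, label)` returning a model whose
#'   `predict(model, newdata, type = "prob")` yields a probability column
#'   per class.  Defaults to a small native forest.
#' @return An object of class `rhythm_cascade`.
#' @export
#' @examples
#' tbl <- simulate_gaussian_table(300, seed = 1)
#' csc <- fit_cascade(tbl, learner = function(d, label) {
#'   fit_forest(d, label, n_trees = 20, seed = 1)
#' })
#' table(predict(csc, tbl, type = "class"))
fit_cascade <- function(data, label = "label", learner = NULL) {
  learner <- learner %||%
    function(d, label) fit_forest(d, label, n_trees = 50, seed = 1)
  y <- as_rhythm_factor(data[[label]])
  if (nlevels(y) != 4) {
    stop("fit_cascade expects the 4-class rhythm problem", call. = FALSE)
  }
  cls <- levels(y)

  fit_stage <- function(rows, pos, neg_label) {
    d <- data[rows, , drop = FALSE]
    yy <- ifelse(as.character(y[rows]) == pos, pos, neg_label)
    present <- unique(yy)
    if (length(present) < 2) {
      structure(list(constant = present, classes = c(neg_label, pos)),
        class = "af_constant"
      )
    } else {
      d[[label]] <- factor(yy, levels = c(neg_label, pos))
      learner(d, label)
    }
  }

  s1 <- fit_stage(seq_along(y), cls[1], "rest")
  s2 <- fit_stage(which(y != cls[1]), cls[2], "rest")
  s3 <- fit_stage(which(y %in% cls[3:4]), cls[3], cls[4])
  structure(
    list(
      stages = list(s1, s2, s3), classes = cls, label = label,
      features = setdiff(names(data), c(label, "record_id"))
    ),
    class = "rhythm_cascade"
  )
}

#' @export
predict.af_constant <- function(object, newdata, type = c("prob", "class"),
                                ...) {
  type <- match.arg(type)
  n <- if (is.matrix(newdata)) nrow(newdata) else nrow(as.data.frame(newdata))
  p <- matrix(0, n, length(object$classes),
    dimnames = list(NULL, object$classes)
  )
  p[, object$constant] <- 1
  finish_prediction(p, type, object$classes)
}

#' @export
predict.rhythm_cascade <- function(object, newdata,
                                   type = c("prob", "class"), ...) {
  type <- match.arg(type)
  cls <- object$classes
  pos_prob <- function(stage, pos) {
    pr <- predict(stage, newdata, type = "prob")
    pr[[pos]]
  }
  p1 <- pos_prob(object$stages[[1]], cls[1])
  p2 <- pos_prob(object$stages[[2]], cls[2])
  p3 <- pos_prob(object$stages[[3]], cls[3])
  if (type == "class") {
    out <- ifelse(p1 >= 0.5, cls[1],
      ifelse(p2 >= 0.5, cls[2], ifelse(p3 >= 0.5, cls[3], cls[4]))
    )
    return(factor(out, levels = cls))
  }
  # chain-rule probabilities: exhaustive and exclusive over the 4 classes
  p <- cbind(
    p1,
    (1 - p1) * p2,
    (1 - p1) * (1 - p2) * p3,
    (1 - p1) * (1 - p2) * (1 - p3)
  )
  colnames(p) <- cls
  tibble::as_tibble(p)
}

#' Wrap an external classifier into the harness contract
#'
#' Adapts any pair of fit/predict-probability functions (e.g. an SVM or
#' boosting implementation from another package) to the classifier-factory
#' contract used by [crossval()] and the importance methods.  The wrapper
#' validates the probability output (one column per class, rows summing to
#' 1) at fit time and rejects predictors without probability output.
#'
#' @param fit Function `function(data, label)` returning an opaque fitted
#'   object.
#' @param predict_proba Function `function(object, newdata)` returning a
#'   matrix or data frame of class probabilities with class names as
#'   column names.
#' @return A classifier factory: `function(data, label)` returning an
#'   object of class `af_adapter`.
#' @export
adapter_wrap <- function(fit, predict_proba) {
  stopifnot(is.function(fit), is.function(predict_proba))
  function(data, label = "label") {
    y <- as_rhythm_factor(data[[label]])
    inner <- fit(data, label)
    model <- structure(
      list(
        inner = inner, predict_proba = predict_proba,
        classes = levels(y),
        features = setdiff(names(data), c(label, "record_id"))
      ),
      class = "af_adapter"
    )
    probe <- predict(model, utils::head(data, 2), type = "prob")
    if (!all(abs(rowSums(probe) - 1) < 1e-6)) {
      stop("adapter predictor must return class probabilities",
        call. = FALSE
      )
    }
    model
  }
}

#' @export
predict.af_adapter <- function(object, newdata, type = c("prob", "class"),
                               ...) {
  type <- match.arg(type)
  p <- object$predict_proba(object$inner, newdata)
  p <- as.matrix(as.data.frame(p))
  if (is.null(colnames(p)) || !all(object$classes %in% colnames(p))) {
    stop("adapter probabilities must be named by class", call. = FALSE)
  }
  p <- p[, object$classes, drop = FALSE]
  if (any(p < -1e-9)) {
    stop("adapter probabilities must be nonnegative", call. = FALSE)
  }
  finish_prediction(p, type, object$classes)
}
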