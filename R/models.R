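# -- data-frame <-> matrix plumbing -----------------------------------------

# Split a modelling data frame into a numeric feature matrix and the label
# factor.  `record_id` is ignored if present.  Missing feature values (the
# explicit missing markers of short RR records) are imputed with the column
# median; the imputation vector is kept so prediction uses the training
# medians.
split_features <- function(data, label = "label") {
  stopifnot(is.data.frame(data), label %in% names(data))
  y <- as_rhythm_factor(data[[label]])
  feats <- setdiff(names(data), c(label, "record_id"))
  x <- as.matrix(data[feats])
  storage.mode(x) <- "double"
  impute <- apply(x, 2, stats::median, na.rm = TRUE)
  impute[!is.finite(impute)] <- 0
  for (j in seq_along(feats)) {
    miss <- !is.finite(x[, j])
    if (any(miss)) x[miss, j] <- impute[j]
  }
  list(x = x, y = y, features = feats, impute = impute)
}

#' Fit a single classification tree
#'
#' Greedy CART on the Gini impurity criterion.  At every node the split
#' search runs over a seeded random subset of `mtry` features and all
#' midpoints between sorted distinct values, choosing the pair with the
#' maximal impurity decrease; ties go to the lowest feature index, then
#' the lowest threshold.  Nodes record per-class sample counts, impurity
#' and the impurity decrease of their split.
#'
#' @param data Data frame of numeric features plus a label column
#'   (`record_id`, if present, is ignored).
#' @param label Name of the label column.
#' @param max_depth Maximum depth (`Inf` = grow to purity).
#' @param min_leaf Minimum samples per child.
#' @param mtry Features tried per node (default: all).
#' @param seed Optional seed for the feature subsampling.
#' @return An object of class `af_tree`.
#' @export
#' @examples
#' d <- data.frame(x = c(1, 2, 3, 4), label = c("N", "N", "A", "A"))
#' fit_tree(d)
fit_tree <- function(data, label = "label", max_depth = Inf, min_leaf = 1,
                     mtry = NULL, seed = NULL) {
  sp <- split_features(data, label)
  if (nrow(sp$x) < 1) stop("no samples", call. = FALSE)
  mtry <- mtry %||% ncol(sp$x)
  md <- if (is.finite(max_depth)) as.integer(max_depth) else 0L
  nodes <- with_local_seed(seed, {
    cpp_fit_tree(
      sp$x, as.integer(sp$y) - 1L, nlevels(sp$y),
      seq_len(nrow(sp$x)) - 1L, md, as.integer(min_leaf),
      as.integer(mtry)
    )
  })
  structure(
    list(
      nodes = nodes, classes = levels(sp$y), features = sp$features,
      impute = sp$impute, min_leaf = min_leaf, max_depth = max_depth
    ),
    class = "af_tree"
  )
}

#' @export
predict.af_tree <- function(object, newdata, type = c("prob", "class"),
                            ...) {
  type <- match.arg(type)
  x <- feature_matrix(newdata, object$features, object$impute)
  p <- cpp_tree_proba(object$nodes, x)
  colnames(p) <- object$classes
  finish_prediction(p, type, object$classes)
}

#' Fit a random forest of native CART trees
#'
#' `n_trees` bootstrap resamples (with replacement, original size), one
#' [fit_tree()] per resample with independent random feature subsets per
#' node.  Prediction averages the per-tree leaf class probabilities; the
#' predicted class is the one with the largest mean probability, ties
#' broken by the fixed class order.
#'
#' @inheritParams fit_tree
#' @param n_trees Number of trees.
#' @param mtry Features tried per node; default `ceiling(sqrt(k))`.
#' @param bootstrap Set `FALSE` to train every tree on the full sample
#'   (then there are no out-of-bag rows).
#' @param seed Seed governing bootstraps and feature subsampling.
#' @return An object of class `rhythm_forest`, with per-tree out-of-bag
#'   row indices in `$oob`.
#' @export
#' @examples
#' tbl <- simulate_gaussian_table(120, seed = 1)
#' fit <- fit_forest(tbl, n_trees = 10, seed = 1)
#' head(predict(fit, tbl))
fit_forest <- function(data, label = "label", n_trees = 100,
                       max_depth = Inf, min_leaf = 1, mtry = NULL,
                       bootstrap = TRUE, seed = NULL) {
  if (n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  sp <- split_features(data, label)
  n <- nrow(sp$x)
  k <- ncol(sp$x)
  mtry <- mtry %||% ceiling(sqrt(k))
  md <- if (is.finite(max_depth)) as.integer(max_depth) else 0L
  fit <- with_local_seed(seed, {
    trees <- vector("list", n_trees)
    oob <- vector("list", n_trees)
    for (t in seq_len(n_trees)) {
      rows <- if (bootstrap) {
        sample.int(n, n, replace = TRUE)
      } else {
        seq_len(n)
      }
      oob[[t]] <- setdiff(seq_len(n), rows)
      trees[[t]] <- cpp_fit_tree(
        sp$x, as.integer(sp$y) - 1L, nlevels(sp$y), rows - 1L,
        md, as.integer(min_leaf), as.integer(mtry)
      )
    }
    list(trees = trees, oob = oob)
  })
  structure(
    list(
      trees = fit$trees, oob = fit$oob, classes = levels(sp$y),
      features = sp$features, impute = sp$impute,
      n_trees = n_trees, mtry = mtry,
      min_leaf = min_leaf, max_depth = max_depth, n_train = n
    ),
    class = "rhythm_forest"
  )
}

#' @export
predict.rhythm_forest <- function(object, newdata,
                                  type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- feature_matrix(newdata, object$features, object$impute)
  p <- cpp_forest_proba(object$trees, x, length(object$classes))
  colnames(p) <- object$classes
  finish_prediction(p, type, object$classes)
}

#' @export
print.rhythm_forest <- function(x, ...) {
  cat(
    "Native random forest:", x$n_trees, "trees,",
    length(x$features), "features, classes",
    paste(x$classes, collapse = "/"), "\n"
  )
  invisible(x)
}

feature_matrix <- function(newdata, features, impute = NULL) {
  if (is.matrix(newdata)) {
    if (ncol(newdata) != length(features)) {
      stop("feature-count mismatch", call. = FALSE)
    }
    x <- newdata
  } else {
    missing <- setdiff(features, names(newdata))
    if (length(missing) > 0) {
      stop(
        "missing features: ", paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    x <- as.matrix(as.data.frame(newdata)[features])
  }
  storage.mode(x) <- "double"
  if (!is.null(impute) && anyNA(x)) {
    for (j in seq_len(ncol(x))) {
      miss <- !is.finite(x[, j])
      if (any(miss)) x[miss, j] <- impute[j]
    }
  }
  x
}

finish_prediction <- function(p, type, classes) {
  if (type == "prob") {
    return(tibble::as_tibble(p))
  }
  factor(classes[max.col(p, ties.method = "first")], levels = classes)
}

# -- serialization ----------------------------------------------------------

#' Serialize and restore fitted tree models
#'
#' Writes a fitted `af_tree` or `rhythm_forest` as structured JSON text
#' capturing the full node arrays (features, thresholds, children, class
#' counts, impurities and split impurity decreases), so models can be
#' reloaded or inspected outside R.
#'
#' @param model A fitted `af_tree` or `rhythm_forest`.
#' @param path File path.
#' @return `read_model()` returns the restored model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, c("af_tree", "rhythm_forest")))
  payload <- unclass(model)
  payload$.class <- class(model)
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path,
    simplifyVector = TRUE,
    simplifyDataFrame = FALSE
  )
  cls <- payload$.class
  payload$.class <- NULL
  fix_nodes <- function(nodes) {
    nodes$counts <- as.matrix(nodes$counts)
    nodes$prob <- as.matrix(nodes$prob)
    nodes$feature <- as.integer(nodes$feature)
    nodes$left <- as.integer(nodes$left)
    nodes$right <- as.integer(nodes$right)
    nodes$n <- as.integer(nodes$n)
    nodes$threshold <- as.numeric(nodes$threshold)
    nodes
  }
  if ("trees" %in% names(payload)) {
    payload$trees <- lapply(payload$trees, fix_nodes)
    payload$oob <- lapply(payload$oob, as.integer)
  } else {
    payload$nodes <- fix_nodes(payload$nodes)
  }
  structure(payload, class = cls)
}
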