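# Attribution container: per-feature additive contributions phi (features
# x outputs), base value (prediction with no features present) and the
# explained output fx, satisfying base + colSums(phi) = fx.
new_attribution <- function(phi, base, fx, method) {
  structure(
    list(phi = phi, base = base, fx = fx, method = method),
    class = "af_attribution"
  )
}

#' @export
print.af_attribution <- function(x, ...) {
  cat("Shapley attribution (", x$method, "), ", nrow(x$phi),
    " features x ", ncol(x$phi), " outputs\n",
    sep = ""
  )
  cat(
    "local accuracy residual:",
    format(max(abs(x$base + colSums(x$phi) - x$fx))), "\n"
  )
  invisible(x)
}

# Normalize a predict function's output to a numeric matrix (n x outputs).
predict_as_matrix <- function(predict_fn, x_rows) {
  out <- predict_fn(x_rows)
  if (is.data.frame(out)) out <- as.matrix(out)
  if (!is.matrix(out)) out <- matrix(out, ncol = 1)
  out
}

#' Interventional coalition value
#'
#' Value of a feature coalition `S` for instance `x`: the mean prediction
#' over the background rows with the features in `S` replaced by `x`'s
#' values (features outside `S` keep the background values, realizing
#' "absence" by marginalization over the background distribution).
#'
#' @param predict_fn Function taking a feature matrix and returning a
#'   numeric vector or a matrix with one column per output.
#' @param x Numeric feature vector of the explained instance.
#' @param S Integer vector of present-feature indices (may be empty).
#' @param background Numeric matrix of reference rows (same feature
#'   arity as `x`).
#' @return Numeric vector, one value per model output.
#' @export
coalition_value <- function(predict_fn, x, S, background) {
  background <- as.matrix(background)
  if (nrow(background) == 0) stop("background must be nonempty")
  stopifnot(length(x) == ncol(background), all(S %in% seq_along(x)))
  comp <- background
  if (length(S) > 0) {
    comp[, S] <- matrix(x[S], nrow(comp), length(S), byrow = TRUE)
  }
  colMeans(predict_as_matrix(predict_fn, comp))
}

# Exact Shapley values of an explicit game: v is a (2^M x outputs) matrix
# (or 2^M vector) of coalition values indexed by bitmask + 1 (bit j =
# feature j present).  Returns the (M x outputs) phi matrix.
#' Exact Shapley values of an enumerated game
#'
#' Computes Shapley values directly from a table of coalition values, one
#' per subset of `M` players indexed by bitmask (+1).  Useful for
#' hand-built games and consistency checks.
#'
#' @param v Numeric vector of length `2^M`, or a `2^M x outputs` matrix.
#' @param M Number of players.
#' @return An `M x outputs` matrix of Shapley values.
#' @export
#' @examples
#' # two-player product game: v(12) = 1, others 0
#' shapley_from_game(c(0, 0, 0, 1), M = 2)
shapley_from_game <- function(v, M) {
  if (!is.matrix(v)) v <- matrix(v, ncol = 1)
  stopifnot(nrow(v) == 2^M)
  sizes <- vapply(
    0:(2^M - 1),
    function(s) sum(bitwAnd(s, 2^(0:(M - 1))) > 0), numeric(1)
  )
  wts <- exp(lfactorial(0:(M - 1)) + lfactorial(M - (0:(M - 1)) - 1) -
    lfactorial(M))
  phi <- matrix(0, M, ncol(v))
  for (sub in 0:(2^M - 1)) {
    s <- sizes[sub + 1]
    for (j in seq_len(M)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(sub, bit) > 0) next
      phi[j, ] <- phi[j, ] + wts[s + 1] * (v[bitwOr(sub, bit) + 1, ] -
        v[sub + 1, ])
    }
  }
  phi
}

# Evaluate the interventional game for every subset of M features,
# batching the composite rows through predict_fn.
enumerate_game <- function(predict_fn, x, background, M) {
  nb <- nrow(background)
  masks <- 0:(2^M - 1)
  # chunk masks so a single predict call stays below ~2^16 rows
  chunk <- max(1L, 2L^16 %/% nb)
  v <- NULL
  for (start in seq(1, length(masks), by = chunk)) {
    idx <- masks[start:min(start + chunk - 1, length(masks))]
    rows <- do.call(rbind, lapply(idx, function(sub) {
      S <- which(bitwAnd(sub, 2^(0:(M - 1))) > 0)
      comp <- background
      if (length(S) > 0) {
        comp[, S] <- matrix(x[S], nb, length(S), byrow = TRUE)
      }
      comp
    }))
    pred <- predict_as_matrix(predict_fn, rows)
    grp <- rep(seq_along(idx), each = nb)
    vv <- apply(pred, 2, function(col) tapply(col, grp, mean))
    if (length(idx) == 1) vv <- matrix(vv, nrow = 1)
    v <- rbind(v, vv)
  }
  v
}

#' Exact interventional Shapley attribution
#'
#' Computes exact Shapley values for one instance by full subset
#' enumeration of the interventional coalition value
#' ([coalition_value()]), so `2^M` coalition evaluations over the
#' background set.  Capped at `M <= 12` features; beyond the cap use
#' [shapley_sampled()].
#'
#' @inheritParams coalition_value
#' @param background Matrix or data frame of background rows.
#' @return An `af_attribution` with `phi` (features x outputs), `base`
#'   (mean background prediction) and `fx` (= `predict_fn(x)`); local
#'   accuracy `base + colSums(phi) = fx` holds by construction.
#' @export
shapley_exact <- function(predict_fn, x, background) {
  background <- as.matrix(background)
  M <- length(x)
  if (M > 12) {
    stop("shapley_exact enumerates 2^M subsets and is capped at M = 12; ",
      "use shapley_sampled()",
      call. = FALSE
    )
  }
  v <- enumerate_game(predict_fn, x, background, M)
  phi <- shapley_from_game(v, M)
  rownames(phi) <- names(x) %||% colnames(background)
  new_attribution(phi,
    base = v[1, ], fx = v[nrow(v), ],
    method = "interventional_exact"
  )
}

#' Permutation-sampling Shapley attribution
#'
#' Castro-style unbiased estimate: for each sampled permutation of the
#' features, accumulate each feature's marginal contribution when added
#' in permutation order; the average over permutations converges to the
#' exact Shapley values.
#'
#' @inheritParams shapley_exact
#' @param n_permutations Number of sampled permutations.
#' @param seed Seed.
#' @return An `af_attribution`; the reported `fx` is the full-coalition
#'   value, and local accuracy holds exactly for every sample size.
#' @export
shapley_sampled <- function(predict_fn, x, background, n_permutations = 200,
                            seed = NULL) {
  stopifnot(n_permutations >= 1)
  background <- as.matrix(background)
  M <- length(x)
  nb <- nrow(background)
  phi <- NULL
  with_local_seed(seed, {
    base <- coalition_value(predict_fn, x, integer(0), background)
    fx <- coalition_value(predict_fn, x, seq_len(M), background)
    phi <- matrix(0, M, length(base))
    for (p in seq_len(n_permutations)) {
      perm <- sample.int(M)
      # batch the M prefix coalitions into one predict call
      rows <- do.call(rbind, lapply(seq_len(M), function(i) {
        S <- perm[seq_len(i)]
        comp <- background
        comp[, S] <- matrix(x[S], nb, length(S), byrow = TRUE)
        comp
      }))
      pred <- predict_as_matrix(predict_fn, rows)
      grp <- rep(seq_len(M), each = nb)
      vv <- apply(pred, 2, function(col) tapply(col, grp, mean))
      if (M == 1) vv <- matrix(vv, nrow = 1)
      prev <- base
      for (i in seq_len(M)) {
        phi[perm[i], ] <- phi[perm[i], ] + (vv[i, ] - prev) / n_permutations
        prev <- vv[i, ]
      }
    }
    rownames(phi) <- names(x) %||% colnames(background)
    new_attribution(phi,
      base = base, fx = fx,
      method = "interventional_sampled"
    )
  })
}

#' Tree-conditional expected prediction
#'
#' Expected prediction of a tree (or the mean over a forest's trees) when
#' only the features in `S` are known: the traversal follows `x`'s branch
#' at nodes splitting on a feature in `S` and averages both children,
#' weighted by their training-sample fractions, elsewhere.
#'
#' @param model An `af_tree` or `rhythm_forest`.
#' @param x Numeric feature vector.
#' @param S Integer indices (into `model$features`) of known features.
#' @return Named numeric vector of class probabilities.
#' @export
tree_expected_value <- function(model, x, S) {
  stopifnot(all(S %in% seq_along(x)))
  in_s <- seq_along(x) %in% S
  if (inherits(model, "af_tree")) {
    out <- cpp_tree_expected(model$nodes, as.numeric(x), in_s)
  } else if (inherits(model, "rhythm_forest")) {
    out <- drop(cpp_forest_coalition(
      model$trees, as.numeric(x), in_s,
      length(model$classes)
    ))
  } else {
    stop("tree_expected_value needs a native tree or forest", call. = FALSE)
  }
  stats::setNames(as.numeric(out), model$classes)
}

#' Tree-conditional Shapley attribution
#'
#' Shapley values of the tree-conditional game, whose coalition value is
#' the forest-mean [tree_expected_value()].  `method = "exact"` runs the
#' reference subset enumeration (capped at 12 features);
#' `method = "sampled"` uses permutation sampling and scales to larger
#' feature sets.  Attributions are per class, on the probability scale.
#'
#' @param forest A [fit_forest()] model (or single tree).
#' @param x Numeric feature vector or one-row data frame.
#' @param method `"exact"` or `"sampled"`.
#' @param n_permutations Permutations for the sampled method.
#' @param seed Seed for the sampled method.
#' @return An `af_attribution` with one column of `phi` per class.
#' @export
tree_shap <- function(forest, x, method = c("exact", "sampled"),
                      n_permutations = 64, seed = NULL) {
  method <- match.arg(method)
  if (inherits(forest, "af_tree")) {
    forest <- structure(
      list(
        trees = list(forest$nodes), classes = forest$classes,
        features = forest$features
      ),
      class = "rhythm_forest"
    )
  }
  stopifnot(inherits(forest, "rhythm_forest"))
  if (is.data.frame(x)) {
    x <- drop(feature_matrix(x, forest$features, forest$impute))
  }
  M <- length(x)
  if (method == "exact") {
    if (M > 12) {
      stop("exact tree Shapley is capped at 12 features; use sampled",
        call. = FALSE
      )
    }
    res <- cpp_tree_shap_exact(
      forest$trees, as.numeric(x),
      length(forest$classes)
    )
    tag <- "tree_conditional_exact"
  } else {
    res <- with_local_seed(seed, {
      out <- cpp_tree_shap_sampled(
        forest$trees,
        matrix(as.numeric(x), nrow = 1),
        length(forest$classes), as.integer(n_permutations)
      )
      list(
        phi = matrix(out$phi, M, length(forest$classes)),
        base = drop(out$base), fx = drop(out$fx)
      )
    })
    tag <- "tree_conditional_sampled"
  }
  phi <- matrix(res$phi, M, length(forest$classes))
  dimnames(phi) <- list(forest$features, forest$classes)
  new_attribution(phi,
    base = stats::setNames(as.numeric(res$base), forest$classes),
    fx = stats::setNames(as.numeric(res$fx), forest$classes),
    method = tag
  )
}

#' Batch tree-conditional Shapley attributions
#'
#' Sampled tree-conditional attributions for every row of `data`,
#' returned both as an array and as one instances-x-features matrix per
#' class, ready for [shap_global()].
#'
#' @param forest A [fit_forest()] model.
#' @param data Data frame or matrix of instances to explain (label and
#'   `record_id` columns are ignored).
#' @param n_permutations Sampled permutations per instance.
#' @param seed Seed.
#' @return An `af_attribution_batch`: list with `phi` (n x M x classes
#'   array), `base`, `fx` (n x classes matrices) and `per_class` (named
#'   list of n x M matrices).
#' @export
tree_shap_batch <- function(forest, data, n_permutations = 16,
                            seed = NULL) {
  stopifnot(inherits(forest, "rhythm_forest"))
  x <- feature_matrix(data, forest$features, forest$impute)
  l <- length(forest$classes)
  res <- with_local_seed(seed, {
    cpp_tree_shap_sampled(
      forest$trees, x, l,
      as.integer(n_permutations)
    )
  })
  phi <- array(res$phi, c(nrow(x), ncol(x), l),
    dimnames = list(NULL, forest$features, forest$classes)
  )
  per_class <- lapply(seq_len(l), function(k) {
    matrix(phi[, , k], nrow(x), ncol(x),
      dimnames = list(NULL, forest$features)
    )
  })
  names(per_class) <- forest$classes
  structure(
    list(
      phi = phi,
      base = matrix(res$base, nrow(x), l,
        dimnames = list(NULL, forest$classes)
      ),
      fx = matrix(res$fx, nrow(x), l,
        dimnames = list(NULL, forest$classes)
      ),
      per_class = per_class
    ),
    class = "af_attribution_batch"
  )
}

#' Executable checks of the Shapley axioms
#'
#' Verifies, on a concrete model and instance, the three defining
#' properties of Shapley attributions: local accuracy (base value plus
#' contributions equals the prediction), missingness (a feature identical
#' across `x` and all background rows gets zero attribution) and, when a
#' second game is supplied, consistency (a game whose marginal
#' contributions for feature `j` weakly dominate the first game's gives
#' `phi_j` at least as large).
#'
#' @inheritParams shapley_exact
#' @param games Optional list of two `2^M` game-value vectors
#'   `list(f = , f_prime = )` and a feature index `j`, as
#'   `list(v = , v_prime = , j = )`, for the consistency check.
#' @param tol Numeric tolerance.
#' @return A tibble with one row per check: `axiom`, `value` (worst
#'   residual, or the consistency margin) and `pass`.
#' @export
shap_axiom_checks <- function(predict_fn, x, background, games = NULL,
                              tol = 1e-9) {
  att <- shapley_exact(predict_fn, x, background)
  local_acc <- max(abs(att$base + colSums(att$phi) - att$fx))
  background <- as.matrix(background)
  constant <- vapply(
    seq_along(x),
    function(j) all(background[, j] == x[j]), logical(1)
  )
  missingness <- if (any(constant)) {
    max(abs(att$phi[constant, , drop = FALSE]))
  } else {
    0
  }
  out <- tibble::tibble(
    axiom = c("local_accuracy", "missingness"),
    value = c(local_acc, missingness),
    pass = c(local_acc <= tol, missingness <= tol)
  )
  if (!is.null(games)) {
    M <- round(log2(length(games$v)))
    phi <- shapley_from_game(games$v, M)
    phi_p <- shapley_from_game(games$v_prime, M)
    margin <- phi_p[games$j, 1] - phi[games$j, 1]
    out <- dplyr::bind_rows(out, tibble::tibble(
      axiom = "consistency",
      value = margin,
      pass = margin >= -tol
    ))
  }
  out
}
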