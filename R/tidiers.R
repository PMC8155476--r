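# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @export
tidy.rhythm_forest <- function(x, ...) {
  tibble::as_tibble(gini_importance(x))
}

#' @export
glance.rhythm_forest <- function(x, ...) {
  depth_of <- function(nodes) {
    depth <- integer(length(nodes$feature))
    for (i in seq_along(depth)) {
      for (ch in c(nodes$left[i], nodes$right[i])) {
        if (ch >= 0) depth[ch + 1] <- depth[i] + 1
      }
    }
    max(depth)
  }
  tibble::tibble(
    n_trees = x$n_trees,
    n_features = length(x$features),
    mtry = x$mtry,
    n_train = x$n_train,
    mean_depth = mean(vapply(x$trees, depth_of, numeric(1))),
    mean_leaves = mean(vapply(
      x$trees, function(t) sum(t$feature < 0),
      numeric(1)
    ))
  )
}

#' @export
tidy.af_logit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coef)),
    estimate = c(x$intercept, unname(x$coef))
  )
}

#' @export
glance.af_logit <- function(x, ...) {
  tibble::tibble(
    logLik = x$llf, lambda = x$lambda, converged = x$converged
  )
}

#' @export
tidy.af_attribution <- function(x, ...) {
  tibble::as_tibble(x$phi, rownames = "feature") |>
    tidyr::pivot_longer(-"feature",
      names_to = "class", values_to = "phi"
    ) |>
    dplyr::mutate(
      base_value = unname(x$base[.data$class]),
      output_value = unname(x$fx[.data$class])
    ) |>
    dplyr::relocate("class", .before = "feature")
}

#' @export
tidy.cv_report <- function(x, ...) {
  x$scores
}

#' @export
glance.cv_report <- function(x, ...) {
  x$summary
}

#' @export
tidy.af_confusion <- function(x, ...) {
  tibble::as_tibble(unclass(x), rownames = "true") |>
    tidyr::pivot_longer(-"true",
      names_to = "predicted",
      values_to = "count"
    )
}

#' @export
autoplot.importance_ranking <- function(object, top = 20, ...) {
  d <- utils::head(tibble::as_tibble(object), top)
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = stats::reorder(.data$feature, .data$score),
      y = .data$score
    )
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "importance",
      title = paste0(object$method[1], " feature importance")
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.af_attribution <- function(object, class = NULL, top = 10, ...) {
  d <- tidy(object)
  class <- class %||% d$class[1]
  d <- d |>
    dplyr::filter(.data$class == !!class) |>
    dplyr::arrange(dplyr::desc(abs(.data$phi))) |>
    utils::head(top)
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = stats::reorder(.data$feature, abs(.data$phi)),
      y = .data$phi, fill = .data$phi > 0
    )
  ) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c("steelblue", "firebrick")) +
    ggplot2::labs(
      x = NULL, y = "contribution to predicted probability",
      title = paste0(
        "Shapley attribution, class ", class,
        " (base ", signif(object$base[class], 3),
        ", output ", signif(object$fx[class], 3), ")"
      )
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fs_curve <- function(object, metric = "f_micro", ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$m, y = .data[[metric]])
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "number of top-ranked features", y = metric,
      title = "Incremental feature-selection curve"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.af_confusion <- function(object, ...) {
  d <- tidy(object)
  d$true <- factor(d$true, levels = rev(rownames(object)))
  d$predicted <- factor(d$predicted, levels = colnames(object))
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$predicted, y = .data$true, fill = .data$count)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$count, 1))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = "Confusion matrix (true x predicted)") +
    ggplot2::theme_minimal()
}
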