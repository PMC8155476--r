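table3 <- function() reference_confusion()

test_that("micro scores pool counts before the ratio", {
  perfect <- as_confusion(diag(c(10, 20, 30, 40)))
  expect_equal(micro_scores(perfect)$f_micro, 1)

  t3 <- micro_scores(table3())
  expect_equal(t3$f_micro, 7103 / 8528, tolerance = 1e-12)
  expect_equal(t3$p_micro, t3$r_micro)

  all_one <- as_confusion(matrix(c(5, 5, 0, 0), 2))
  expect_equal(micro_scores(all_one)$f_micro, 0.5)
  expect_error(micro_scores(as_confusion(matrix(0, 2, 2))), "empty")
})

test_that("macro scores average per-class ratios", {
  perfect <- as_confusion(diag(4))
  m <- macro_scores(perfect)
  expect_equal(unlist(m), c(p_macro = 1, r_macro = 1, f_macro = 1))

  t3 <- macro_scores(table3())
  want_p <- mean(c(4724 / 5448, 519 / 647, 1715 / 2225, 145 / 208))
  expect_equal(t3$p_macro, want_p, tolerance = 1e-12)
  expect_equal(t3$p_macro, 0.7843, tolerance = 1e-4)

  # a class never predicted contributes precision 0 (with a warning)
  never <- as_confusion(matrix(c(5, 5, 0, 0), 2, byrow = FALSE))
  expect_warning(m2 <- macro_scores(never), "0/0")
  expect_equal(m2$p_macro, (5 / 10 + 0) / 2)
})

test_that("per-class F matches the published worked example", {
  pc <- per_class_f(table3())
  expect_equal(round(pc$f[pc$class == "N"] * 1000) / 1000, 0.900)
  expect_equal(round(pc$f[pc$class == "O"] * 1000) / 1000, 0.733)
  expect_equal(f_mean(c(0.900, 0.768, 0.733, 0.579)), 0.745)
  expect_equal(f_mean(c(0.899, 0.740, 0.730, 0.596)), 0.74125)
})

test_that("confusion count identities hold on random matrices", {
  set.seed(81)
  for (i in 1:100) {
    l <- sample(2:5, 1)
    cm <- as_confusion(matrix(rpois(l * l, 8), l))
    cc <- confusion_counts(cm)
    expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, rep(sum(cm), l))
    expect_equal(cc$tp, unname(diag(cm)))
    expect_equal(cc$fp, unname(colSums(cm) - diag(cm)))
    expect_equal(cc$fn, unname(rowSums(cm) - diag(cm)))

    oracle <- scores_oracle(cm)
    expect_equal(micro_scores(cm)$f_micro, oracle$f_micro)
    ms <- macro_scores(cm, quiet = TRUE)
    expect_equal(ms$p_macro, oracle$p_macro)
    expect_equal(ms$r_macro, oracle$r_macro)
    expect_equal(ms$f_macro, oracle$f_macro)
    expect_equal(per_class_f(cm, quiet = TRUE)$f, unname(oracle$f_class))
  }
})

test_that("micro precision, recall and F coincide for single-label data", {
  set.seed(82)
  truth <- sample(rhythm_classes(), 300, TRUE)
  pred <- sample(rhythm_classes(), 300, TRUE)
  cm <- confusion_matrix(truth, pred)
  ms <- micro_scores(cm)
  expect_equal(ms$p_micro, ms$r_micro)
  expect_equal(ms$p_micro, ms$f_micro)
  expect_equal(ms$f_micro, mean(truth == pred))
})

test_that("rank-statistic AUC equals trapezoidal ROC integration", {
  # scores ascending toward class b: reversed for a (AUC 0), perfect
  # for b (AUC 1)
  expect_equal(
    roc_auc(cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4)),
      c("a", "a", "b", "b"))$auc,
    c(0, 1)
  )
  set.seed(83)
  for (i in 1:20) {
    n <- 60
    score <- round(rnorm(n), 1) # ties on purpose
    pos <- sample(c(TRUE, FALSE), n, TRUE)
    got <- roc_auc(
      cbind(x = score, y = -score),
      ifelse(pos, "x", "y")
    )$auc[1]
    want <- auc_trapezoid_oracle(score, pos)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # large-sample random scores sit near 1/2
  set.seed(84)
  rnd <- roc_auc(
    cbind(x = rnorm(4000)),
    sample(c("x", "o"), 4000, TRUE)
  )
  expect_lt(abs(rnd$auc - 0.5), 0.03)
  expect_error(roc_auc(cbind(x = 1:3), c("x", "x", "x")), "two")
})

test_that("AUC agrees with the pROC reference implementation", {
  set.seed(85)
  score <- rnorm(100)
  pos <- sample(c(TRUE, FALSE), 100, TRUE)
  got <- roc_auc(cbind(x = score), ifelse(pos, "x", "o"))$auc[1]
  want <- as.numeric(pROC::auc(pROC::roc(
    response = pos, predictor = score,
    levels = c(FALSE, TRUE), direction = "<", quiet = TRUE
  )))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("stratified cross-validation partitions each class evenly", {
  tbl <- simulate_gaussian_table(400, seed = 86)
  folds1 <- afexplain:::stratified_folds
  set.seed(1)
  f1 <- folds1(tbl$label, 5)
  for (cl in rhythm_classes()) {
    sizes <- table(f1[tbl$label == cl])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  cv1 <- crossval(tbl, function(d, label) {
    fit_forest(d, label, n_trees = 5, seed = 1)
  }, k = 5, seed = 7)
  cv2 <- crossval(tbl, function(d, label) {
    fit_forest(d, label, n_trees = 5, seed = 1)
  }, k = 5, seed = 7)
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(cv1$scores, cv2$scores)
  # averaged matrix is the elementwise mean of fold matrices
  expect_equal(sum(cv1$mean_confusion), 400 / 5, tolerance = 1e-9)
  expect_error(
    crossval(tbl[1:20, ], function(d, label) NULL, k = 10),
    "at least k"
  )
})

test_that("a perfect classifier scores 1 in every fold", {
  tbl <- simulate_gaussian_table(200, seed = 87)
  oracle_clf <- structure(list(), class = "label_peek")
  registerS3method(
    "predict", "label_peek",
    function(object, newdata, type = "class", ...) newdata$label
  )
  cv <- crossval(
    dplyr::mutate(tbl, label2 = label),
    function(d, label) oracle_clf,
    label = "label2", k = 4, seed = 2
  )
  expect_true(all(cv$scores$f_micro == 1))
  expect_true(all(cv$scores$f_macro == 1))
})

test_that("Wilcoxon comparison matches the exact sign-enumeration null", {
  set.seed(88)
  a <- c(0.81, 0.83, 0.85, 0.80, 0.86, 0.84)
  b <- c(0.78, 0.84, 0.81, 0.78, 0.80, 0.79) # distinct |d|, no zeros
  got <- suppressWarnings(wilcoxon_paired(a, b))
  want_p <- wilcoxon_exact_oracle(a - b)
  expect_equal(got$p_value, want_p, tolerance = 1e-12)

  # swapping the pair flips nothing (two-sided symmetry)
  rev <- suppressWarnings(wilcoxon_paired(b, a))
  expect_equal(rev$p_value, got$p_value, tolerance = 1e-12)

  expect_error(wilcoxon_paired(a, a), "degenerate")
})

test_that("feature-selection curves share folds and end at the full run", {
  tbl <- simulate_gaussian_table(250, n_informative = 3, n_noise = 2,
    effect_size = 2, seed = 89
  )
  tbl$record_id <- NULL
  factory <- function(d, label) fit_forest(d, label, n_trees = 10, seed = 3)
  f <- fit_forest(tbl, n_trees = 10, seed = 3)
  rk <- gini_importance(f)
  curve <- feature_selection_curve(rk, tbl, factory, k = 4, seed = 11)
  expect_equal(nrow(curve), 5)
  expect_equal(curve$m, 1:5)
  full <- crossval(tbl, factory, k = 4, seed = 11)
  expect_equal(
    as.data.frame(curve[curve$m == 5, -1]),
    as.data.frame(full$summary),
    tolerance = 1e-12
  )
  bad <- rk[-1, ]
  class(bad) <- class(rk)
  expect_error(
    feature_selection_curve(bad, tbl, factory, k = 4, seed = 1),
    "cover"
  )
})
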