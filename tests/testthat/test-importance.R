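fake_logit <- function(coef, classes = c("rest", "pos")) {
  structure(
    list(
      coef = coef, intercept = 0, scaled = TRUE,
      positive = "pos", classes = classes,
      features = names(coef)
    ),
    class = "af_logit"
  )
}

test_that("coefficient importance ranks by absolute standardized weight", {
  fit <- fake_logit(c(f1 = 2, f2 = -3, f3 = 0))
  rk <- lr_importance(fit)
  expect_identical(rk$feature, c("f2", "f1", "f3"))
  expect_equal(rk$score, c(3, 2, 0))
  expect_identical(rk$rank, 1:3)
})

test_that("all-zero coefficients fall back to the registry tie-break", {
  fit <- fake_logit(c(PSS = 0, CosEn = 0, AFE = 0))
  rk <- lr_importance(fit)
  # registry indices: CosEn 7, AFE 8, PSS 42
  expect_identical(rk$feature, c("CosEn", "AFE", "PSS"))
})

test_that("unscaled models are rejected", {
  fit <- fake_logit(c(f1 = 1))
  fit$scaled <- FALSE
  expect_error(lr_importance(fit), "standardized")
})

test_that("duplicated columns share importance under a ridge penalty", {
  set.seed(51)
  n <- 400
  x <- rnorm(n)
  d <- data.frame(
    a = x, b = x, c = rnorm(n),
    label = ifelse(stats::rbinom(n, 1, stats::plogis(2 * x)) == 1,
      "pos", "neg"
    )
  )
  fit <- fit_logistic(d, positive = "pos", lambda = 1)
  rk <- lr_importance(fit)
  sa <- rk$score[rk$feature == "a"]
  sb <- rk$score[rk$feature == "b"]
  expect_equal(sa, sb, tolerance = 1e-6) # symmetric optimum
  expect_lt(which(rk$feature == "a"), which(rk$feature == "b")) # tie-break
})

test_that("gini importance accumulates recorded impurity decreases", {
  # feature never used -> exactly 0
  set.seed(52)
  d <- data.frame(
    good = c(rnorm(50), rnorm(50, 10)),
    dead = rep(1, 100),
    label = rep(c("a", "b"), each = 50)
  )
  f <- fit_forest(d, n_trees = 10, mtry = 2, seed = 1)
  rk <- gini_importance(f)
  expect_equal(rk$score[rk$feature == "dead"], 0)
  expect_gt(rk$score[rk$feature == "good"], 0)
  expect_equal(sum(rk$score_normalized), 1)
  expect_true(all(rk$score >= 0))

  # single stump: importance equals the stump's weighted dG
  stump <- fit_forest(d,
    n_trees = 1, bootstrap = FALSE, mtry = 2,
    max_depth = 1, seed = 2
  )
  rk2 <- gini_importance(stump)
  expect_equal(
    rk2$score[rk2$feature == "good"],
    stump$trees[[1]]$delta[1]
  )
})

test_that("the hand-built 50/50 -> 40/10, 10/40 split records dG = 0.18", {
  d <- data.frame(
    x = c(rep(0, 50), rep(1, 50)),
    label = c(
      rep("a", 40), rep("b", 10),
      rep("a", 10), rep("b", 40)
    )
  )
  tr <- fit_tree(d, max_depth = 1)
  expect_equal(tr$nodes$delta[1], 0.18, tolerance = 1e-12)
  rk <- gini_importance(tr)
  expect_equal(rk$score[rk$feature == "x"], 0.18, tolerance = 1e-12)
})

test_that("permuting a feature the model never reads scores exactly 0", {
  set.seed(53)
  d <- data.frame(
    used = c(rnorm(40), rnorm(40, 8)),
    unused = rnorm(80),
    label = rep(c("a", "b"), each = 40)
  )
  f <- fit_forest(d, n_trees = 10, mtry = 1, seed = 3)
  rk <- permutation_importance(f, d, n_repeats = 5, seed = 9)
  # `used` separates perfectly so the forest never splits on `unused`
  expect_equal(rk$score[rk$feature == "unused"], 0)
  expect_gt(rk$score[rk$feature == "used"], 0.3)
})

test_that("mean decrease matches the exhaustive permutation expectation", {
  clf <- structure(list(), class = "threshold_clf")
  d <- data.frame(x = c(0, 0, 1, 1), label = c("a", "a", "b", "b"))
  rk <- permutation_importance(clf, d, n_repeats = 4000, seed = 4)
  # over all 24 permutations the expected accuracy decrease is 0.5
  expect_equal(rk$score, 0.5, tolerance = 0.03)

  # n = 6 rows: compare against full enumeration of the 720 permutations
  d6 <- data.frame(
    x = c(0, 0, 0, 1, 1, 1),
    label = c("a", "a", "a", "b", "b", "b")
  )
  oracle <- perm_importance_oracle(
    function(x) predict.threshold_clf(NULL, x),
    as.matrix(d6["x"]), d6$label,
    j = 1
  )
  rk6 <- permutation_importance(clf, d6, n_repeats = 4000, seed = 5)
  expect_lt(abs(rk6$score - oracle), 3 * 0.25 / sqrt(4000) + 0.02)
})

test_that("out-of-bag permutation importance runs and agrees in sign", {
  set.seed(54)
  tbl <- simulate_gaussian_table(300, n_informative = 2, n_noise = 3,
    effect_size = 2, seed = 54
  )
  f <- fit_forest(tbl, n_trees = 30, seed = 6)
  rk <- permutation_importance(f, tbl, n_repeats = 5, seed = 7, oob = TRUE)
  inf_scores <- rk$score[rk$feature %in% c("inf1", "inf2")]
  noise_scores <- rk$score[grepl("noise", rk$feature)]
  expect_gt(min(inf_scores), max(noise_scores))
})

test_that("global SHAP reduces attribution matrices as documented", {
  z <- matrix(0, 5, 3, dimnames = list(NULL, c("f1", "f2", "f3")))
  rk0 <- shap_global(list(N = z))
  expect_true(all(rk0$score == 0))

  m <- matrix(c(1, 3, 3, 1), 2, 2, dimnames = list(NULL, c("f1", "f2")))
  rk <- shap_global(list(N = m))
  expect_equal(rk$score, c(2, 2))
  expect_identical(rk$feature, c("f1", "f2")) # tie broken by order

  # signed reduction can cancel
  s <- matrix(c(-1, 1, 2, 2), 2, 2, dimnames = list(NULL, c("f1", "f2")))
  expect_equal(shap_global(list(N = s), reduce = "signed")$score, c(2, 0))
  expect_error(shap_global(list(
    N = m,
    A = matrix(0, 2, 3, dimnames = list(NULL, paste0("g", 1:3)))
  )))
})

test_that("select_top returns nested rank prefixes", {
  fit <- fake_logit(c(f1 = 2, f2 = -3, f3 = 0.5))
  rk <- lr_importance(fit)
  expect_identical(select_top(rk, 1), "f2")
  expect_identical(select_top(rk, 3), c("f2", "f1", "f3"))
  for (m in 1:2) {
    expect_true(all(select_top(rk, m) %in% select_top(rk, m + 1)))
  }
  expect_error(select_top(rk, 0), "must lie")
  expect_error(select_top(rk, 4), "must lie")
})
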