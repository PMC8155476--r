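test_that("coalition values interpolate between base and full prediction", {
  pf <- function(x) x[, 1] + 2 * x[, 2]
  bg <- matrix(0, 1, 2)
  x <- c(3, 5)
  expect_equal(coalition_value(pf, x, 1:2, bg), 13)
  expect_equal(coalition_value(pf, x, integer(0), bg), 0)
  expect_equal(coalition_value(pf, x, 2, bg), 10)
  expect_error(coalition_value(pf, x, 1, bg[0, , drop = FALSE]), "nonempty")
})

test_that("exact Shapley solves the textbook product game", {
  pf <- function(x) x[, 1] * x[, 2]
  att <- shapley_exact(pf, c(1, 1), matrix(0, 1, 2))
  expect_equal(unname(att$phi[, 1]), c(0.5, 0.5))
  expect_equal(unname(att$base), 0)
  expect_equal(unname(att$fx), 1)
})

test_that("a constant predictor gets zero attributions", {
  att <- shapley_exact(function(x) rep(4.2, nrow(x)), c(1, 2, 3),
    matrix(rnorm(15), 5, 3)
  )
  expect_equal(unname(att$phi[, 1]), rep(0, 3))
  expect_equal(unname(att$base), 4.2)
})

test_that("additive models decompose feature-wise", {
  set.seed(61)
  bg <- matrix(rnorm(40), 10, 4)
  x <- rnorm(4)
  g <- list(function(v) v^2, function(v) sin(v), function(v) 2 * v,
    function(v) abs(v))
  pf <- function(m) {
    g[[1]](m[, 1]) + g[[2]](m[, 2]) + g[[3]](m[, 3]) + g[[4]](m[, 4])
  }
  att <- shapley_exact(pf, x, bg)
  want <- vapply(
    1:4,
    function(j) g[[j]](x[j]) - mean(g[[j]](bg[, j])), numeric(1)
  )
  expect_equal(unname(att$phi[, 1]), want, tolerance = 1e-9)
})

test_that("exact Shapley matches the permutation-order oracle", {
  set.seed(62)
  for (rep in 1:5) {
    m <- 4
    bg <- matrix(rnorm(5 * m), 5, m)
    x <- rnorm(m)
    w <- rnorm(2^m) # random multilinear-ish model via subset interactions
    pf <- function(mat) {
      out <- numeric(nrow(mat))
      for (sub in 0:(2^m - 1)) {
        on <- which(bitwAnd(sub, 2^(0:(m - 1))) > 0)
        term <- if (length(on) == 0) 1 else apply(
          mat[, on, drop = FALSE], 1, prod
        )
        out <- out + w[sub + 1] * term
      }
      out
    }
    att <- shapley_exact(pf, x, bg)
    oracle <- shapley_perm_oracle(
      function(S) coalition_value(pf, x, S, bg)[1], m
    )
    expect_equal(unname(att$phi[, 1]), oracle, tolerance = 1e-9)
  }
})

test_that("efficiency, symmetry and dummy axioms hold exactly", {
  set.seed(63)
  tbl <- simulate_gaussian_table(120, n_informative = 3, n_noise = 2,
    seed = 63
  )
  f <- fit_forest(tbl, n_trees = 10, max_depth = 3, seed = 1)
  pf <- function(m) as.matrix(predict(f, m, type = "prob"))
  bg <- as.matrix(tbl[1:20, f$features])
  for (i in c(3, 50)) {
    x <- unlist(tbl[i, f$features])
    att <- shapley_exact(pf, x, bg)
    expect_lt(max(abs(att$base + colSums(att$phi) - att$fx)), 1e-9)
  }

  # symmetry: identical columns treated identically by a symmetric model
  pf_sym <- function(m) m[, 1] * m[, 2] + m[, 1] + m[, 2]
  x <- c(1.3, 1.3, 0.7)
  bg2 <- cbind(rnorm(8), 0, rnorm(8))
  bg2[, 2] <- bg2[, 1]
  att_s <- shapley_exact(pf_sym, x, bg2)
  expect_equal(att_s$phi[1, 1], att_s$phi[2, 1], tolerance = 1e-9)

  # dummy: a feature the model ignores gets exactly zero
  expect_equal(att_s$phi[3, 1], 0)
})

test_that("missingness and consistency checks are executable", {
  pf <- function(m) m[, 1] + 3 * m[, 2]
  bg <- cbind(rnorm(6), 2) # feature 2 constant in background
  x <- c(0.5, 2) # ... and equal to x's value
  rep <- shap_axiom_checks(pf, x, bg,
    games = list(
      v = c(0, 1, 2, 3), # 2-player game
      v_prime = c(0, 1, 2 + 0.5, 3 + 0.5), # +bonus when player 2 present
      j = 2
    )
  )
  expect_true(all(rep$pass))
  expect_equal(rep$value[rep$axiom == "missingness"], 0)
  # Shapley linearity: the bonus game adds exactly bonus to phi_2
  expect_equal(rep$value[rep$axiom == "consistency"], 0.5)
})

test_that("sampled Shapley converges to the exact values", {
  set.seed(64)
  tbl <- simulate_gaussian_table(100, n_informative = 3, n_noise = 5,
    seed = 64
  )
  f <- fit_forest(tbl, n_trees = 15, max_depth = 3, seed = 2)
  pf <- function(m) as.matrix(predict(f, m, type = "prob"))[, "N"]
  bg <- as.matrix(tbl[1:15, f$features])
  x <- unlist(tbl[7, f$features])
  exact <- shapley_exact(pf, x, bg)
  few <- shapley_sampled(pf, x, bg, n_permutations = 20, seed = 1)
  many <- shapley_sampled(pf, x, bg, n_permutations = 400, seed = 1)
  err_few <- max(abs(few$phi - exact$phi))
  err_many <- max(abs(many$phi - exact$phi))
  expect_lt(err_many, err_few + 1e-12)
  expect_lt(err_many, 0.05)
  # local accuracy holds for the sampled estimate too
  expect_lt(max(abs(many$base + colSums(many$phi) - many$fx)), 1e-9)
  # seeded reproducibility
  again <- shapley_sampled(pf, x, bg, n_permutations = 20, seed = 1)
  expect_identical(few$phi, again$phi)
})

test_that("tree-conditional expectation follows the weighted recursion", {
  d <- data.frame(
    x = c(1, 1, 5, 5), y = c(0, 1, 0, 1),
    label = c("a", "a", "b", "b")
  )
  stump <- fit_tree(d, max_depth = 1)
  # S = all: plain traversal
  expect_equal(
    tree_expected_value(stump, c(1, 0), 1:2),
    c(a = 1, b = 0)
  )
  # S empty on a balanced stump: 0.5/0.5 mixture of the leaves
  expect_equal(
    tree_expected_value(stump, c(1, 0), integer(0)),
    c(a = 0.5, b = 0.5)
  )
  # single-leaf tree returns its leaf for any S
  leaf <- fit_tree(data.frame(x = 1:4, label = "a"))
  expect_equal(tree_expected_value(leaf, 2, integer(0)), c(a = 1))
  expect_equal(tree_expected_value(leaf, 2, 1), c(a = 1))
})

test_that("tree-conditional traversal matches the recursive oracle", {
  set.seed(65)
  tbl <- simulate_gaussian_table(120, n_informative = 3, n_noise = 2,
    seed = 65
  )
  tr <- fit_tree(tbl, max_depth = 4, seed = 3)
  x <- unlist(tbl[11, tr$features])
  for (S in list(integer(0), 1, c(2, 4), 1:5)) {
    got <- tree_expected_value(tr, x, S)
    want <- tree_expected_oracle(tr$nodes, x, S)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("a stump attributes everything to its split feature", {
  d <- data.frame(
    x = c(1, 1, 5, 5), y = c(0, 1, 0, 1),
    label = c("a", "a", "b", "b")
  )
  stump <- fit_tree(d, max_depth = 1)
  att <- tree_shap(stump, c(1, 0), method = "exact")
  expect_equal(att$phi["x", "a"], unname(att$fx["a"] - att$base["a"]))
  expect_equal(att$phi["y", "a"], 0)
})

test_that("tree SHAP keeps local accuracy on random forests", {
  set.seed(66)
  tbl <- simulate_gaussian_table(150, n_informative = 3, n_noise = 3,
    seed = 66
  )
  f <- fit_forest(tbl, n_trees = 50, max_depth = 3, seed = 4)
  idx <- sample.int(150, 20)
  batch <- tree_shap_batch(f, tbl[idx, ], n_permutations = 8, seed = 5)
  resid <- abs(batch$base + apply(batch$phi, c(1, 3), sum) - batch$fx)
  expect_lt(max(resid), 1e-9)
  # the batch fx equals the forest prediction
  expect_equal(
    unname(batch$fx),
    unname(as.matrix(predict(f, tbl[idx, ], type = "prob"))),
    tolerance = 1e-9
  )
})

test_that("stump tree-conditional SHAP equals interventional SHAP with
           the training background", {
  d <- data.frame(
    x = c(1, 1, 1, 5, 5), y = rnorm(5),
    label = c("a", "a", "a", "b", "b")
  )
  stump <- fit_tree(d, max_depth = 1, seed = 1)
  x <- c(1, 0)
  cond <- tree_shap(stump, x, method = "exact")
  pf <- function(m) as.matrix(predict(stump, m, type = "prob"))
  intv <- shapley_exact(pf, x, as.matrix(d[, c("x", "y")]))
  expect_equal(unname(cond$phi), unname(intv$phi), tolerance = 1e-9)
  expect_equal(unname(cond$base), unname(intv$base), tolerance = 1e-9)
})

test_that("the exact cap directs users to the sampled variant", {
  tbl <- simulate_gaussian_table(60, n_informative = 3, n_noise = 17,
    seed = 67
  )
  f <- fit_forest(tbl, n_trees = 5, seed = 5)
  expect_error(
    tree_shap(f, tbl[1, ], method = "exact"),
    "sampled"
  )
  expect_error(
    shapley_exact(
      function(m) rowSums(m),
      rnorm(13), matrix(0, 2, 13)
    ),
    "shapley_sampled"
  )
})
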