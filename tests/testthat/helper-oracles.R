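# Independent brute-force oracles used to check the package's
# implementations.  These deliberately share no code with R/.

# O(n^2) sample-entropy template counter (double loop, no vectorized
# shortcuts).
cosen_oracle <- function(rr, m = 1, r = 0.030) {
  n <- length(rr)
  count <- function(len) {
    n_tpl <- n - m
    total <- 0
    for (i in seq_len(n_tpl)) {
      for (j in seq_len(n_tpl)) {
        if (j <= i) next
        dmax <- 0
        for (k in 0:(len - 1)) {
          dmax <- max(dmax, abs(rr[i + k] - rr[j + k]))
        }
        if (dmax <= r) total <- total + 1
      }
    }
    total
  }
  b <- count(m)
  a <- count(m + 1)
  if (a == 0 || b == 0) {
    return(list(SampEn = NA_real_, CosEn = NA_real_))
  }
  se <- -log(a / b)
  list(SampEn = se, CosEn = se + log(2 * r) - log(mean(rr)))
}

# Shapley values by enumeration of all M! player orders (independent of
# the subset-weight formula used in the package).
shapley_perm_oracle <- function(value_fn, M) {
  perms <- function(v) {
    if (length(v) <= 1) {
      return(list(v))
    }
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  phi <- numeric(M)
  all_p <- perms(seq_len(M))
  for (p in all_p) {
    s <- integer(0)
    v_prev <- value_fn(s)
    for (j in p) {
      s <- c(s, j)
      v_new <- value_fn(s)
      phi[j] <- phi[j] + (v_new - v_prev)
      v_prev <- v_new
    }
  }
  phi / length(all_p)
}

# Recursive tree-conditional expectation written directly from the node
# arrays (independent of the C++ traversal).
tree_expected_oracle <- function(nodes, x, S) {
  rec <- function(i) {
    f <- nodes$feature[i + 1]
    if (f < 0) {
      return(nodes$prob[i + 1, ])
    }
    if ((f + 1) %in% S) {
      child <- if (x[f + 1] <= nodes$threshold[i + 1]) {
        nodes$left[i + 1]
      } else {
        nodes$right[i + 1]
      }
      return(rec(child))
    }
    wl <- nodes$n[nodes$left[i + 1] + 1] / nodes$n[i + 1]
    wr <- nodes$n[nodes$right[i + 1] + 1] / nodes$n[i + 1]
    wl * rec(nodes$left[i + 1]) + wr * rec(nodes$right[i + 1])
  }
  rec(0)
}

# Per-class precision/recall/F written from first principles on the
# count decomposition.
scores_oracle <- function(cm) {
  l <- nrow(cm)
  tp <- fp <- fn <- numeric(l)
  for (i in seq_len(l)) {
    tp[i] <- cm[i, i]
    fp[i] <- sum(cm[, i]) - cm[i, i]
    fn[i] <- sum(cm[i, ]) - cm[i, i]
  }
  pmi <- sum(tp) / sum(tp + fp)
  rmi <- sum(tp) / sum(tp + fn)
  p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  pma <- mean(p)
  rma <- mean(r)
  list(
    f_micro = 2 * pmi * rmi / (pmi + rmi),
    p_macro = pma, r_macro = rma,
    f_macro = 2 * pma * rma / (pma + rma),
    f_class = ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  )
}

# Exact mean permutation-importance by enumerating every permutation of
# the evaluation column (n <= 7).
perm_importance_oracle <- function(predict_cls, x, y, j) {
  n <- nrow(x)
  perms <- function(v) {
    if (length(v) <= 1) {
      return(list(v))
    }
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  base <- mean(predict_cls(x) != y)
  deltas <- vapply(perms(seq_len(n)), function(p) {
    xp <- x
    xp[, j] <- x[p, j]
    mean(predict_cls(xp) != y) - base
  }, numeric(1))
  mean(deltas)
}

# Trapezoidal area under the empirical ROC curve.
auc_trapezoid_oracle <- function(score, pos) {
  th <- sort(unique(score), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(score[pos] >= t), numeric(1)), 1)
  fpr <- c(0, vapply(th, function(t) mean(score[!pos] >= t), numeric(1)), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Exact Wilcoxon signed-rank p-value by enumerating all 2^n sign vectors
# (two-sided, no ties assumed).
wilcoxon_exact_oracle <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- vapply(0:(2^n - 1), function(mask) {
    sum(r[bitwAnd(mask, 2^(0:(n - 1))) > 0])
  }, numeric(1))
  mu <- n * (n + 1) / 4
  mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-9)
}

# Brute-force Shapley by direct evaluation of the subset-weight formula,
# written independently of the package's enumeration (plain R loops over
# explicitly listed subsets).
shapley_subsets_oracle <- function(value_fn, M) {
  subsets <- lapply(0:(2^M - 1), function(mask) {
    which(bitwAnd(mask, 2^(0:(M - 1))) > 0)
  })
  phi <- numeric(M)
  for (j in seq_len(M)) {
    for (S in subsets) {
      if (j %in% S) next
      s <- length(S)
      w <- factorial(s) * factorial(M - s - 1) / factorial(M)
      phi[j] <- phi[j] + w * (value_fn(sort(c(S, j))) - value_fn(S))
    }
  }
  phi
}

# Forest-mean tree-conditional value using the recursive R oracle.
forest_cond_value_oracle <- function(forest, x, S, class_idx) {
  vals <- vapply(forest$trees, function(tr) {
    tree_expected_oracle(tr, x, S)[class_idx]
  }, numeric(1))
  mean(vals)
}
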