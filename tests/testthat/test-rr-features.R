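test_that("basic HRV statistics match hand arithmetic", {
  const <- hrv_basic(rep(0.8, 20))
  expect_equal(const$AVNN, 800)
  expect_equal(const$SDNN, 0)
  expect_equal(const$RMSSD, 0)
  expect_equal(const$pNN50, 0)

  alt <- hrv_basic(rep(c(0.800, 0.860), 10))
  expect_equal(alt$RMSSD, 60, tolerance = 1e-9)
  expect_equal(alt$pNN50, 100)

  tri <- hrv_basic(c(0.700, 0.800, 0.900))
  expect_equal(tri$AVNN, 800)
  expect_equal(tri$min_rr, 700)
  expect_equal(tri$max_rr, 900)
  expect_equal(tri$med_rr, 800)
  expect_equal(tri$SEM, tri$SDNN / sqrt(3))

  expect_error(hrv_basic(0.8), "at least 2")
})

test_that("outlier counting follows the trailing-window rule", {
  expect_equal(rr_outliers(rep(0.8, 30)), 0L)
  # |1000 - 800| = 200 > 0.2 * 800 = 160 -> outlier
  expect_equal(rr_outliers(c(rep(0.8, 12), 1.0)), 1L)
  # |900 - 800| = 100 <= 160 -> not an outlier
  expect_equal(rr_outliers(c(rep(0.8, 12), 0.9)), 0L)
})

test_that("variation ratios flag large jumps and alternans", {
  const <- variation_ratios(rep(0.8, 10))
  expect_equal(const$lv_rr, 0)
  expect_equal(const$al_rr, 0)

  alt <- variation_ratios(rep(c(0.6, 0.9), 10))
  expect_equal(alt$lv_rr, 1)
  expect_equal(alt$al_rr, 1)

  ramp <- variation_ratios(seq(0.800, 0.830, by = 0.005))
  expect_equal(ramp$lv_rr, 0)
  expect_equal(ramp$al_rr, 0)
})

test_that("fragmentation indices match hand enumeration", {
  mono <- fragmentation(seq(0.80, 0.89, by = 0.01)) # 10 intervals
  expect_equal(mono$PIP, 0)
  expect_equal(mono$IALS, 1 / 9)
  expect_equal(mono$PSS, 0)
  expect_equal(mono$PAS, 0)

  alt <- fragmentation(rep(c(0.6, 0.9), 10))
  expect_equal(alt$PIP, 100)
  expect_equal(alt$IALS, 1)
  expect_equal(alt$PSS, 100)
  expect_equal(alt$PAS, 100)

  hand <- fragmentation(c(0.800, 0.810, 0.820, 0.810, 0.800))
  expect_equal(hand$PIP, 100 / 3, tolerance = 1e-9)
  expect_equal(hand$IALS, 0.5)
  expect_equal(hand$PSS, 100)
  expect_equal(hand$PAS, 0)
})

test_that("constant series give SampEn 0 and the analytic CosEn shift", {
  res <- cosen(rep(0.8, 25), r = 0.03)
  expect_equal(res$SampEn, 0)
  expect_equal(res$CosEn, log(2 * 0.03) - log(0.8))
})

test_that("cosen matches the O(n^2) template-counting oracle", {
  set.seed(101)
  worst <- 0
  for (i in 1:200) {
    n <- sample(5:50, 1)
    rr <- runif(n, 0.4, 1.2)
    r <- runif(1, 0.01, 0.1)
    got <- cosen(rr, m = 1, r = r)
    want <- cosen_oracle(rr, m = 1, r = r)
    if (is.na(want$CosEn)) {
      expect_true(is.na(got$CosEn))
    } else {
      worst <- max(worst, abs(got$CosEn - want$CosEn))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("cosen is invariant to joint rescaling of intervals and r", {
  set.seed(5)
  rr <- runif(30, 0.5, 1.1)
  a <- cosen(rr, r = 0.03)
  b <- cosen(rr * 2.5, r = 0.03 * 2.5)
  expect_equal(a$SampEn, b$SampEn, tolerance = 1e-12)
  expect_equal(a$CosEn, b$CosEn, tolerance = 1e-12)
})

test_that("Lorenz evidence scores match hand binning", {
  const <- lorenz_evidence(rep(0.8, 12))
  expect_equal(const$OrC, 10L) # n - 2 points, all at the origin
  expect_equal(const$IrE, 0L)
  expect_equal(const$PACe, 0L)
  expect_equal(const$AFE, -10L)

  # dRR sequence (0, 0, 0, .1, .2, .3): 2 origin points, 3 distinct bins
  hand <- lorenz_evidence(c(0.8, 0.8, 0.8, 0.8, 0.9, 1.1, 1.4))
  expect_equal(hand$OrC, 2L)
  expect_equal(hand$IrE, 3L)
  expect_equal(hand$AFE, 1L)
})

test_that("AFE separates simulated AF from sinus rhythm", {
  cfg <- generator_config()
  wins <- vapply(1:100, function(s) {
    set.seed(s)
    a <- pmax(afexplain:::sim_rr_af(1000, cfg$rr_a), 0.2)
    n <- afexplain:::sim_rr_sinus(1000, cfg$rr_n)
    lorenz_evidence(a)$AFE > lorenz_evidence(n)$AFE
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("bimodality follows the moment identities", {
  # balanced two-point mixture: skew 0, kurtosis 1 -> coefficient 1
  two <- bimodality(rep(c(0.6, 1.0), 20))
  expect_equal(two, 1, tolerance = 1e-9)
  # Gaussian: kurtosis 3 -> coefficient about 1/3
  set.seed(9)
  g <- bimodality(rnorm(10000, 0.8, 0.05))
  expect_equal(g, 1 / 3, tolerance = 0.03)
  expect_true(is.na(bimodality(rep(0.8, 15))))
})

test_that("rr_features fills exactly the rhythm-feature registry", {
  rr <- simulate_rr("N", 30, generator_config(), seed = 3)
  out <- rr_features(rr, record_id = "rec1")
  expect_identical(
    setdiff(names(out), "record_id"),
    rhythm_feature_names()
  )
  expect_true(all(is.finite(unlist(out[rhythm_feature_names()]))))

  short <- rr_features(c(0.8, 0.82))
  expect_true(is.finite(short$AVNN))
  expect_true(is.na(short$PIP))
  expect_true(is.na(short$CosEn))
  expect_true(is.na(short$bi_rr))
})

test_that("rhythm features separate AF from sinus with high AUC", {
  cfg <- generator_config()
  set.seed(77)
  n_per <- 500
  sim_feats <- function(lb) {
    t(vapply(seq_len(n_per), function(i) {
      rr <- simulate_rr(lb, runif(1, 20, 40), cfg)
      unlist(rr_features(rr)[c("AFE", "CosEn", "lv_rr", "PSS")])
    }, numeric(4)))
  }
  fa <- sim_feats("A")
  fn <- sim_feats("N")
  labels <- c(rep(TRUE, n_per), rep(FALSE, n_per))
  for (j in 1:4) {
    sc <- c(fa[, j], fn[, j])
    ok <- is.finite(sc)
    r <- rank(sc[ok])
    n1 <- sum(labels[ok])
    n0 <- sum(!labels[ok])
    auc <- (sum(r[labels[ok]]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    expect_gt(max(auc, 1 - auc), 0.9)
  }
})

test_that("features are deterministic in the input sequence", {
  rr <- simulate_rr("O", 30, generator_config(), seed = 8)
  expect_identical(
    rr_features(rr, record_id = "x"),
    dplyr::mutate(rr_features(rr, record_id = "y"), record_id = "x")
  )
})
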