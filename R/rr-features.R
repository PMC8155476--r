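#' Basic heart-rate-variability statistics
#'
#' Time-domain HRV measures of an RR-interval sequence.  Intervals are
#' supplied in seconds; interval-valued outputs (`min_rr`, `max_rr`,
#' `med_rr`, `AVNN`, `SDNN`, `RMSSD`, `SEM`) are reported in milliseconds
#' and `pNN50` as a percentage in \[0, 100\].
#'
#' @param rr Numeric vector of RR intervals in seconds, length >= 2.
#' @return A named list with elements `min_rr`, `max_rr`, `med_rr`, `AVNN`
#'   (mean NN interval), `SDNN` (sample standard deviation), `RMSSD`
#'   (root-mean-square of successive differences), `pNN50` (% of successive
#'   differences exceeding 50 ms) and `SEM` (`SDNN / sqrt(n)`).
#' @export
#' @examples
#' hrv_basic(c(0.7, 0.8, 0.9))
hrv_basic <- function(rr) {
  check_rr(rr, min_len = 2)
  ms <- rr * 1000
  d <- diff(ms)
  n <- length(ms)
  sdnn <- stats::sd(ms)
  list(
    min_rr = min(ms),
    max_rr = max(ms),
    med_rr = stats::median(ms),
    AVNN = mean(ms),
    SDNN = sdnn,
    RMSSD = sqrt(mean(d^2)),
    pNN50 = 100 * mean(abs(d) > 50),
    SEM = sdnn / sqrt(n)
  )
}

#' Count RR-interval outliers against a trailing window average
#'
#' An interval is an outlier when its absolute deviation from the trailing
#' moving average of the previous `min(window, available)` intervals
#' exceeds `frac` times that average.  The first interval has no trailing
#' window and is never an outlier.
#'
#' @inheritParams hrv_basic
#' @param window Trailing window size in beats.
#' @param frac Relative deviation threshold.
#' @return Integer count of outliers (`nb_out`).
#' @export
#' @examples
#' rr_outliers(c(rep(0.8, 12), 1.0))
rr_outliers <- function(rr, window = 12, frac = 0.20) {
  check_rr(rr, min_len = 1)
  n <- length(rr)
  if (n < 2) {
    return(0L)
  }
  out <- 0L
  for (i in 2:n) {
    lo <- max(1, i - window)
    avg <- mean(rr[lo:(i - 1)])
    if (abs(rr[i] - avg) > frac * avg) out <- out + 1L
  }
  out
}

#' Large-variation and alternation ratios of an RR series
#'
#' `lv_rr` is the fraction of successive interval pairs whose absolute
#' change exceeds `large_frac` of the previous interval.  `al_rr` is the
#' fraction of interior intervals that are strict local extrema with both
#' flanking relative changes above `alt_frac` (beat-to-beat alternation).
#' Both are fractions in \[0, 1\].
#'
#' @inheritParams hrv_basic
#' @param large_frac Relative-change threshold for a large variation.
#' @param alt_frac Relative-change threshold for alternation.
#' @return A named list with `lv_rr` and `al_rr`.
#' @export
variation_ratios <- function(rr, large_frac = 0.20, alt_frac = 0.05) {
  check_rr(rr, min_len = 3)
  n <- length(rr)
  prev <- rr[-n]
  nxt <- rr[-1]
  lv <- mean(abs(nxt - prev) > large_frac * prev)
  i <- 2:(n - 1)
  dl <- rr[i] - rr[i - 1]
  dr <- rr[i + 1] - rr[i]
  extremum <- dl * dr < 0
  big <- (abs(dl) / rr[i - 1] > alt_frac) & (abs(dr) / rr[i] > alt_frac)
  list(lv_rr = lv, al_rr = mean(extremum & big))
}

# Sign sequence of successive RR differences with the zero-difference
# convention: zeros inherit the previous nonzero sign, leading zeros are
# positive.  This keeps monotone (and constant) series free of spurious
# inflection points.
rr_diff_signs <- function(rr) {
  s <- sign(diff(rr))
  prev <- 1
  for (i in seq_along(s)) {
    if (s[i] == 0) s[i] <- prev else prev <- s[i]
  }
  s
}

#' Heart-rate fragmentation indices
#'
#' Fragmentation metrics of the sign sequence of successive RR differences:
#' `PIP`, percentage of positions where the sign changes; `IALS`, inverse of
#' the mean length of maximal constant-sign runs; `PSS`, percentage of
#' difference positions lying in runs shorter than 3; `PAS`, percentage of
#' difference positions lying in alternation runs (sign flipping at every
#' step) spanning at least 4 NN intervals.  `PIP`, `PSS`, `PAS` are
#' percentages in \[0, 100\].
#'
#' @inheritParams hrv_basic
#' @return A named list with `PIP`, `IALS`, `PSS` and `PAS`.
#' @export
fragmentation <- function(rr) {
  check_rr(rr, min_len = 4)
  s <- rr_diff_signs(rr)
  nd <- length(s)
  flips <- s[-1] != s[-nd]
  pip <- 100 * mean(flips)
  runs <- rle(s)$lengths
  ials <- 1 / mean(runs)
  pss <- 100 * sum(runs[runs < 3]) / nd
  # maximal alternating stretches: break wherever the sign repeats
  alt_len <- diff(c(0L, which(!flips), nd))
  # a stretch of L differences spans L + 1 NN intervals
  pas <- 100 * sum(alt_len[alt_len + 1 >= 4]) / nd
  list(PIP = pip, IALS = ials, PSS = pss, PAS = pas)
}

#' Coefficient of sample entropy (COSEn)
#'
#' Sample entropy of the RR series at template length `m` and tolerance `r`
#' (Chebyshev distance, self-matches excluded), shifted by
#' `log(2 * r) - log(mean(rr))` to suit short RR records.  `r` and the
#' intervals must share one unit (seconds here); the shift makes the result
#' invariant to rescaling both together.
#'
#' @inheritParams hrv_basic
#' @param m Template length.
#' @param r Match tolerance in seconds.
#' @return A named list with `SampEn` and `CosEn`; both are `NA` when no
#'   template pair matches at length `m` or `m + 1` (entropy undefined).
#' @export
cosen <- function(rr, m = 1, r = 0.030) {
  check_rr(rr, min_len = m + 2)
  stopifnot(r > 0)
  n <- length(rr)
  n_tpl <- n - m
  count_matches <- function(len) {
    cnt <- 0
    for (i in seq_len(n_tpl - 1)) {
      js <- (i + 1):n_tpl
      dmax <- abs(rr[i] - rr[js])
      if (len > 1) {
        for (k in 1:(len - 1)) {
          dmax <- pmax(dmax, abs(rr[i + k] - rr[js + k]))
        }
      }
      cnt <- cnt + sum(dmax <= r)
    }
    cnt
  }
  b <- count_matches(m)
  a <- count_matches(m + 1)
  if (a == 0 || b == 0) {
    return(list(SampEn = NA_real_, CosEn = NA_real_))
  }
  samp_en <- -log(a / b)
  list(SampEn = samp_en, CosEn = samp_en + log(2 * r) - log(mean(rr)))
}

#' Lorenz-plot irregularity evidence scores
#'
#' Forms the Lorenz (Poincare) scatter of successive RR differences, points
#' `(dRR[i], dRR[i - 1])`, and derives the evidence scores used for AF
#' screening: `OrC`, the number of points in the origin region
#' (`max(|x|, |y|) <= origin_radius`); `IrE`, the number of occupied
#' non-origin bins on a square grid of side `bin_width` covering
#' +/- 0.6 s (points beyond are clamped to edge bins); `PACe`, the number
#' of points in the premature-beat pattern region (exactly one coordinate
#' beyond the origin radius, with the short-long compensatory sign
#' pattern); and `AFE = IrE - OrC - 2 * PACe`.
#'
#' @inheritParams hrv_basic
#' @param bin_width Grid bin side in seconds.
#' @param origin_radius Half-width of the origin region in seconds.
#' @return A named list with integer `AFE`, `OrC`, `IrE`, `PACe`.
#' @export
lorenz_evidence <- function(rr, bin_width = 0.025, origin_radius = 0.020) {
  check_rr(rr, min_len = 3)
  d <- diff(rr)
  nd <- length(d)
  x <- d[-1]
  y <- d[-nd]
  at_origin <- pmax(abs(x), abs(y)) <= origin_radius
  orc <- sum(at_origin)
  xo <- x[!at_origin]
  yo <- y[!at_origin]
  ire <- 0L
  if (length(xo) > 0) {
    nb <- ceiling(1.2 / bin_width)
    ix <- pmin(pmax(floor((xo + 0.6) / bin_width), 0), nb - 1)
    iy <- pmin(pmax(floor((yo + 0.6) / bin_width), 0), nb - 1)
    ire <- length(unique(ix * nb + iy))
  }
  pace <- sum((x < -origin_radius & abs(y) <= origin_radius) |
    (abs(x) <= origin_radius & y > origin_radius))
  list(
    AFE = as.integer(ire - orc - 2L * pace),
    OrC = as.integer(orc),
    IrE = as.integer(ire),
    PACe = as.integer(pace)
  )
}

#' Bimodality coefficient of the RR distribution
#'
#' `(skewness^2 + 1) / kurtosis` on the raw intervals, with kurtosis the
#' raw (non-excess) fourth standardized moment, so a Gaussian sample gives
#' about 1/3 and values above 0.555 flag bimodality.
#'
#' @inheritParams hrv_basic
#' @return The coefficient (`bi_rr`), or `NA` for a zero-variance series.
#' @export
bimodality <- function(rr) {
  check_rr(rr, min_len = 10)
  z <- rr - mean(rr)
  m2 <- mean(z^2)
  if (m2 == 0) {
    return(NA_real_)
  }
  skew <- mean(z^3) / m2^1.5
  kurt <- mean(z^4) / m2^2
  (skew^2 + 1) / kurt
}

#' Extract all rhythm features from one RR sequence
#'
#' Computes the 21 RR-interval (rhythm) features of [feature_registry()]
#' from a single sequence.  Features whose length preconditions are not met
#' (e.g. fragmentation on fewer than 4 intervals) are returned as `NA`
#' rather than raising.
#'
#' @inheritParams hrv_basic
#' @param record_id Optional identifier carried into the output.
#' @return A one-row tibble with `record_id` (if given) and the 21 rhythm
#'   feature columns in registry order.
#' @export
#' @examples
#' rr_features(c(0.80, 0.82, 0.79, 0.81, 0.80, 0.83))
rr_features <- function(rr, record_id = NULL) {
  check_rr(rr, min_len = 2)
  n <- length(rr)
  vals <- stats::setNames(
    as.list(rep(NA_real_, length(rhythm_feature_names()))),
    rhythm_feature_names()
  )
  vals[names(hrv_basic(rr))] <- hrv_basic(rr)
  vals$nb_out <- as.numeric(rr_outliers(rr))
  if (n >= 3) {
    vals[c("lv_rr", "al_rr")] <- variation_ratios(rr)[c("lv_rr", "al_rr")]
    le <- lorenz_evidence(rr)
    vals[c("AFE", "OrC", "IrE", "PACe")] <-
      lapply(le[c("AFE", "OrC", "IrE", "PACe")], as.numeric)
    vals$CosEn <- cosen(rr)$CosEn
  }
  if (n >= 4) {
    vals[c("PIP", "IALS", "PSS", "PAS")] <-
      fragmentation(rr)[c("PIP", "IALS", "PSS", "PAS")]
  }
  if (n >= 10) {
    vals$bi_rr <- bimodality(rr)
  }
  out <- tibble::as_tibble(vals)
  if (!is.null(record_id)) {
    out <- dplyr::bind_cols(tibble::tibble(record_id = record_id), out)
  }
  out
}

check_rr <- function(rr, min_len) {
  if (!is.numeric(rr) || length(rr) < min_len) {
    stop("`rr` must be a numeric vector with at least ", min_len,
      " intervals",
      call. = FALSE
    )
  }
  if (any(!is.finite(rr)) || any(rr <= 0)) {
    stop("RR intervals must be finite and positive", call. = FALSE)
  }
  invisible(rr)
}
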