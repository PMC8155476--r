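#' Rhythm class labels
#'
#' The four admissible rhythm labels, in the fixed reporting order used
#' throughout the package: normal sinus rhythm (`N`), atrial fibrillation
#' (`A`), other rhythms (`O`) and noisy recordings (`~`).
#'
#' @return A character vector of length four.
#' @export
#' @examples
#' rhythm_classes()
rhythm_classes <- function() {
  c("N", "A", "O", "~")
}

# Coerce labels to a factor with the canonical class order.  Labels outside
# {N, A, O, ~} keep their own levels (sorted), so the machinery also works
# on generic multi-class problems.
as_rhythm_factor <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (all(x %in% rhythm_classes())) {
    factor(x, levels = rhythm_classes())
  } else {
    factor(x)
  }
}

#' Registry of the 56 hand-crafted ECG features
#'
#' The canonical feature set extracted from short single-lead ECG
#' recordings: signal-quality indices, morphology measurements and
#' RR-interval (rhythm) statistics.  Only the rhythm features are computed
#' by this package (from RR-interval sequences); quality and morphology
#' features require waveform processing and are emulated by the synthetic
#' generator as class-conditional surrogate columns.
#'
#' @return A tibble with columns `index` (the conventional 1-56 ordering,
#'   used as the deterministic tie-break in importance rankings), `feature`
#'   (name) and `kind` (`"rhythm"` or `"surrogate"`).
#' @export
#' @examples
#' feature_registry()
#' rhythm_feature_names()
feature_registry <- function() {
  names56 <- c(
    "bSQI", "meanSQI", "medSQI", "quarSQI", "len_seg", "distQRS",
    "CosEn", "AFE", "OrC", "IrE", "PACe", "al_rr", "lv_rr", "bi_rr",
    "min_rr", "max_rr", "med_rr", "nb_out", "HR", "medQS", "stdQS",
    "medR", "stdR", "Ratio", "max_freq", "medQT", "medQT_b", "medQT_fre",
    "medQT_fra", "medQT_hod", "medP", "medPR", "stdPR", "medT", "medTamp",
    "stdTamp", "Ttype", "stdP", "stdT", "PIP", "IALS", "PSS", "AVNN",
    "SDNN", "RMSSD", "pNN50", "SEM", "PAS", "nbpwaves", "medPamp",
    "stdPamp", "med_tb", "medSTvar1", "medSTvar2", "medST", "medPRseg"
  )
  rhythm_idx <- c(7:18, 40:48)
  tibble::tibble(
    index = seq_along(names56),
    feature = names56,
    kind = ifelse(seq_along(names56) %in% rhythm_idx, "rhythm", "surrogate")
  )
}

#' @rdname feature_registry
#' @export
rhythm_feature_names <- function() {
  reg <- feature_registry()
  reg$feature[reg$kind == "rhythm"]
}

#' @rdname feature_registry
#' @export
surrogate_feature_names <- function() {
  reg <- feature_registry()
  reg$feature[reg$kind == "surrogate"]
}

# Deterministic tie-break index for a feature name: its registry index if it
# is one of the 56 canonical features, otherwise 56 + its position in the
# supplied ordering.
feature_tiebreak_index <- function(features) {
  reg <- feature_registry()
  idx <- match(features, reg$feature)
  extra <- is.na(idx)
  idx[extra] <- nrow(reg) + seq_len(sum(extra))
  idx
}
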