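# Minimal classifier that predicts its (binary) first feature column
# directly; used to make permutation-importance expectations computable
# by hand.
predict.threshold_clf <- function(object, newdata, type = "class", ...) {
  x <- if (is.matrix(newdata)) newdata[, 1] else newdata[[1]]
  factor(ifelse(x > 0.5, "b", "a"), levels = c("a", "b"))
}
registerS3method("predict", "threshold_clf", predict.threshold_clf)
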