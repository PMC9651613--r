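# Independent double-loop oracles for the confusion counts and trapezoidal
# AUROC. Deliberately naive: explicit loops over samples and thresholds,
# sharing no code with the package implementations they check.

oracle_confusion <- function(scores, labels, thr) {
  TrP <- 0L; TrN <- 0L; FaP <- 0L; FaN <- 0L
  for (i in seq_along(scores)) {
    pred <- scores[i] >= thr
    if (pred && labels[i] == 1) TrP <- TrP + 1L
    else if (!pred && labels[i] == 0) TrN <- TrN + 1L
    else if (pred) FaP <- FaP + 1L
    else FaN <- FaN + 1L
  }
  c(TrP = TrP, TrN = TrN, FaP = FaP, FaN = FaN)
}

oracle_auroc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1); N <- sum(labels == 0)
  tpr <- 0; fpr <- 0; auc <- 0
  for (t in thr) {
    cc <- oracle_confusion(scores, labels, t)
    tpr2 <- cc[["TrP"]] / P; fpr2 <- cc[["FaP"]] / N
    auc <- auc + (fpr2 - fpr) * (tpr2 + tpr) / 2
    tpr <- tpr2; fpr <- fpr2
  }
  auc + (1 - fpr) * (tpr + 1) / 2
}
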