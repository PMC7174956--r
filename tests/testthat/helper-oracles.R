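# Independent brute-force oracles, written as literal transcriptions of
# the defining formulas. They stay loop-based on purpose: the package's
# vectorized implementations are checked against them, never the other
# way round.

HH20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Column means by explicit double loop.
aacOracle <- function(h) {
  L <- nrow(h)
  out <- numeric(20)
  for (j in 1:20) {
    s <- 0
    for (i in 1:L) s <- s + h[i, j]
    out[j] <- s / L
  }
  out
}

# Transition probability composition by explicit triple loop:
# y[i,j] = sum_k h[k,i]*h[k+1,j] / sum_{j'} sum_k h[k,i]*h[k+1,j'],
# with all-zero rows where the denominator is zero.
tpcOracle <- function(h) {
  L <- nrow(h)
  num <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20) {
    s <- 0
    for (k in 1:(L - 1)) s <- s + h[k, i] * h[k + 1, j]
    num[i, j] <- s
  }
  out <- matrix(0, 20, 20)
  for (i in 1:20) {
    den <- sum(num[i, ])
    if (den > 0) for (j in 1:20) out[i, j] <- num[i, j] / den
  }
  out
}

# Four-branch confusion tally.
confusionOracle <- function(yt, yp) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(yt)) {
    if (yt[i] == 1 && yp[i] == 1) tp <- tp + 1L
    else if (yt[i] == 0 && yp[i] == 1) fp <- fp + 1L
    else if (yt[i] == 0 && yp[i] == 0) tn <- tn + 1L
    else fn <- fn + 1L
  }
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

# Direct formula evaluation of the four confusion metrics.
metricsOracle <- function(cc) {
  TP <- cc[["TP"]]; FP <- cc[["FP"]]; TN <- cc[["TN"]]; FN <- cc[["FN"]]
  oa <- (TP + TN) / (TP + FP + TN + FN)
  sn <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  sp <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (den == 0) 0 else (TP * TN - FP * FN) / sqrt(den)
  list(OA = oa, SN = sn, SP = sp, MCC = mcc)
}

# AUC as the normalized Mann-Whitney pairwise count, ties worth 1/2.
aucPairOracle <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Naive .hhm line scanner: keeps every line whose first two tokens are a
# residue letter and an index, takes tokens 3..22 as the emissions.
hhmScannerOracle <- function(path) {
  rows <- list()
  for (ln in readLines(path)) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 22 && grepl("^[A-Za-z-]$", tok[1]) &&
        grepl("^[0-9]+$", tok[2])) {
      rows[[length(rows) + 1]] <-
        suppressWarnings(as.integer(ifelse(tok[3:22] == "*", NA, tok[3:22])))
    }
  }
  do.call(rbind, rows)
}
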