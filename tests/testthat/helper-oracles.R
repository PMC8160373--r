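# Independent naive MRMR oracle: re-evaluates the greedy
# relevance/redundancy criterion with plain table-based MI at every step,
# sharing no code with mrmr_rank() internals.
oracle_mi <- function(a, b) {
  qbin <- function(v) {
    if (length(unique(v)) <= 8) return(v)
    br <- unique(quantile(v, 0:4 / 4))
    as.integer(cut(v, br, include.lowest = TRUE))
  }
  tab <- table(qbin(a), qbin(b)) / length(a)
  px <- rowSums(tab); py <- colSums(tab)
  s <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab)))
    if (tab[i, j] > 0) s <- s + tab[i, j] * log(tab[i, j] / (px[i] * py[j]))
  s
}

oracle_mrmr <- function(X, y, k) {
  rel <- sapply(seq_len(ncol(X)), function(j) oracle_mi(X[, j], y))
  sel <- integer(0)
  for (step in seq_len(k)) {
    rest <- setdiff(seq_len(ncol(X)), sel)
    crit <- sapply(rest, function(j) {
      if (length(sel) == 0) return(rel[j])
      rel[j] / (mean(sapply(sel, function(s) oracle_mi(X[, j], X[, s]))) + 1e-12)
    })
    best <- rest[order(-crit, -rel[rest], rest)][1]
    sel <- c(sel, best)
  }
  colnames(X)[sel]
}
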