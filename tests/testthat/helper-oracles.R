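# explicit loop-sum covariance oracle, independent of the implementation
loop_cov <- function(a, b) {
  n <- length(a)
  s <- 0
  ma <- sum(a) / n; mb <- sum(b) / n
  for (i in seq_len(n)) s <- s + (a[i] - ma) * (b[i] - mb)
  s / (n - 1)
}

loop_response <- function(F, O_t, O_lag) {
  k <- ncol(O_t)
  C_FO <- matrix(0, 1, k)
  C_OO <- matrix(0, k, k)
  for (j in seq_len(k)) {
    C_FO[1, j] <- loop_cov(F, O_lag[, j])
    for (i in seq_len(k)) C_OO[i, j] <- loop_cov(O_t[, i], O_lag[, j])
  }
  as.numeric(C_FO %*% solve(C_OO))
}

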