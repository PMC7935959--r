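# Independent brute-force oracles, deliberately written with naive loops so
# they share no code path with the implementation.

# Distance correlation by explicit double centering, O(n^2) loops.
oracle_dcor <- function(x, y) {
  n <- length(x)
  a <- matrix(0, n, n)
  b <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    a[i, j] <- abs(x[i] - x[j])
    b[i, j] <- abs(y[i] - y[j])
  }
  A <- matrix(0, n, n)
  B <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    A[i, j] <- a[i, j] - mean(a[i, ]) - mean(a[, j]) + mean(a)
    B[i, j] <- b[i, j] - mean(b[i, ]) - mean(b[, j]) + mean(b)
  }
  dcov2 <- sum(A * B) / n^2
  dvx <- sum(A * A) / n^2
  dvy <- sum(B * B) / n^2
  if (dvx <= 0 || dvy <= 0) return(0)
  sqrt(max(dcov2, 0) / sqrt(dvx * dvy))
}

# Mann-Whitney AUC by exhaustive pair counting (concordant + half ties).
oracle_auc <- function(a, b) {
  total <- 0
  for (x in a) for (y in b)
    total <- total + (x > y) + 0.5 * (x == y)
  total / (length(a) * length(b))
}

# Gaussian-mixture survival probability, explicit sum.
oracle_kde_tail <- function(obs, samples, bw) {
  acc <- 0
  for (s in samples)
    acc <- acc + (1 - pnorm((obs - s) / bw))
  acc / length(samples)
}

# Welch T statistic from the textbook formula, per column.
oracle_welch_t <- function(g1, g2) {
  apply_cols <- function(M, f) vapply(seq_len(ncol(M)),
                                      function(j) f(M[, j]), numeric(1))
  m1 <- apply_cols(g1, mean); m2 <- apply_cols(g2, mean)
  v1 <- apply_cols(g1, var);  v2 <- apply_cols(g2, var)
  (m1 - m2) / sqrt(v1 / nrow(g1) + v2 / nrow(g2))
}

# Multifunctionality by direct summation over sets.
oracle_multifun <- function(sets, universe) {
  out <- setNames(numeric(length(universe)), universe)
  for (g in universe)
    for (s in sets)
      if (g %in% s)
        out[g] <- out[g] + 1 / (length(s) * (length(universe) - length(s)))
  out
}
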