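# Independent oracles used to freeze expected values. These deliberately
# use brute-force formulations, not the package's code paths.

# two-sided Wilcoxon rank-sum p by full enumeration of rank assignments
oracle_wilcoxon <- function(x, y) {
  stopifnot(!anyDuplicated(c(x, y)))
  n <- length(x) + length(y)
  w_obs <- sum(rank(c(x, y))[seq_along(x)])
  combos <- utils::combn(n, length(x))
  w_all <- apply(combos, 2, sum)
  d_obs <- abs(w_obs - mean(w_all))
  mean(abs(w_all - mean(w_all)) >= d_obs - 1e-9)
}

# TOM by an element-wise triple loop
oracle_tom <- function(adj) {
  a <- adj
  diag(a) <- 0
  n <- nrow(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i])
    kj <- sum(a[j, -j])
    tom[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(adj)
  tom
}

# ARI via explicit pair counting (agree-agree, agree-disagree, ...)
oracle_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_a <- a[i] == a[j]
    same_b <- b[i] == b[j]
    if (same_a && same_b) s11 <- s11 + 1
    else if (!same_a && !same_b) s00 <- s00 + 1
    else if (same_a) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  num <- 2 * (s11 * s00 - s10 * s01)
  den <- (s11 + s10) * (s10 + s00) + (s11 + s01) * (s01 + s00)
  if (den == 0) 0 else num / den
}

# first principal component sample scores by eigendecomposition of the
# sample-sample crossproduct of the row-standardised block
oracle_first_pc <- function(block) {
  b <- t(scale(t(block)))
  ev <- eigen(crossprod(b), symmetric = TRUE)
  ev$vectors[, 1]
}

# brute-force kNN imputation for one missing entry
oracle_knn_one <- function(X, a, s, k) {
  obs <- !is.na(X)
  d <- rep(NA_real_, nrow(X))
  for (b in seq_len(nrow(X))) {
    if (b == a) next
    co <- obs[a, ] & obs[b, ]
    if (!any(co)) next
    d[b] <- sqrt(mean((X[a, co] - X[b, co])^2))
  }
  elig <- which(obs[, s] & !is.na(d))
  elig <- elig[order(d[elig])]
  mean(X[elig[seq_len(min(k, length(elig)))], s])
}

# absolute cosine similarity of two vectors
abs_cosine <- function(u, v) abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
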