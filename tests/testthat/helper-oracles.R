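# Independent reference implementations used only by the tests. Each is a
# deliberately naive algorithm sharing no code with the package paths it
# checks.

# All-pairs shortest paths by Floyd-Warshall on an adjacency list.
oracle_floyd_warshall <- function(adj) {
  n <- length(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) d[i, adj[[i]]] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# Ordered pair count by explicit double loop over all atom pairs.
oracle_pair_count <- function(mol, center, target, n) {
  ci <- which(qsarga:::.flag_vector(mol, center))
  ti <- which(qsarga:::.flag_vector(mol, target))
  cnt <- 0L
  for (a in ci) for (b in ti) if (mol$dist[a, b] == n) cnt <- cnt + 1L
  cnt
}

# Charge sum with set semantics: atoms reachable from >= 1 center at 1..n.
oracle_charge_sum <- function(mol, center, target, n) {
  ci <- which(qsarga:::.flag_vector(mol, center))
  ti <- which(qsarga:::.flag_vector(mol, target))
  if (!length(ci)) return(0)
  contributing <- integer()
  for (b in ti) {
    for (a in ci) {
      if (mol$dist[a, b] >= 1 && mol$dist[a, b] <= n) {
        contributing <- union(contributing, b)
        break
      }
    }
  }
  sum(partial_charges(mol)[contributing])
}

# OLS coefficients by the textbook normal equations.
oracle_normal_equations <- function(X, y) {
  Xd <- cbind(1, X)
  solve(t(Xd) %*% Xd, t(Xd) %*% y)[, 1]
}

# Leave-one-out by brute-force n refits.
oracle_loo <- function(X, y) {
  n <- nrow(X)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    b <- oracle_normal_equations(X[-i, , drop = FALSE], y[-i])
    pred[i] <- sum(c(1, X[i, ]) * b)
  }
  press <- sum((y - pred)^2)
  list(Q2 = 1 - press / sum((y - mean(y))^2), PRESS = press, pred = pred)
}

# Exhaustive best-Q2_LOO subset of size k.
oracle_exhaustive_subset <- function(X, y, k) {
  combos <- utils::combn(ncol(X), k)
  tss <- sum((y - mean(y))^2)
  fits <- apply(combos, 2, function(idx)
    qsarga:::.q2_loo_fitness(X, y, idx, tss))
  list(subset = sort(combos[, which.max(fits)]), fitness = max(fits))
}

# K correlation index straight from the eigen decomposition definition.
oracle_k_index <- function(M) {
  lam <- eigen(cor(M))$values
  m <- ncol(M)
  sum(abs(lam / sum(lam) - 1 / m)) / (2 * (m - 1) / m)
}

# External statistics computed cell-by-cell, spreadsheet style.
oracle_external <- function(y, pred, ytr) {
  n <- length(y)
  rss <- sum((pred - y)^2)
  list(
    Q2_F1 = 1 - rss / sum((y - mean(ytr))^2),
    Q2_F2 = 1 - rss / sum((y - mean(y))^2),
    Q2_F3 = 1 - (rss / n) / (sum((ytr - mean(ytr))^2) / length(ytr))
  )
}
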