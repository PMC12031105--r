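# Independent brute-force oracles used across tests. These stay
# deliberately naive (enumeration, direct convolution, quadratic
# loops) and never call the implementation paths they check.

# triangle-enumeration clustering coefficient
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] != 0)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (adj[nb[a], nb[b]] != 0) tri <- tri + 1
      }
    }
    ci[i] <- 2 * tri / (k * (k - 1))
  }
  ci
}

# Floyd-Warshall all-pairs shortest paths on a binary graph
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj != 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_global_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- oracle_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_efficiency <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] != 0)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(adj[nb, nb, drop = FALSE])
  }, numeric(1))
}

# discrete Hilbert transform by direct convolution with the ideal
# kernel (periodic form), for analytic-signal cross-checks
oracle_analytic_phase <- function(x) {
  n <- length(x)
  h <- numeric(n)
  k <- seq_len(n) - 1
  if (n %% 2 == 0) {
    odd <- k %% 2 == 1
    h[odd] <- 2 / (n * tan(pi * k[odd] / n))
  } else {
    h <- (1 - cos(pi * k)) / (n * tan(pi * k / n))
    h[1] <- 0
  }
  hx <- numeric(n)
  for (t in seq_len(n)) {
    idx <- ((t - 1) - k) %% n + 1
    hx[t] <- sum(x[idx] * h)
  }
  atan2(hx, x)
}

# direct quadruple-loop valid convolution (cross-correlation
# indexing, multi-channel), ReLU applied
oracle_conv <- function(channels, K, bconv, kernel) {
  kr <- kernel[1]; kc <- kernel[2]
  nr <- nrow(channels[[1]]); ncx <- ncol(channels[[1]])
  C <- length(channels)
  nf <- nrow(K)
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    m <- matrix(0, nr - kr + 1, ncx - kc + 1)
    for (i in seq_len(nrow(m))) {
      for (j in seq_len(ncol(m))) {
        acc <- bconv[f]
        for (c in seq_len(C)) {
          for (a in seq_len(kr)) {
            for (b in seq_len(kc)) {
              w <- K[f, (c - 1) * kr * kc + (a - 1) * kc + b]
              acc <- acc + channels[[c]][i + a - 1, j + b - 1] * w
            }
          }
        }
        m[i, j] <- max(acc, 0)
      }
    }
    out[[f]] <- m
  }
  out
}

# step-by-step single-layer GAT forward in plain R (Eqs. of the
# attention mechanism), self-loops included
oracle_gat <- function(X, A, W, a, slope = 0.2) {
  n <- nrow(X)
  Z <- X %*% W
  fp <- ncol(W)
  e <- matrix(-Inf, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || A[i, j] != 0) {
        raw <- sum(a[seq_len(fp)] * Z[i, ]) + sum(a[fp + seq_len(fp)] * Z[j, ])
        e[i, j] <- ifelse(raw > 0, raw, slope * raw)
      }
    }
  }
  alpha <- matrix(0, n, n)
  for (i in seq_len(n)) {
    sup <- which(is.finite(e[i, ]))
    ex <- exp(e[i, sup] - max(e[i, sup]))
    alpha[i, sup] <- ex / sum(ex)
  }
  P <- alpha %*% Z
  H <- ifelse(P > 0, P, exp(P) - 1)
  list(alpha = alpha, H = H)
}

# two-pass variance for differential-entropy cross-checks
oracle_var2pass <- function(x) {
  m <- sum(x) / length(x)
  sum((x - m)^2) / (length(x) - 1)
}

random_sym_adj <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
  A + t(A)
}
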