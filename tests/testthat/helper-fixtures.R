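# Shared fixtures and independent oracle implementations used across tests.
# Oracles are deliberately naive (nested loops, closed forms) so they stay
# independent of the vectorized package code they check.

# random binary association matrix with labeled axes
random_binary_A <- function(nd, nm, p = 0.3, seed = 1) {
  set.seed(seed)
  matrix(rbinom(nd * nm, 1, p), nd, nm,
         dimnames = list(paste0("d", seq_len(nd)), paste0("m", seq_len(nm))))
}

# nested-loop GIP kernel oracle over rows of X
oracle_gip <- function(X) {
  n <- nrow(X)
  gamma <- n / sum(apply(X, 1, function(r) sum(r^2)))
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      S[i, j] <- exp(-gamma * sum((X[i, ] - X[j, ])^2))
    }
  }
  S
}

# nested-loop Hamming similarity oracle over rows of X
oracle_hamming <- function(X) {
  n <- nrow(X)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      S[i, j] <- 1 - sum(abs(X[i, ] - X[j, ])) / ncol(X)
    }
  }
  S
}

# nested-loop cosine similarity oracle over rows of X (zero profiles -> 0,
# diagonal forced to 1)
oracle_cosine <- function(X) {
  n <- nrow(X)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ni <- sqrt(sum(X[i, ]^2))
      nj <- sqrt(sum(X[j, ]^2))
      S[i, j] <- if (ni == 0 || nj == 0) 0 else sum(X[i, ] * X[j, ]) / (ni * nj)
    }
  }
  diag(S) <- 1
  S
}

# closed-form RWR oracle: row i is (1 - phi) * solve(I - phi M) e_i
oracle_rwr <- function(S, phi) {
  n <- nrow(S)
  M <- matrix(0, n, n)
  cs <- colSums(S)
  for (j in seq_len(n)) {
    M[, j] <- if (cs[j] > 0) S[, j] / cs[j] else rep(1 / n, n)
  }
  t((1 - phi) * solve(diag(n) - phi * M))
}

# brute-force transition-matrix oracle: evaluates attention, row
# normalization and self-loop degree scaling entry by entry
oracle_transition <- function(HN, A, a, slope) {
  n <- nrow(HN)
  nd <- nrow(A)
  mask <- HN > 0
  diag(mask) <- TRUE
  att <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (mask[i, j]) {
        e <- sum(c(HN[i, ], HN[j, ]) * a)
        if (e < 0) e <- slope * e
        att[i, j] <- exp(e)
      }
    }
  }
  P <- matrix(0, n, n)
  for (i in seq_len(n)) P[i, ] <- att[i, ] / sum(att[i, ])
  d <- numeric(n)
  for (i in seq_len(nd)) d[i] <- sum(A[i, ])
  for (j in seq_len(ncol(A))) d[nd + j] <- sum(A[, j])
  Tm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      Tm[i, j] <- P[i, j] / (sqrt(1 + d[i]) * sqrt(1 + d[j]))
    }
  }
  list(T = Tm, P = P, att = att)
}

# brute-force AUC: all positive-negative comparisons, ties as 1/2
oracle_auc <- function(sp, sn) {
  tot <- 0
  for (p in sp) {
    for (q in sn) {
      tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  tot / (length(sp) * length(sn))
}

# nested-loop same-padding cross-correlation oracle
oracle_conv2d <- function(X, K) {
  k <- nrow(K)
  cen <- (k + 1) %/% 2
  out <- matrix(0, nrow(X), ncol(X))
  for (i in seq_len(nrow(X))) {
    for (j in seq_len(ncol(X))) {
      acc <- 0
      for (p in seq_len(k)) {
        for (q in seq_len(k)) {
          ii <- i + p - cen
          jj <- j + q - cen
          if (ii >= 1 && ii <= nrow(X) && jj >= 1 && jj <= ncol(X)) {
            acc <- acc + X[ii, jj] * K[p, q]
          }
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# small integrated-similarity heterogeneous network for encoder tests
small_network <- function(nd = 4, nm = 6, p = 0.4, seed = 2) {
  A <- random_binary_A(nd, nm, p, seed)
  if (sum(A) == 0) A[1, 1] <- 1
  SD <- integrate_similarity(gip_similarity(A, "disease"),
                             hamming_similarity(A, "disease"))
  SM <- integrate_similarity(gip_similarity(A, "microbe"),
                             hamming_similarity(A, "microbe"))
  list(A = A, SD = SD, SM = SM,
       HN = build_heterogeneous_network(SD, SM, A))
}

# numerical gradient of f at params by central differences
numerical_gradient <- function(f, params, eps = 1e-6) {
  out <- params
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- array(0, dim = if (is.null(dim(p))) length(p) else dim(p))
    for (i in seq_along(p)) {
      pp <- params
      pp[[nm]][i] <- p[i] + eps
      pm <- params
      pm[[nm]][i] <- p[i] - eps
      g[i] <- (f(pp) - f(pm)) / (2 * eps)
    }
    out[[nm]] <- g
  }
  out
}
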