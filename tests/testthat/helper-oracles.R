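# Brute-force reference implementations, kept deliberately independent of
# the package code paths they check.

# adjusted R2 by explicit summation
oracle_adj_r2 <- function(obs, pred, p) {
  n <- length(obs)
  m <- sum(obs) / n
  ss_tot <- 0
  ss_res <- 0
  for (i in seq_len(n)) {
    ss_tot <- ss_tot + (obs[i] - m)^2
    ss_res <- ss_res + (obs[i] - pred[i])^2
  }
  r2 <- 1 - ss_res / ss_tot
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

# upper-tail hypergeometric P(X >= k) by direct summation of the pmf
oracle_hyper_tail <- function(k, K, N, n) {
  lo <- max(0, n - (N - K))
  hi <- min(n, K)
  total <- 0
  for (x in seq(lo, hi)) {
    if (x >= k) {
      total <- total + exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n))
    }
  }
  total
}

# upper-tail standard normal probability via the complementary error
# function (pracma's series/continued-fraction implementation)
oracle_norm_upper <- function(z) {
  0.5 * pracma::erfc(z / sqrt(2))
}

# Benjamini-Hochberg step-up by hand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in seq(m - 1, 1)) {
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# --- brute-force Shapley values for a single tree, path-dependent
# conditional expectations (enumerates all feature subsets; p <= 4 only)

oracle_tree_covers <- function(tr, X) {
  cv <- numeric(length(tr$left))
  for (i in seq_len(nrow(X))) {
    node <- 0
    cv[1] <- cv[1] + 1
    while (tr$feature[node + 1] >= 0) {
      node <- if (X[i, tr$feature[node + 1] + 1] <= tr$threshold[node + 1]) {
        tr$left[node + 1]
      } else {
        tr$right[node + 1]
      }
      cv[node + 1] <- cv[node + 1] + 1
    }
  }
  cv
}

oracle_tree_expvalue <- function(tr, cover, x, S) {
  rec <- function(j) {
    if (tr$feature[j + 1] < 0) return(tr$value[j + 1])
    f <- tr$feature[j + 1]
    if ((f + 1) %in% S) {
      if (x[f + 1] <= tr$threshold[j + 1]) rec(tr$left[j + 1]) else rec(tr$right[j + 1])
    } else {
      (cover[tr$left[j + 1] + 1] * rec(tr$left[j + 1]) +
         cover[tr$right[j + 1] + 1] * rec(tr$right[j + 1])) / cover[j + 1]
    }
  }
  rec(0)
}

oracle_tree_shap <- function(tr, cover, x, p) {
  phi <- numeric(p)
  for (i in seq_len(p)) {
    others <- setdiff(seq_len(p), i)
    for (k in 0:length(others)) {
      subsets <- if (k == 0) list(integer(0)) else utils::combn(others, k, simplify = FALSE)
      for (S in subsets) {
        w <- factorial(k) * factorial(p - k - 1) / factorial(p)
        phi[i] <- phi[i] + w * (oracle_tree_expvalue(tr, cover, x, c(S, i)) -
                                  oracle_tree_expvalue(tr, cover, x, S))
      }
    }
  }
  phi
}
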