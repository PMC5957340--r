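# Independent brute-force oracles. These deliberately re-derive every
# quantity with literal loops and first-principles formulas, sharing no
# code path with the package implementation.

# Normalized corrected Shannon entropy, evaluated literally: explicit
# window enumeration, explicit probability sum, explicit correction.
brute_ncse <- function(y, L = 3, xi = 2) {
  y <- as.numeric(y)
  s <- integer(length(y))
  for (i in seq_along(y)) s[i] <- if (y[i] >= mean(y)) 1L else 0L
  n_words <- length(s) - L + 1
  words <- integer(n_words)
  for (j in seq_len(n_words)) {
    w <- 0
    for (k in 0:(L - 1)) w <- w + s[j + k] * xi^k
    words[j] <- w
  }
  M <- xi^L
  se <- 0
  for (w in unique(words)) {
    p <- sum(words == w) / n_words
    se <- se - p * log(p) / log(2)
  }
  cr <- length(unique(words))
  cse <- se + (cr - 1) / (2 * M * log(2))
  cse_mx <- -log(1 / M) / log(2) + (M - 1) / (2 * M * log(2))
  cse / cse_mx
}

# Sample entropy by O(N^2 m) double loop over ordered template pairs.
brute_sampen <- function(x, m = 2, r) {
  x <- as.numeric(x)
  nt <- length(x) - m
  A <- 0; B <- 0
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      if (i == j) next
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) NA_real_ else -log(A / B)
}

# AUC as the all-pairs concordance fraction.
brute_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Exact two-sided Mann-Whitney p-value by exhaustive enumeration of all
# assignments of the pooled values into groups of sizes n1, n2.
brute_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    s <- 0
    for (p in x) for (q in y) s <- s + (p > q) + 0.5 * (p == q)
    s
  }
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * length(b) / 2
  all_idx <- utils::combn(length(pooled), n1)
  us <- apply(all_idx, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Midrank mean per group from an explicit pooled sort.
brute_mean_ranks <- function(groups) {
  pooled <- unlist(groups, use.names = FALSE)
  ord <- order(pooled)
  rk <- numeric(length(pooled))
  i <- 1
  while (i <= length(pooled)) {
    j <- i
    while (j < length(pooled) && pooled[ord[j + 1]] == pooled[ord[i]]) j <- j + 1
    rk[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  idx <- rep(seq_along(groups), lengths(groups))
  sapply(split(rk, idx), mean)
}

# A deterministic ensemble of seeds for Monte-Carlo style tests.
ens_seeds <- function(n, base = 100L) seq.int(base, length.out = n)
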