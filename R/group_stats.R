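check_groups <- function(groups, min_size = 1L) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least two groups")
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  sizes <- lengths(groups)
  if (any(sizes < min_size))
    stop("every group needs at least ", min_size, " observation(s)")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  groups
}

#' Per-group mean ranks
#'
#' Pools all groups, assigns midranks (ties receive the average of the
#' ranks they span), and returns the mean rank of each group — the summary
#' used to report which group carries the higher entropy. The weighted
#' average of the mean ranks always equals `(N + 1) / 2`.
#'
#' @param groups named list of numeric vectors (NAs dropped).
#' @return named numeric vector of mean ranks.
#' @export
mean_ranks <- function(groups) {
  groups <- check_groups(groups, 1L)
  pooled <- unlist(groups, use.names = FALSE)
  rk <- rank(pooled)
  idx <- rep(seq_along(groups), lengths(groups))
  vapply(split(rk, idx), mean, numeric(1)) |>
    stats::setNames(names(groups))
}

#' Kruskal-Wallis rank test
#'
#' Nonparametric analogue of one-way ANOVA: tests whether several groups
#' come from distributions with equal location, via the tie-corrected H
#' statistic referred to a chi-square with `k - 1` degrees of freedom.
#' When every pooled value is identical the statistic is taken as 0 with
#' p = 1 (no evidence of any difference).
#'
#' @param groups named list of numeric vectors, each with >= 2 values.
#' @return list with `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- check_groups(groups, 2L)
  pooled <- unlist(groups, use.names = FALSE)
  n <- length(pooled)
  k <- length(groups)
  if (length(unique(pooled)) == 1L)
    return(list(statistic = 0, df = k - 1L, p_value = 1))
  rk <- rank(pooled)
  idx <- rep(seq_along(groups), lengths(groups))
  rsum <- vapply(split(rk, idx), sum, numeric(1))
  h <- 12 / (n * (n + 1)) * sum(rsum^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(pooled)
  h <- h / (1 - sum(ties^3 - ties) / (n^3 - n))
  list(statistic = h, df = k - 1L,
       p_value = pchisq(h, df = k - 1L, lower.tail = FALSE))
}

#' Wilcoxon-Mann-Whitney test
#'
#' Two-sided rank-sum test for a location difference between two groups.
#' The U statistic for group a counts pairs `(a_i, b_j)` with `a_i > b_j`,
#' ties counting one half; `u_a + u_b = n_a * n_b`. The p-value comes from
#' exact enumeration of the permutation distribution (computed by dynamic
#' programming over midranks, so ties are handled exactly) whenever
#' `n_a * n_b <= exact_limit`, and otherwise from the normal approximation
#' with tie correction and continuity correction.
#'
#' @param a,b numeric vectors (NAs dropped).
#' @param exact_limit switch to the asymptotic p-value above this product
#'   of group sizes.
#' @return list with `u_a`, `u_b`, `p_value`, `method` (`"exact"` or
#'   `"normal_approx"`).
#' @export
mann_whitney <- function(a, b, exact_limit = 400L) {
  g <- check_groups(list(a = a, b = b), 1L)
  a <- g$a; b <- g$b
  n1 <- length(a); n2 <- length(b)
  rk <- rank(c(a, b))
  w <- sum(rk[seq_len(n1)])
  u_a <- w - n1 * (n1 + 1) / 2
  u_b <- n1 * n2 - u_a
  if (n1 * n2 <= exact_limit) {
    p <- mw_exact_p(rk, n1, u_a)
    method <- "exact"
  } else {
    ties <- table(c(a, b))
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- u_a - n1 * n2 / 2
    z <- sign(z) * max(abs(z) - 0.5, 0) / sqrt(sigma2)  # continuity correction
    p <- 2 * pnorm(-abs(z))
    method <- "normal_approx"
  }
  list(u_a = u_a, u_b = u_b, p_value = min(p, 1), method = method)
}

# Exact two-sided permutation p-value for the Mann-Whitney U.
# Doubled midranks are integers, so the number of size-n1 subsets attaining
# each rank-sum is computed by subset-sum dynamic programming; counts stay
# exact in doubles far beyond any n with n1*n2 <= 400.
mw_exact_p <- function(rk, n1, u_obs) {
  r2 <- as.integer(round(2 * rk))
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  # f[c+1, s+1] = number of subsets of size c with doubled-rank sum s
  f <- matrix(0, nrow = n1 + 1L, ncol = smax + 1L)
  f[1L, 1L] <- 1
  for (r in r2) {
    cmax <- n1
    for (c in seq.int(cmax, 1L)) {
      cols <- seq_len(smax + 1L - r)
      f[c + 1L, cols + r] <- f[c + 1L, cols + r] + f[c, cols]
    }
  }
  counts <- f[n1 + 1L, ]
  sums2 <- seq.int(0L, smax)                  # doubled rank sums
  u_all <- sums2 / 2 - n1 * (n1 + 1) / 2      # corresponding U values
  mu <- n1 * (length(rk) - n1) / 2
  extreme <- abs(u_all - mu) >= abs(u_obs - mu) - 1e-9
  sum(counts[extreme]) / sum(counts)
}

#' Area under the ROC curve
#'
#' `AUC = P(X_pos > X_neg) + 0.5 P(X_pos = X_neg)`, estimated over all
#' pairs; identical to the Mann-Whitney U of the positive group divided by
#' `n_pos * n_neg`. 1 means complete separation with the positive group
#' higher, 0.5 is chance, and `auc(a, b) = 1 - auc(b, a)`.
#'
#' @param pos,neg numeric vectors for the positive and negative group.
#' @return a value in `[0, 1]`.
#' @export
auc <- function(pos, neg) {
  g <- check_groups(list(pos = pos, neg = neg), 1L)
  rk <- rank(c(g$pos, g$neg))
  n1 <- length(g$pos); n2 <- length(g$neg)
  (sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Per-scale group comparison of entropy profiles
#'
#' The per-scale machinery behind group-discrimination tables: for each
#' method and scale, pools the subjects' entropy values (undefined values
#' dropped), computes per-group mean ranks, a p-value (Wilcoxon-Mann-
#' Whitney for two groups, Kruskal-Wallis for more) and, for two groups,
#' the AUC of group 1 against group 2. No multiplicity correction is
#' applied across scales unless `bonferroni = TRUE`.
#'
#' @param profiles a tidy [profile_table()] (or list of profiles).
#' @param labels either NULL (use the `label` column of `profiles`) or a
#'   data.frame with columns `source_id`, `group`.
#' @param bonferroni multiply p-values by the number of scales tested.
#' @return data.frame with one row per (method, scale): mean rank per
#'   group, `n` per group, `p_value`, and `auc` (NA when > 2 groups).
#' @export
compare_groups <- function(profiles, labels = NULL, bonferroni = FALSE) {
  df <- if (is.data.frame(profiles)) profiles else profile_table(profiles)
  if (!is.null(labels)) {
    if (!all(c("source_id", "group") %in% names(labels)))
      stop("`labels` needs columns source_id and group")
    miss <- setdiff(unique(df$source_id), labels$source_id)
    if (length(miss))
      stop("unlabeled source(s): ", paste(miss, collapse = ", "))
    df$label <- labels$group[match(df$source_id, labels$source_id)]
  }
  if (anyNA(df$label)) stop("profiles carry no group labels")
  gnames <- unique(df$label)
  out <- list()
  for (meth in unique(df$method)) {
    dm <- df[df$method == meth, ]
    for (sc in sort(unique(dm$scale))) {
      ds <- dm[dm$scale == sc, ]
      groups <- lapply(gnames, function(g) ds$value[ds$label == g & !is.na(ds$value)])
      names(groups) <- gnames
      if (any(lengths(groups) < 2L)) next
      mr <- mean_ranks(groups)
      p <- if (length(groups) == 2L)
        mann_whitney(groups[[1]], groups[[2]])$p_value
      else kruskal_wallis(groups)$p_value
      a <- if (length(groups) == 2L) auc(groups[[1]], groups[[2]]) else NA_real_
      row <- data.frame(method = meth, scale = sc, p_value = p, auc = a,
                        stringsAsFactors = FALSE)
      for (g in gnames) {
        row[[paste0("mean_rank_", g)]] <- mr[[g]]
        row[[paste0("n_", g)]] <- length(groups[[g]])
      }
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no (method, scale) cell had >= 2 defined values per group")
  if (bonferroni)
    res$p_value <- pmin(1, res$p_value * length(unique(res$scale)))
  rownames(res) <- NULL
  res
}
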