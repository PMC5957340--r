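test_that("mean ranks use joint midranks over the pooled sample", {
  expect_equal(mean_ranks(list(a = c(1, 2), b = c(3, 4))),
               c(a = 1.5, b = 3.5))
  expect_equal(mean_ranks(list(a = c(5, 5), b = c(5, 5))),
               c(a = 2.5, b = 2.5))
  set.seed(3)
  for (i in 1:20) {
    g <- list(a = sample(1:6, 5, TRUE), b = sample(1:6, 7, TRUE))
    mr <- mean_ranks(g)
    expect_equal(unname(mr), unname(brute_mean_ranks(g)), tolerance = 1e-12)
    # weighted average of mean ranks is (N+1)/2
    n <- lengths(g)
    expect_equal(sum(mr * n) / sum(n), (sum(n) + 1) / 2, tolerance = 1e-12)
  }
  expect_error(mean_ranks(list(a = numeric(0), b = 1)), "at least 1")
})

test_that("Kruskal-Wallis H matches the rank-sum formula and base R", {
  kw <- kruskal_wallis(list(a = c(1, 2, 3), b = c(101, 102, 103)))
  expect_equal(kw$statistic, 3.857143, tolerance = 1e-6)
  expect_equal(kw$p_value, 0.04953461, tolerance = 1e-6)
  # identical groups: no evidence of separation
  expect_gt(kruskal_wallis(list(a = c(1, 2, 3), b = c(1, 2, 3)))$p_value, 0.9)
  expect_equal(kruskal_wallis(list(a = c(5, 5), b = c(5, 5)))$p_value, 1)
  # cross-check with the independent base-R implementation, with ties
  set.seed(11)
  for (i in 1:10) {
    g <- list(a = sample(1:8, 6, TRUE), b = sample(1:8, 5, TRUE),
              c = sample(1:8, 7, TRUE))
    ref <- kruskal.test(g)
    got <- kruskal_wallis(g)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
  # rank statistic: invariant under strictly monotone transforms
  g <- list(a = c(0.1, 0.5, 0.9), b = c(0.2, 0.3, 1.4), c = c(2, 0.05, 0.6))
  expect_equal(kruskal_wallis(g)$statistic,
               kruskal_wallis(lapply(g, function(v) exp(3 * v)))$statistic,
               tolerance = 1e-12)
})

test_that("Mann-Whitney exact p equals exhaustive permutation enumeration", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$u_a, 0)
  expect_equal(mw$u_b, 4)                        # complementary convention
  expect_equal(mw$method, "exact")
  set.seed(5)
  for (i in 1:15) {
    a <- sample(1:7, sample(3:5, 1), TRUE)       # ties across and within groups
    b <- sample(1:7, sample(3:5, 1), TRUE)
    got <- mann_whitney(a, b)
    expect_equal(got$p_value, brute_mw_p(a, b), tolerance = 1e-12)
    # symmetry: swapping the groups leaves p unchanged
    expect_equal(got$p_value, mann_whitney(b, a)$p_value, tolerance = 1e-12)
    expect_equal(got$u_a + got$u_b, length(a) * length(b))
  }
})

test_that("Mann-Whitney normal branch matches base R with tie correction", {
  set.seed(6)
  a <- rnorm(25); b <- rnorm(25, 0.4)
  got <- mann_whitney(a, b)                      # 625 > 400 -> asymptotic
  expect_equal(got$method, "normal_approx")
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  # with heavy ties
  a <- sample(1:4, 30, TRUE); b <- sample(1:4, 30, TRUE)
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(mann_whitney(a, b)$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("AUC is the pairwise concordance and the U identity holds", {
  expect_equal(auc(c(3, 4), c(1, 2)), 1)
  expect_equal(auc(c(5, 5), c(5, 5)), 0.5)
  set.seed(8)
  for (i in 1:20) {
    pos <- sample(1:9, sample(2:6, 1), TRUE)
    neg <- sample(1:9, sample(2:6, 1), TRUE)
    a <- auc(pos, neg)
    expect_equal(a, brute_auc(pos, neg), tolerance = 1e-12)
    u <- mann_whitney(pos, neg)$u_a
    expect_equal(a, u / (length(pos) * length(neg)), tolerance = 1e-12)
    expect_equal(auc(pos, neg), 1 - auc(neg, pos), tolerance = 1e-12)
  }
})

test_that("per-scale group comparison mirrors the discrimination-table design", {
  # healthy-like (long-range correlated) vs CHF-like (whiter) ensembles
  healthy <- lapply(ens_seeds(12), function(s)
    mncse_profile(generate_pink(1500, s), tau_max = 6))
  chf <- lapply(ens_seeds(12, base = 500), function(s)
    mncse_profile(generate_wgn(1500, s), tau_max = 6))
  for (i in seq_along(healthy)) healthy[[i]]$label <- "healthy"
  for (i in seq_along(chf)) chf[[i]]$label <- "chf"
  tab <- compare_groups(c(healthy, chf))
  expect_setequal(tab$scale, 1:6)
  # the whiter group has uniformly higher symbolic entropy: AUC(healthy, chf)
  # below chance at every scale >= 2, equivalently separation above chance
  expect_true(all(pmax(tab$auc, 1 - tab$auc)[tab$scale >= 2] > 0.5))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  # mean-rank columns are present for both groups and average correctly
  expect_true(all(c("mean_rank_healthy", "mean_rank_chf") %in% names(tab)))
  n <- tab$n_healthy + tab$n_chf
  expect_equal((tab$mean_rank_healthy * tab$n_healthy +
                tab$mean_rank_chf * tab$n_chf) / n, (n + 1) / 2,
               tolerance = 1e-12)
  # labels supplied separately must cover every source
  df <- profile_table(c(healthy, chf))
  df$label <- NULL
  labs <- data.frame(source_id = unique(df$source_id)[-1], group = "x")
  df$label <- NA
  expect_error(compare_groups(df, labels = labs), "unlabeled")
})
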