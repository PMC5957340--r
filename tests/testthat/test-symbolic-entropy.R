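test_that("mean-threshold symbolization follows the >= rule", {
  expect_equal(as.integer(symbolize(c(5, 5, 5, 5))), c(1L, 1L, 1L, 1L))  # equality -> 1
  expect_equal(as.integer(symbolize(c(1, 0, 1, 0, 1, 0))), c(1L, 0L, 1L, 0L, 1L, 0L))
  expect_equal(as.integer(symbolize(c(-3, 3))), c(0L, 1L))
  expect_error(symbolize(1:10, xi = 3), "unsupported quantization")
  # the threshold is this series' own mean: shifting/scaling changes nothing
  y <- rnorm(50)
  expect_identical(as.integer(symbolize(y)), as.integer(symbolize(3 * y + 10)))
  # binary invariant: #1s equals #samples >= mean
  expect_equal(sum(symbolize(y) == 1L), sum(y >= mean(y)))
})

test_that("word counting encodes overlapping windows in base xi", {
  h <- count_words(symbolize(c(1, 0, 1, 0, 1)), L = 3)
  # symbols 1,0,1,0,1 -> words 5, 2, 5
  expect_equal(h$counts[c(3, 6)], c(1L, 2L))       # indices 2 and 5 (0-based)
  expect_equal(h$n_words, 3L)
  expect_equal(h$c_r, 2L)
  expect_equal(h$m_words, 8L)
  z <- count_words(rep(0L, 4), L = 3, xi = 2)
  expect_equal(z$counts[1], 2L)
  expect_equal(z$c_r, 1L)
  expect_error(count_words(c(0L, 1L), L = 3), "too few symbols")
  # binary alphabet, word length 3: exactly 8 possible words, indices 0..7
  expect_length(h$counts, 8L)
})

test_that("entropy formulas match hand-computed worked examples", {
  h <- count_words(symbolize(c(1, 0, 1, 0, 1)), L = 3)   # counts {2:1, 5:2}
  expect_equal(shannon_entropy(h), -(1/3) * log2(1/3) - (2/3) * log2(2/3),
               tolerance = 1e-12)
  expect_equal(shannon_entropy(h), 0.9182958, tolerance = 1e-7)
  expect_equal(corrected_shannon(h), shannon_entropy(h) + 1 / (16 * log(2)),
               tolerance = 1e-12)
  expect_equal(ncse(h), 0.2777236, tolerance = 1e-6)
  expect_equal(cse_max(3, 2), 3 + 7 / (16 * log(2)), tolerance = 1e-12)
  expect_equal(cse_max(3, 2), 3.6312, tolerance = 1e-4)
  expect_equal(cse_max(1, 2), 1 + 1 / (4 * log(2)), tolerance = 1e-12)
  # CSE_max strictly increases with L
  expect_true(all(diff(vapply(1:8, cse_max, numeric(1), xi = 2L)) > 0))
})

test_that("NCSE attains its endpoints exactly", {
  # constant series: one word only -> SE = 0, C_R = 1, NCSE = 0
  expect_identical(ncse_series(rep(2.5, 40)), 0)
  # uniform occupation of all 8 words: de Bruijn-like cycle 00010111 repeated
  s <- rep(c(0L, 0L, 0L, 1L, 0L, 1L, 1L, 1L), 10)
  h <- count_words(c(s, s[1:2]), L = 3, xi = 2)          # wrap to close the cycle
  expect_equal(h$c_r, 8L)
  expect_true(all(h$counts == h$counts[1]))
  expect_identical(ncse(h), 1)
  expect_equal(shannon_entropy(h), 3, tolerance = 1e-12)
  expect_equal(corrected_shannon(h), cse_max(3, 2), tolerance = 1e-12)
})

test_that("pipeline NCSE equals the literal brute-force evaluation", {
  set.seed(42)
  for (n in seq(10, 50, by = 5)) {
    for (rep in 1:3) {
      y <- if (rep %% 2) rnorm(n) else runif(n)
      for (L in c(2, 3, 4)) {
        if (n < L) next
        expect_equal(ncse_series(y, L = L), brute_ncse(y, L = L),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("NCSE stays in [0, 1] on fuzzed inputs", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(10:500, 1)
    y <- switch(1 + i %% 3, rnorm(n), runif(n), cumsum(rnorm(n)))
    v <- ncse_series(y, L = sample(2:4, 1))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("multiscale profile is total, bounded, and reduces to NCSE at scale 1", {
  x <- generate_wgn(300, 3)
  p <- mncse_profile(x, tau_max = 10)
  expect_s3_class(p, "entropy_profile")
  expect_false(anyNA(p$values))
  expect_true(all(p$values >= 0 & p$values <= 1))
  expect_equal(p$values[1], ncse_series(as.numeric(x)), tolerance = 1e-12)
  # every scale with floor(N/tau) >= L is defined even for a 100-sample series
  p100 <- mncse_profile(generate_wgn(100, 4), tau_max = 20)
  defined <- !is.na(p100$values)
  expect_identical(defined, (100 %/% 1:20) >= 3)
  # scales that cannot host one word are NA + warning, not an error
  expect_warning(mncse_profile(rnorm(10), tau_max = 6), "too short")
})

test_that("symbol words are order-sensitive: shuffling whitens 1/f noise", {
  # destroying the long-range correlation of 1/f noise must move its NCSE
  # toward (never beyond) the white-noise value, on ensemble average
  gap <- vapply(ens_seeds(20), function(s) {
    pink <- as.numeric(generate_pink(2000, s))
    wgn <- ncse_series(as.numeric(generate_wgn(2000, s + 1000)))
    set.seed(s)
    shuf <- sample(pink)                                 # marginal kept, order destroyed
    c(orig = abs(ncse_series(pink) - wgn), shuf = abs(ncse_series(shuf) - wgn))
  }, numeric(2))
  expect_lt(mean(gap["shuf", ]), mean(gap["orig", ]))
})
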