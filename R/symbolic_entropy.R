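#' Binarize a series at its mean
#'
#' Maps each sample to symbol 1 when it is greater than or equal to the
#' mean of the series being symbolized, else 0. The threshold is the mean
#' of *this* series — for a coarse-grained series it is recomputed at every
#' scale — which makes the symbolization self-referential and
#' amplitude-invariant. Equality with the mean yields symbol 1, so a
#' constant series symbolizes to all ones.
#'
#' Only the binary alphabet (`xi = 2`) has a defined partition rule;
#' other quantization levels are rejected.
#'
#' @param y a numeric vector or [coarse_grain()] output.
#' @param xi quantization level (alphabet size); only 2 is supported.
#' @return integer vector of class `symbol_sequence` with symbols in
#'   `{0, ..., xi - 1}` and attributes `xi` and `scale`.
#' @export
symbolize <- function(y, xi = 2L) {
  if (!identical(as.integer(xi), 2L))
    stop("unsupported quantization level: only the binary mean-split (xi = 2) is defined")
  v <- as.numeric(y)
  if (length(v) < 1L) stop("cannot symbolize an empty series")
  s <- as.integer(v >= mean(v))
  structure(s, xi = 2L, scale = attr(y, "scale"), class = "symbol_sequence")
}

#' Count overlapping symbol words
#'
#' Slides a window of `L` consecutive symbols along the sequence with step
#' one and encodes each window as its base-`xi` number,
#' `w_j = sum_{k=0}^{L-1} s_{j+k} * xi^k` (the first symbol in the window
#' is the least significant digit). Returns the histogram of word indices
#' over `0 .. xi^L - 1`, the sufficient statistic for all the entropy
#' formulas.
#'
#' @param s a [symbolize()] result (or integer vector in `0..xi-1`).
#' @param L word length, >= 1; the sequence must hold at least `L` symbols.
#' @param xi alphabet size (taken from `s` if present).
#' @return an object of class `word_histogram`: a list with `counts`
#'   (length `xi^L`), `L`, `xi`, `n_words` (number of windows),
#'   `c_r` (number of distinct occurring words) and `m_words` (`xi^L`).
#' @export
count_words <- function(s, L = 3L, xi = attr(s, "xi")) {
  L <- check_count(L, 1L, "L")
  if (is.null(xi)) xi <- 2L
  xi <- check_count(xi, 2L, "xi")
  sym <- as.integer(s)
  if (any(sym < 0L | sym >= xi)) stop("symbols must lie in 0..xi-1")
  n <- length(sym)
  if (n < L) stop("too few symbols for word length: n = ", n, ", L = ", L)
  w <- if (L == 1L) sym else as.vector(stats::embed(sym, L) %*% xi^(L - seq_len(L)))
  m <- xi^L
  counts <- tabulate(w + 1L, nbins = m)
  structure(list(counts = counts, L = L, xi = xi,
                 n_words = n - L + 1L,
                 c_r = sum(counts > 0L), m_words = m),
            class = "word_histogram")
}

#' @export
print.word_histogram <- function(x, ...) {
  cat(sprintf("<word_histogram> L = %d, xi = %d: %d words, %d/%d distinct\n",
              x$L, x$xi, x$n_words, x$c_r, x$m_words))
  occ <- which(x$counts > 0L)
  print(stats::setNames(x$counts[occ], occ - 1L))
  invisible(x)
}

#' Shannon entropy of a word histogram
#'
#' `SE = -sum_w p_w log2 p_w` in bits, with `p_w = count_w / n_words`,
#' summing only over occurring words (`0 log 0 := 0`).
#'
#' @param h a [count_words()] histogram.
#' @return entropy in bits.
#' @export
shannon_entropy <- function(h) {
  stopifnot(inherits(h, "word_histogram"))
  if (h$n_words < 1L) stop("empty word histogram")
  p <- h$counts[h$counts > 0L] / h$n_words
  -sum(p * log2(p))
}

#' Bias-corrected Shannon entropy
#'
#' Plug-in Shannon entropy estimates are biased low; the leading-order
#' (Miller–Madow type) correction adds `(C_R - 1) / (2 M ln 2)` bits, where
#' `C_R` is the number of occurring words and `M = xi^L` the number of
#' possible words. Note the denominator uses the possible-word count `M`,
#' not the sample size: this is the convention under which a uniform
#' occupation of all `M` words attains exactly [cse_max()], so that the
#' normalized measure reaches 1.
#'
#' @inheritParams shannon_entropy
#' @return corrected entropy in bits.
#' @export
corrected_shannon <- function(h) {
  shannon_entropy(h) + (h$c_r - 1) / (2 * h$m_words * log(2))
}

#' Maximum of the corrected Shannon entropy
#'
#' Attained when all `M = xi^L` words occur with uniform probability:
#' `CSE_max = log2(M) + (M - 1) / (2 M ln 2)`. Grows with `L`, which is why
#' entropies at different word lengths are only comparable after
#' normalization.
#'
#' @param L word length, >= 1.
#' @param xi alphabet size, >= 2.
#' @return maximum corrected entropy in bits.
#' @export
cse_max <- function(L, xi = 2L) {
  L <- check_count(L, 1L, "L"); xi <- check_count(xi, 2L, "xi")
  m <- xi^L
  log2(m) + (m - 1) / (2 * m * log(2))
}

#' Normalized corrected Shannon entropy
#'
#' `NCSE = CSE / CSE_max(L, xi)`, bounded in \[0, 1\] for every input:
#' 0 exactly when a single word occurs (a constant symbol stream), 1
#' exactly when all `M` words occur equiprobably. Being a plug-in
#' functional of the word distribution it is always finite — the property
#' that keeps the multiscale profile defined on short series where sample
#' entropy fails.
#'
#' @inheritParams shannon_entropy
#' @return a value in `[0, 1]`.
#' @export
ncse <- function(h) {
  corrected_shannon(h) / cse_max(h$L, h$xi)
}

#' Single-scale NCSE of a raw series
#'
#' Convenience composition `count_words(symbolize(y), L, xi)` |> [ncse()].
#'
#' @param y numeric vector or series.
#' @param L word length.
#' @param xi alphabet size (binary only).
#' @return a value in `[0, 1]`.
#' @export
ncse_series <- function(y, L = 3L, xi = 2L) {
  ncse(count_words(symbolize(y, xi), L = L, xi = xi))
}
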