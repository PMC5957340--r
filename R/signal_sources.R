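#' Generate white Gaussian noise
#'
#' Draws `n` i.i.d. samples from a standard Gaussian (mean 0, variance 1).
#' WGN is the canonical uncorrelated reference signal for validating
#' multiscale entropy measures. The generator is a pure function of
#' `(n, seed)`: the caller's RNG state is left untouched.
#'
#' @param n number of samples, >= 1.
#' @param seed integer seed; identical seeds give identical series.
#' @return a [signal_series()] of length `n`.
#' @seealso [generate_pink()]
#' @export
generate_wgn <- function(n, seed) {
  n <- check_count(n, 1L, "n")
  x <- with_seed(seed, rnorm(n))
  signal_series(x, label = "WGN", source_id = sprintf("wgn_n%d_s%d", n, as.integer(seed)))
}

#' Generate 1/f (pink) noise
#'
#' Produces an `n`-sample real series whose expected power spectral density
#' is proportional to 1/f. Construction: draw uniformly distributed white
#' noise, take its FFT, rescale every positive-frequency amplitude by
#' 1/sqrt(f) (so that power goes as 1/f), zero the DC bin, restore conjugate
#' symmetry, invert the FFT, and standardize the real part to zero mean and
#' unit variance. 1/f noise carries long-range correlations and is the
#' canonical "complex" reference signal.
#'
#' The DC bin is set to zero (avoids a 1/0 amplitude and an arbitrary
#' offset); phases are inherited from the white-noise FFT.
#'
#' @inheritParams generate_wgn
#' @param n number of samples, >= 2.
#' @return a [signal_series()] of length `n` with mean 0 and variance 1.
#' @export
generate_pink <- function(n, seed) {
  n <- check_count(n, 2L, "n")
  w <- with_seed(seed, runif(n) - 0.5)
  W <- fft(w)
  half <- n %/% 2L
  scale <- numeric(n)
  # positive frequencies k/n, k = 1..floor(n/2); amplitude ~ 1/sqrt(f)
  k <- seq_len(half)
  scale[k + 1L] <- 1 / sqrt(k / n)
  # mirror onto negative frequencies (conjugate partners share the gain)
  if (n > 2L) {
    neg <- seq.int(n, half + 2L)
    scale[neg] <- scale[seq.int(2L, n - half)]
  }
  x <- Re(fft(W * scale, inverse = TRUE)) / n
  x <- (x - mean(x)) / stats::sd(x)
  signal_series(x, label = "1/f", source_id = sprintf("pink_n%d_s%d", n, as.integer(seed)))
}

#' Read an interbeat (RR) interval series from plain text
#'
#' Expects one numeric interval per line; blank lines and lines starting
#' with `#` are ignored. Intervals are returned in seconds. In `"auto"`
#' mode the file is interpreted as milliseconds (divided by 1000) when the
#' median raw value exceeds 10 — no human RR interval is 10 s long and none
#' is 10 ms short, so the two unit conventions found in Physionet exports
#' are unambiguous.
#'
#' @param path file to read.
#' @param units one of `"auto"`, `"seconds"`, `"milliseconds"`.
#' @return a [signal_series()] of RR intervals in seconds, with `source_id`
#'   set to the file name.
#' @export
read_rr <- function(path, units = c("auto", "seconds", "milliseconds")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  if (!any(keep)) stop("no data lines in ", path)
  vals <- suppressWarnings(as.numeric(trimws(raw[keep])))
  if (anyNA(vals)) {
    bad <- which(keep)[which(is.na(vals))[1L]]
    stop(sprintf("unparseable value on line %d of %s: '%s'",
                 bad, path, trimws(raw[bad])))
  }
  ms <- switch(units,
               milliseconds = TRUE,
               seconds      = FALSE,
               auto         = stats::median(vals) > 10)
  if (ms) vals <- vals / 1000
  signal_series(vals, source_id = basename(path))
}

#' Remove artifactual RR intervals
#'
#' Drops intervals that are non-positive or longer than `max_interval`
#' (default 2 s), preserving the order of the remainder. Overlong intervals
#' in annotated RR records are almost always missed-beat artifacts rather
#' than physiology; entropy profiles computed with and without this filter
#' can be compared to assess a measure's robustness to such noise.
#'
#' @param rr RR intervals in seconds ([signal_series()] or numeric).
#' @param max_interval artifact cutoff in seconds.
#' @return the filtered [signal_series()]; the number of samples removed is
#'   available as `attr(, "removed")`.
#' @export
filter_artifacts <- function(rr, max_interval = 2.0) {
  x <- series_values(rr)
  keep <- x > 0 & x <= max_interval
  if (!any(keep)) stop("artifact filter removed every interval; series unusable")
  out <- signal_series(x[keep],
                       label = attr(rr, "label"),
                       source_id = attr(rr, "source_id"))
  attr(out, "removed") <- sum(!keep)
  out
}

#' Write a signal series as plain text
#'
#' One sample per line, the same format [read_rr()] accepts.
#'
#' @param x a [signal_series()] or numeric vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_signal <- function(x, path) {
  writeLines(format(series_values(x), scientific = FALSE, trim = TRUE, digits = 15), path)
  invisible(path)
}

check_count <- function(x, least, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < least || x != trunc(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, least), call. = FALSE)
  as.integer(x)
}
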