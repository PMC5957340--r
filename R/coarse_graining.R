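#' Coarse-grain a series at temporal scale tau
#'
#' Step one of every multiscale entropy measure: the scale-`tau` series is
#' the sequence of means over consecutive non-overlapping windows of `tau`
#' samples. Element `j` (1-based) is the mean of
#' `x[(j-1)*tau + 1 .. j*tau]`; the trailing `N %% tau` samples that do not
#' fill a window are discarded, so the result has `floor(N / tau)` samples.
#' At `tau = 1` the series is returned unchanged.
#'
#' @param x a [signal_series()] or numeric vector.
#' @param tau positive integer scale factor; must not exceed `length(x)`.
#' @return numeric vector of class `coarse_grained_series` with attributes
#'   `scale` and `source_length`.
#' @export
coarse_grain <- function(x, tau) {
  tau <- check_count(tau, 1L, "tau")
  v <- series_values(x)
  n <- length(v)
  if (n < tau) stop("series shorter than scale: N = ", n, ", tau = ", tau)
  m <- n %/% tau
  y <- if (tau == 1L) v else .colMeans(v[seq_len(m * tau)], tau, m)
  structure(y, scale = tau, source_length = n, class = "coarse_grained_series")
}

#' @export
print.coarse_grained_series <- function(x, ...) {
  cat(sprintf("<coarse_grained_series> tau = %d, n = %d (from N = %d)\n",
              attr(x, "scale"), length(x), attr(x, "source_length")))
  print(head(as.numeric(x), 10L))
  invisible(x)
}
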