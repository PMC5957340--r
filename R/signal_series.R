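#' Construct a signal series
#'
#' A `signal_series` is a finite ordered sequence of real samples with an
#' optional group label and source identifier. Noise signals are
#' dimensionless; interbeat (RR) interval series are in seconds. All
#' package functions that take a series also accept a plain numeric vector.
#'
#' @param values numeric vector of finite samples, length >= 1.
#' @param label optional free-text group tag (e.g. `"NSR"`, `"CHF"`).
#' @param source_id optional free-text identifier (e.g. a file name).
#' @return a numeric vector of class `signal_series` carrying `label` and
#'   `source_id` attributes.
#' @export
signal_series <- function(values, label = NULL, source_id = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("a signal series needs at least one sample")
  if (!all(is.finite(values))) stop("all samples must be finite")
  structure(values,
            label = label, source_id = source_id,
            class = "signal_series")
}

#' @export
print.signal_series <- function(x, ...) {
  id <- attr(x, "source_id"); lb <- attr(x, "label")
  cat(sprintf("<signal_series> n = %d%s%s\n", length(x),
              if (!is.null(id)) paste0(", source = ", id) else "",
              if (!is.null(lb)) paste0(", label = ", lb) else ""))
  print(head(as.numeric(x), 10L))
  if (length(x) > 10L) cat("...\n")
  invisible(x)
}

# strip class/attributes for numeric work
series_values <- function(x) as.numeric(x)
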