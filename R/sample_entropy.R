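#' Sample entropy of a series
#'
#' `SampEn(m, r) = -ln(A/B)`, where `B` counts pairs of distinct length-`m`
#' templates within Chebyshev distance `r` of each other and `A` counts the
#' same pairs extended to length `m + 1`. Self-matches are excluded — the
#' property that distinguishes sample entropy from approximate entropy.
#' When no template pairs match (`B = 0`) or no extended pairs match
#' (`A = 0`) the statistic is undefined: the function returns `NA` rather
#' than raising or returning infinity. This failure mode on short series is
#' precisely what motivates the symbolic alternative in [mncse_profile()].
#'
#' @param x numeric vector, length > `m + 1`.
#' @param m embedding dimension (template length), default 2.
#' @param r similarity tolerance (absolute, same units as `x`), > 0.
#' @return the sample entropy in nats, or `NA` when undefined. The A and B
#'   pair counts are attached as `attr(, "counts")`.
#' @export
sample_entropy <- function(x, m = 2L, r) {
  m <- check_count(m, 1L, "m")
  v <- as.numeric(x)
  if (length(v) <= m + 1L)
    stop("series too short for sample entropy: need length > m + 1")
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("`r` must be a single positive tolerance")
  ab <- .sampen_counts(v, m, r)
  out <- if (ab[1] == 0 || ab[2] == 0) NA_real_ else -log(ab[1] / ab[2])
  attr(out, "counts") <- c(A = ab[1], B = ab[2])
  out
}
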