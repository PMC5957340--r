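new_entropy_profile <- function(method, values, params, source_id = NULL, label = NULL) {
  structure(list(method = method,
                 scales = seq_along(values),
                 values = as.numeric(values),
                 params = params,
                 source_id = source_id,
                 label = label),
            class = "entropy_profile")
}

#' Multiscale normalized corrected Shannon entropy profile
#'
#' For each scale `tau = 1..tau_max`: coarse-grain the series, binarize at
#' the coarse-grained mean, count overlapping length-`L` words and compute
#' the normalized corrected Shannon entropy. A scale whose coarse-grained
#' series is shorter than `L` (no complete word) is marked `NA` with a
#' warning rather than raising; for every other scale the value is finite
#' and in \[0, 1\] — MNCSE has no undefined-entropy failure mode.
#'
#' At `tau = 1` the profile equals the single-scale NCSE of the raw series.
#'
#' @param x a [signal_series()] or numeric vector.
#' @param tau_max largest scale, >= 1.
#' @param L word length (default 3).
#' @param xi quantization level (binary only).
#' @return an `entropy_profile` with `method = "MNCSE"`.
#' @export
mncse_profile <- function(x, tau_max = 20L, L = 3L, xi = 2L) {
  tau_max <- check_count(tau_max, 1L, "tau_max")
  L <- check_count(L, 1L, "L")
  v <- series_values(x)
  vals <- rep(NA_real_, tau_max)
  short <- integer(0)
  for (tau in seq_len(tau_max)) {
    if (length(v) %/% tau < L) { short <- c(short, tau); next }
    vals[tau] <- ncse_series(coarse_grain(v, tau), L = L, xi = xi)
  }
  if (length(short))
    warning("series too short for word length at scale(s) ",
            paste(short, collapse = ", "), "; marked NA")
  new_entropy_profile("MNCSE", vals, list(L = L, xi = as.integer(xi)),
                      source_id = attr(x, "source_id"), label = attr(x, "label"))
}

#' Multiscale sample entropy (MSE) profile
#'
#' The classical comparator: sample entropy of each coarse-grained series.
#' Following the original MSE convention, the tolerance is
#' `r = r_fraction * SD(x)` computed once from the scale-1 series
#' (population SD) and held fixed across scales; `r_reference = "per_scale"`
#' recomputes it from each coarse-grained series instead, for sensitivity
#' studies. Scales where sample entropy is undefined (no template matches)
#' carry `NA` markers.
#'
#' @param x a [signal_series()] or numeric vector.
#' @param tau_max largest scale.
#' @param m embedding dimension (template length), default 2.
#' @param r_fraction similarity criterion as a fraction of SD, default 0.15.
#' @param r_reference `"scale1"` (original MSE) or `"per_scale"`.
#' @return an `entropy_profile` with `method = "MSE"`.
#' @export
mse_profile <- function(x, tau_max = 20L, m = 2L, r_fraction = 0.15,
                        r_reference = c("scale1", "per_scale")) {
  tau_max <- check_count(tau_max, 1L, "tau_max")
  m <- check_count(m, 1L, "m")
  if (!is.numeric(r_fraction) || r_fraction <= 0 || r_fraction >= 1)
    stop("`r_fraction` must lie in (0, 1)")
  r_reference <- match.arg(r_reference)
  v <- series_values(x)
  pop_sd <- function(z) sqrt(mean((z - mean(z))^2))
  r1 <- r_fraction * pop_sd(v)
  vals <- rep(NA_real_, tau_max)
  for (tau in seq_len(tau_max)) {
    n_cg <- length(v) %/% tau
    if (n_cg <= m + 1L) next
    y <- coarse_grain(v, tau)
    r <- if (r_reference == "scale1") r1 else r_fraction * pop_sd(y)
    vals[tau] <- sample_entropy(y, m = m, r = r)
  }
  new_entropy_profile("MSE", vals,
                      list(m = m, r_fraction = r_fraction, r_reference = r_reference),
                      source_id = attr(x, "source_id"), label = attr(x, "label"))
}

#' @export
print.entropy_profile <- function(x, ...) {
  p <- paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  cat(sprintf("<entropy_profile> %s (%s)%s\n", x$method, p,
              if (!is.null(x$source_id)) paste0(" — ", x$source_id) else ""))
  print(round(stats::setNames(x$values, x$scales), 4))
  if (anyNA(x$values))
    cat(sum(is.na(x$values)), "scale(s) undefined (NA)\n")
  invisible(x)
}

#' @export
as.data.frame.entropy_profile <- function(x, ...) {
  data.frame(source_id = if (is.null(x$source_id)) NA_character_ else x$source_id,
             label = if (is.null(x$label)) NA_character_ else x$label,
             method = x$method,
             scale = x$scales,
             value = x$values,
             defined = as.integer(!is.na(x$values)),
             L = if (is.null(x$params$L)) NA_integer_ else x$params$L,
             xi = if (is.null(x$params$xi)) NA_integer_ else x$params$xi,
             m = if (is.null(x$params$m)) NA_integer_ else x$params$m,
             r_fraction = if (is.null(x$params$r_fraction)) NA_real_ else x$params$r_fraction,
             stringsAsFactors = FALSE)
}

#' Bind entropy profiles into a tidy table
#'
#' @param profiles a list of `entropy_profile` objects (or a single one).
#' @return a data.frame with columns `source_id`, `label`, `method`,
#'   `scale`, `value`, `defined`, `L`, `xi`, `m`, `r_fraction` — the
#'   interchange schema used by [write_profiles()], [compare_groups()] and
#'   [build_feature_table()]. Undefined entropies appear as `NA` values
#'   with `defined = 0`.
#' @export
profile_table <- function(profiles) {
  if (inherits(profiles, "entropy_profile")) profiles <- list(profiles)
  do.call(rbind, lapply(profiles, as.data.frame))
}

#' Write / read profile tables as CSV
#'
#' Undefined entropy values are written as the literal token `NA` alongside
#' the `defined = 0` flag column, so they round-trip unambiguously.
#'
#' @param profiles a list of profiles, or a tidy [profile_table()].
#' @param path CSV file.
#' @return `write_profiles()`: `path`, invisibly. `read_profiles()`: the
#'   tidy data.frame.
#' @export
write_profiles <- function(profiles, path) {
  df <- if (is.data.frame(profiles)) profiles else profile_table(profiles)
  write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.csv(path, stringsAsFactors = FALSE)
}

# matrix of profile values: rows = profiles, cols = scales (NA kept)
profile_matrix <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) p$values))
}
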