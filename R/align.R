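#' Align two interval series by integer beat lag
#'
#' The two devices stream intervals without a shared clock, so before any
#' paired comparison the series must be aligned beat-by-beat. For every
#' integer lag in `[-max_lag, max_lag]` the Pearson correlation of the
#' overlapping segments is computed; the chosen lag maximizes the
#' correlation, with ties broken by the minimum variance of the element-wise
#' differences, then by the smaller absolute lag. A positive lag means `b`
#' starts later than `a` (i.e. `b[i]` pairs with `a[i + lag]`).
#'
#' @param a,b numeric interval series, ms.
#' @param max_lag maximum absolute lag searched, beats.
#' @param min_overlap smallest admissible overlap, beats.
#' @return list with `lag`, `overlap_n`, `xcorr_at_lag`, `var_diff_at_lag`,
#'   and the truncated, index-aligned `aligned_a`, `aligned_b`.
#' @export
synchronize <- function(a, b, max_lag = 15, min_overlap = 30) {
  check_intervals(a); check_intervals(b)
  max_lag <- as.integer(max_lag)
  if (max_lag < 0) stop("max_lag must be >= 0")
  if (length(a) <= 2 * max_lag || length(b) <= 2 * max_lag) {
    stop("both series must be longer than 2*max_lag")
  }
  segment <- function(lag) {
    if (lag >= 0) {
      n <- min(length(a) - lag, length(b))
      if (n < 1L) return(NULL)
      list(a = a[lag + seq_len(n)], b = b[seq_len(n)])
    } else {
      n <- min(length(a), length(b) + lag)
      if (n < 1L) return(NULL)
      list(a = a[seq_len(n)], b = b[-lag + seq_len(n)])
    }
  }
  lags <- seq(-max_lag, max_lag)
  stats <- lapply(lags, function(L) {
    s <- segment(L)
    if (is.null(s) || length(s$a) < min_overlap) return(NULL)
    r <- suppressWarnings(cor(s$a, s$b))
    if (is.na(r)) r <- -Inf  # zero-variance overlap: never preferred
    list(lag = L, n = length(s$a), r = r, v = var(s$a - s$b))
  })
  ok <- !vapply(stats, is.null, logical(1))
  if (!any(ok)) stop(sprintf("no lag admits an overlap of at least %d beats", min_overlap))
  stats <- stats[ok]
  r <- vapply(stats, `[[`, numeric(1), "r")
  v <- vapply(stats, `[[`, numeric(1), "v")
  L <- vapply(stats, `[[`, numeric(1), "lag")
  cand <- which(r >= max(r) - 1e-12)
  cand <- cand[v[cand] <= min(v[cand]) + 1e-12]
  cand <- cand[abs(L[cand]) == min(abs(L[cand]))]
  best <- cand[which.min(L[cand])]
  lag <- as.integer(L[best])
  s <- segment(lag)
  list(lag = lag, overlap_n = length(s$a),
       xcorr_at_lag = r[best], var_diff_at_lag = v[best],
       aligned_a = s$a, aligned_b = s$b)
}
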