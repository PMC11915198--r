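# Multiple structural-break detection in a piecewise-constant-mean model:
# exact dynamic-programming minimization of total within-segment RSS for
# each candidate number of breaks, model order chosen by BIC.

#' Detect multiple mean-shift breakpoints in a series
#'
#' Fits piecewise-constant-mean models with m = 0..`max_breaks` breaks by
#' exact dynamic programming: for each m the partition minimizing the total
#' within-segment residual sum of squares, subject to a minimum segment
#' length of `ceiling(min_segment_frac * n)`. The number of breaks is chosen
#' by BIC, `n log(RSS/n) + (2m + 1) log(n)` (ties between models with equal
#' RSS go to the smaller m). Each break gets a conservative 95% confidence
#' interval of plus/minus half the minimum segment length, clipped to the
#' series range.
#'
#' Missing values (at most 10% of the series) are linearly interpolated
#' before the search; a series shorter than two minimum segments returns
#' zero breaks.
#'
#' @param x Numeric series.
#' @param min_segment_frac Minimum segment length as a fraction of `n`
#'   (default 0.15).
#' @param max_breaks Maximum number of breaks considered (default 5).
#' @return An object of class `fs_breakpoints`: list with `breaks` (last
#'   index of each pre-break segment, sorted), `ci_lo`, `ci_hi`, `n_breaks`,
#'   `segment_means`, `rss` (of the selected model), `rss_by_m`, `bic_by_m`,
#'   `n`, `min_segment`.
#' @export
detect_breakpoints <- function(x, min_segment_frac = 0.15, max_breaks = 5) {
  x <- as.numeric(x)
  n <- length(x)
  bad <- !is.finite(x)
  if (any(bad)) {
    if (mean(bad) > 0.10) stop("more than 10% missing values in series")
    x <- stats::approx(which(!bad), x[!bad], xout = seq_len(n), rule = 2)$y
  }
  h <- ceiling(min_segment_frac * n)
  empty <- structure(list(breaks = integer(0), ci_lo = integer(0),
                          ci_hi = integer(0), n_breaks = 0L,
                          segment_means = mean(x),
                          rss = sum((x - mean(x))^2),
                          rss_by_m = sum((x - mean(x))^2), bic_by_m = NA_real_,
                          n = n, min_segment = h),
                     class = "fs_breakpoints")
  if (n < 2 * h || h < 1) return(empty)
  mmax <- min(max_breaks, floor(n / h) - 1)
  if (mmax < 1) return(empty)

  # segment cost matrix C[i, j] = RSS of x[i..j] via cumulative sums
  s1 <- c(0, cumsum(x)); s2 <- c(0, cumsum(x^2))
  seg_cost <- function(i, j) {
    # vectorized over i (or j)
    len <- j - i + 1
    (s2[j + 1] - s2[i]) - (s1[j + 1] - s1[i])^2 / len
  }
  # F[m+1, j]: min cost of fitting x[1..j] with m breaks (m+1 segments)
  Fm <- matrix(Inf, mmax + 1, n)
  bt <- matrix(NA_integer_, mmax + 1, n)  # last break position argmin
  js <- h:n
  Fm[1, js] <- seg_cost(1, js)
  for (m in seq_len(mmax)) {
    # x[1..j] with m breaks; last segment [t+1..j], t is the m-th break
    for (j in seq((m + 1) * h, n)) {
      ts <- (m * h):(j - h)
      cand <- Fm[m, ts] + seg_cost(ts + 1, j)
      k <- which.min(cand)
      Fm[m + 1, j] <- cand[k]
      bt[m + 1, j] <- ts[k]
    }
  }
  rss_by_m <- Fm[, n]
  # clamp numerically-zero RSS (cumulative-sum cancellation) so BIC ties
  # resolve toward fewer breaks on constant or exactly-piecewise series
  tol <- 1e-10 * max(1, seg_cost(1, n))
  rss_by_m[rss_by_m < tol] <- 0
  bic_by_m <- n * log(pmax(rss_by_m, 1e-300) / n) +
    (2 * (0:mmax) + 1) * log(n)
  m_sel <- which.min(bic_by_m) - 1L

  if (m_sel == 0L) {
    out <- empty
    out$rss_by_m <- rss_by_m
    out$bic_by_m <- bic_by_m
    return(out)
  }
  # backtrack breaks of the selected model
  breaks <- integer(m_sel)
  j <- n
  for (m in m_sel:1) {
    breaks[m] <- bt[m + 1, j]
    j <- breaks[m]
  }
  ci_half <- ceiling(h / 2)
  bounds <- c(0, breaks, n)
  means <- vapply(seq_len(m_sel + 1), function(k) {
    mean(x[(bounds[k] + 1):bounds[k + 1]])
  }, numeric(1))
  structure(list(
    breaks = breaks,
    ci_lo = pmax(breaks - ci_half, 1L),
    ci_hi = pmin(breaks + ci_half, n),
    n_breaks = m_sel,
    segment_means = means,
    rss = rss_by_m[m_sel + 1],
    rss_by_m = rss_by_m,
    bic_by_m = bic_by_m,
    n = n, min_segment = h
  ), class = "fs_breakpoints")
}

#' @export
print.fs_breakpoints <- function(x, ...) {
  cat(sprintf("<fs_breakpoints> n = %d, %d break(s), RSS = %.4g\n",
              x$n, x$n_breaks, x$rss))
  if (x$n_breaks > 0) {
    cat("  at:", paste(sprintf("%d [%d, %d]", x$breaks, x$ci_lo, x$ci_hi),
                       collapse = ", "), "\n")
  }
  invisible(x)
}

#' @describeIn detect_breakpoints Tidy the detected breaks: one row per
#'   break with its confidence interval and adjacent segment means.
#' @param x An `fs_breakpoints` object.
#' @param ... Unused.
#' @export
tidy.fs_breakpoints <- function(x, ...) {
  if (x$n_breaks == 0) {
    return(tibble::tibble(break_index = integer(0), ci_lo = integer(0),
                          ci_hi = integer(0), mean_before = numeric(0),
                          mean_after = numeric(0)))
  }
  tibble::tibble(
    break_index = x$breaks,
    ci_lo = x$ci_lo, ci_hi = x$ci_hi,
    mean_before = x$segment_means[seq_len(x$n_breaks)],
    mean_after = x$segment_means[seq_len(x$n_breaks) + 1]
  )
}

#' @describeIn detect_breakpoints One-row model summary (n, breaks, RSS,
#'   selected BIC).
#' @export
glance.fs_breakpoints <- function(x, ...) {
  tibble::tibble(n = x$n, n_breaks = x$n_breaks, rss = x$rss,
                 bic = x$bic_by_m[x$n_breaks + 1],
                 min_segment = x$min_segment)
}
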