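# Independent oracles used across tests. These deliberately use brute-force
# enumeration or textbook closed forms, not the package's code paths.

# exhaustive minimum-RSS segmentation with at most `max_breaks` breaks and
# minimum segment length h; returns the best model per break count and the
# BIC-selected one (same criterion as the method under test, applied to
# exhaustively optimal partitions)
oracle_breaks_exhaustive <- function(x, min_segment_frac = 0.15,
                                     max_breaks = 2) {
  n <- length(x)
  h <- ceiling(min_segment_frac * n)
  rss_seg <- function(i, j) {
    z <- x[i:j]
    sum((z - mean(z))^2)
  }
  best <- list(`0` = list(breaks = integer(0), rss = rss_seg(1, n)))
  if (max_breaks >= 1 && n >= 2 * h) {
    b1 <- Inf; a1 <- NULL
    for (t in h:(n - h)) {
      r <- rss_seg(1, t) + rss_seg(t + 1, n)
      if (r < b1 - 1e-12) { b1 <- r; a1 <- t }
    }
    best$`1` <- list(breaks = a1, rss = b1)
  }
  if (max_breaks >= 2 && n >= 3 * h) {
    b2 <- Inf; a2 <- NULL
    for (t1 in h:(n - 2 * h)) {
      for (t2 in (t1 + h):(n - h)) {
        r <- rss_seg(1, t1) + rss_seg(t1 + 1, t2) + rss_seg(t2 + 1, n)
        if (r < b2 - 1e-12) { b2 <- r; a2 <- c(t1, t2) }
      }
    }
    best$`2` <- list(breaks = a2, rss = b2)
  }
  ms <- as.integer(names(best))
  rss <- vapply(best, `[[`, numeric(1), "rss")
  bic <- n * log(pmax(rss, 1e-300) / n) + (2 * ms + 1) * log(n)
  sel <- which.min(bic)
  list(by_m = best, rss_by_m = rss, bic_by_m = bic,
       breaks = best[[sel]]$breaks, rss = unname(rss[sel]),
       n_breaks = ms[sel])
}

# Welch two-sample t-test p-value from the textbook formulas
oracle_welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# chi-squared contingency p-value from first principles
oracle_chisq_p <- function(tab, correct = FALSE) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  d <- abs(tab - expected)
  if (correct) d <- pmax(d - 0.5, 0)
  stat <- sum(d^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(stat = stat, p = pchisq(stat, df, lower.tail = FALSE))
}

# OLS slope, p-value and R^2 from closed forms
oracle_ols <- function(year, y) {
  n <- length(y)
  xb <- mean(year); yb <- mean(y)
  sxx <- sum((year - xb)^2)
  slope <- sum((year - xb) * (y - yb)) / sxx
  yhat <- yb + slope * (year - xb)
  sse <- sum((y - yhat)^2)
  sst <- sum((y - yb)^2)
  se <- sqrt(sse / (n - 2) / sxx)
  t <- slope / se
  list(slope = slope, p = 2 * pt(-abs(t), n - 2), r2 = 1 - sse / sst)
}

# brute-force Queen dilation ring of a fire mask (stop-set oracle)
oracle_dilation_ring <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  ring <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (mask[r, c]) next
    for (dr in -1:1) for (dc in -1:1) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && mask[r2, c2]) {
        ring[r, c] <- TRUE
      }
    }
  }
  ring
}

# small helper: a single-fire scene drawn directly from a day-of-burn matrix
scene_from_matrix <- function(m, ...) {
  burn_scene(m, label_fire_events(m), ...)
}
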