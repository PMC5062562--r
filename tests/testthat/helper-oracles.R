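# Independent oracles, written directly from the definitions, against which
# the package's computations are checked. They deliberately share no code
# with the implementation.

# linear interpolation between order statistics ("type 7")
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# nearest-rank ("type 1"): smallest order statistic whose rank >= n*p
oracle_quantile1 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (p <= 0) return(x[1L])
  x[max(1L, ceiling(n * p))]
}

# brute-force re-application of the four exclusion rules in order
oracle_exclusion <- function(gps, manual, software, cv,
                             k = 1.42, cvmax = 0.5,
                             fence = c("quartile_fences", "median_centered"),
                             qfun = oracle_quantile7) {
  fence <- match.arg(fence)
  n <- length(gps)
  reason <- rep(NA_character_, n)
  reason[manual] <- "manual_flag"
  reason[is.na(reason) & software] <- "software_outlier"
  cand <- which(is.na(reason))
  if (length(cand)) {
    v <- gps[cand]
    q1 <- qfun(v, 0.25)
    q2 <- qfun(v, 0.50)
    q3 <- qfun(v, 0.75)
    iqr <- q3 - q1
    b <- if (fence == "quartile_fences") c(q1 - k * iqr, q3 + k * iqr)
         else c(q2 - k * iqr, q2 + k * iqr)
    out <- cand[gps[cand] < b[1L] | gps[cand] > b[2L]]
    reason[out] <- "iqr_fence"
  }
  reason[is.na(reason) & cv > cvmax] <- "pixel_cv"
  reason
}

# exact two-sided Mann-Whitney p by exhaustive enumeration of all
# choose(n_a + n_b, n_a) rank assignments (no ties assumed)
oracle_mw_p <- function(a, b) {
  n_a <- length(a)
  n_b <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combos <- utils::combn(n_a + n_b, n_a)
  ws <- colSums(matrix(combos, nrow = n_a)) - n_a * (n_a + 1) / 2
  p <- if (w_obs > n_a * n_b / 2) mean(ws >= w_obs) else mean(ws <= w_obs)
  min(2 * p, 1)
}
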