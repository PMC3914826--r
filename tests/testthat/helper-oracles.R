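# Brute-force oracles, deliberately written as plain loops over the
# definitions, independent of the package's vectorised implementations.

# medcouple: all-pairs kernel median, straight from the definition
oracle_medcouple <- function(x) {
  x <- sort(x)
  m <- stats::median(x)
  xl <- x[x <= m]
  xr <- x[x >= m]
  k <- sum(x == m)
  h <- c()
  for (i in seq_along(xl)) {
    for (j in seq_along(xr)) {
      a <- xl[i]
      b <- xr[j]
      if (a == m && b == m) {
        # indices of this pair among the k median-tied points
        ii <- i - (length(xl) - k)
        jj <- j
        h <- c(h, sign(ii + jj - 1L - k))
      } else {
        h <- c(h, ((b - m) - (m - a)) / (b - a))
      }
    }
  }
  stats::median(h)
}

# minimum SRT: exhaustive scan over all candidate run starts
oracle_min_srt <- function(binned, k = 5, alpha = 0.05) {
  crit <- stats::qchisq(1 - alpha, df = 1)
  nb <- nrow(binned)
  sig <- logical(nb)
  for (i in seq_len(nb)) {
    nc <- binned$n_correct[i]
    ni <- binned$n_incorrect[i]
    n <- nc + ni
    sig[i] <- n > 0 && ((nc - ni)^2 / n) >= crit && nc > ni
  }
  if (nb >= k) {
    for (i in seq_len(nb - k + 1L)) {
      if (all(sig[i:(i + k - 1L)])) return(binned$bin_left[i])
    }
  }
  NA_real_
}

# random binned-count instances for the minimum-SRT scan oracle
random_binned <- function(n_bins = 30, max_count = 12) {
  structure(data.frame(
    bin_left = (seq_len(n_bins) - 1L) * 10,
    n_correct = sample(0:max_count, n_bins, replace = TRUE),
    n_incorrect = sample(0:max_count, n_bins, replace = TRUE)),
    width_ms = 10, class = c("binned_srt", "data.frame"))
}
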