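# Independent brute-force oracle for the modified cosine: enumerates every
# one-to-one matching over candidate fragment pairs (direct or
# precursor-shifted) and returns the best achievable score. Written naively
# on purpose -- no sorting, no pruning bound shared with the package code.

oracle_modified_cosine <- function(a, b, fragment_tol = 0.9, zero_shift_tol = 0) {
  if (nrow(a$peaks) == 0L || nrow(b$peaks) == 0L)
    return(list(cosine = 0, matched_peaks = 0L))
  dprec <- a$precursor_mz - b$precursor_mz
  if (abs(dprec) <= zero_shift_tol) dprec <- 0
  pairs <- list()
  for (i in seq_len(nrow(a$peaks))) {
    for (j in seq_len(nrow(b$peaks))) {
      d <- a$peaks[i, 1] - b$peaks[j, 1]
      if (abs(d) <= fragment_tol || abs(d - dprec) <= fragment_tol)
        pairs[[length(pairs) + 1L]] <-
          c(i = i, j = j,
            w = unname(sqrt(a$peaks[i, 2]) * sqrt(b$peaks[j, 2])))
    }
  }
  best <- list(score = 0, matched = 0L)
  recurse <- function(k, used_i, used_j, acc, m) {
    if (acc > best$score) best <<- list(score = acc, matched = m)
    if (k > length(pairs)) return()
    p <- pairs[[k]]
    if (!(p["i"] %in% used_i) && !(p["j"] %in% used_j))
      recurse(k + 1L, c(used_i, p["i"]), c(used_j, p["j"]), acc + p["w"], m + 1L)
    recurse(k + 1L, used_i, used_j, acc, m)
  }
  recurse(1L, integer(0), integer(0), 0, 0L)
  score <- best$score / (sqrt(sum(a$peaks[, 2])) * sqrt(sum(b$peaks[, 2])))
  list(cosine = unname(min(1, max(0, score))),
       matched_peaks = unname(best$matched))
}

# Random related spectrum pair: B copies some of A's peaks with jitter, some
# shifted by the precursor difference, plus random fill.
random_spectrum_pair <- function(max_peaks = 8L) {
  na <- sample(2:max_peaks, 1)
  mza <- sort(runif(na, 50, 500))
  pa <- runif(1, 520, 900)
  a <- fragment_spectrum(pa, 1L, mz = mza, intensity = runif(na, 10, 1000),
                         feature_id = 1L)
  pb <- pa + runif(1, -30, 30)
  mzb <- numeric(0)
  for (m in mza) {
    r <- runif(1)
    if (r < 0.4) mzb <- c(mzb, m + runif(1, -0.3, 0.3))
    else if (r < 0.7) mzb <- c(mzb, m + (pb - pa) + runif(1, -0.3, 0.3))
  }
  while (length(mzb) < 2) mzb <- c(mzb, runif(1, 50, 500))
  mzb <- utils::head(sort(mzb), max_peaks)
  b <- fragment_spectrum(pb, 1L, mz = mzb,
                         intensity = runif(length(mzb), 10, 1000),
                         feature_id = 2L)
  list(a = a, b = b)
}
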