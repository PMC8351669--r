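# Independent brute-force oracles, deliberately coded without reuse of the
# package's internals.

# Exhaustive segmented regression: every breakpoint subset of the interior
# distinct times, RSS via lm(), BIC = n log(RSS/n) + p log(n).
slow_segmented <- function(y, t, sex, maxK = 8, minPerSegment = 2) {
  n <- length(y)
  cand <- sort(unique(t))
  cand <- cand[-c(1, length(cand))]
  useSex <- length(unique(sex)) > 1
  best <- list(bic = Inf)
  for (k in 0:maxK) {
    sets <- if (k == 0) list(numeric(0)) else {
      if (length(cand) < k) list() else utils::combn(cand, k, simplify = FALSE)
    }
    kbest <- NULL
    for (bp in sets) {
      seg <- findInterval(t, c(-Inf, bp, Inf), left.open = TRUE)
      if (any(tabulate(seg, nbins = k + 1) < minPerSegment)) next
      df <- data.frame(y = y, t = t)
      X <- cbind(t = t)
      for (b in bp) X <- cbind(X, pmax(t - b, 0))
      if (useSex) X <- cbind(X, sex = sex)
      fit <- stats::lm(y ~ X)
      if (anyNA(stats::coef(fit))) next
      rss <- sum(stats::resid(fit)^2)
      if (is.null(kbest) || rss < kbest$rss - 1e-12)
        kbest <- list(k = k, bp = bp, rss = rss, p = length(stats::coef(fit)))
    }
    if (!is.null(kbest)) {
      bic <- n * log(kbest$rss / n) + kbest$p * log(n)
      if (bic < best$bic) best <- c(kbest, list(bic = bic))
    }
  }
  best
}

# O(n^3) topological overlap by explicit loops.
slow_tom <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { tom[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# Exclusive set regions by per-element membership enumeration.
slow_regions <- function(sets) {
  u <- unique(unlist(sets))
  key <- vapply(u, function(el)
    paste(names(sets)[vapply(sets, function(s) el %in% s, logical(1))],
          collapse = "&"), character(1))
  split(u, key)
}

# Two-sided Fisher p by enumeration of the hypergeometric support.
slow_fisher_p <- function(a, b, c, d) {
  m <- a + c; nn <- b + d; k <- a + b
  support <- max(0, k - nn):min(k, m)
  probs <- stats::dhyper(support, m, nn, k)
  sum(probs[probs <= stats::dhyper(a, m, nn, k) * (1 + 1e-7)])
}
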