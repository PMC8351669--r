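#' @importFrom S4Vectors DataFrame
NULL

# Breakpoint placements: subsets of the interior distinct observed times for
# which every segment keeps >= minPerSegment samples. A sample at exactly a
# breakpoint belongs to the segment on its left.
placements_for_k <- function(t, k, minPerSegment) {
  cand <- sort(unique(t))
  cand <- cand[-c(1, length(cand))]
  if (k == 0L) return(list(numeric(0)))
  if (length(cand) < k) return(list())
  sets <- utils::combn(cand, k, simplify = FALSE)
  ok <- vapply(sets, function(bp) {
    cuts <- c(-Inf, bp, Inf)
    seg <- findInterval(t, cuts, left.open = TRUE)   # t <= bp -> left segment
    counts <- tabulate(seg, nbins = k + 1L)
    all(counts >= minPerSegment)
  }, logical(1))
  sets[ok]
}

hinge_design <- function(t, sex, bp, useSex) {
  X <- cbind(1, t)
  for (b in bp) X <- cbind(X, pmax(t - b, 0))
  if (useSex) X <- cbind(X, sex)
  X
}

# Contrast matrix mapping coefficients to the k+1 segment slopes:
# s_0 = beta_t, s_j = s_{j-1} + delta_j.
slope_contrasts <- function(k, p) {
  L <- matrix(0, k + 1L, p)
  L[, 2] <- 1
  if (k > 0) for (j in seq_len(k)) L[(j + 1):(k + 1), 2 + j] <- 1
  L
}

#' Fit BIC-selected segmented regressions to an expression matrix
#'
#' For every gene, fits ordinary least squares on the continuous hinge basis
#' `y = b0 + b1 t + sum_j delta_j (t - bp_j)_+ + gamma sex` for every
#' admissible breakpoint placement (breakpoints restricted to interior
#' distinct observed ages, every segment holding at least `minPerSegment`
#' samples) and every breakpoint count `k = 0..maxK`; keeps the minimum-RSS
#' placement per `k` and selects `k` by the smallest
#' `BIC = n log(RSS/n) + p log(n)` (ties resolved toward fewer parameters).
#' The search shares one QR decomposition per placement across all genes,
#' so a whole matrix costs little more than a single gene.
#'
#' The reported adjusted R-squared is partial with respect to the
#' intercept + sex baseline: it measures the variance the time terms
#' explain beyond sex, so a gene whose expression is purely sex-driven
#' scores near zero however strong the sex effect.
#'
#' @param Y Expression matrix, genes x samples (variance-stabilized scale).
#' @param t Ages in months, one per sample.
#' @param sex Binary vector (0 = female, 1 = male), one per sample; the sex
#'   term is a single additive covariate shared across segments.
#' @param maxK Largest number of breakpoints searched (default 8).
#' @param minPerSegment Minimum samples per segment (default 2).
#' @param slopeAlpha Segment slopes with p-value at or above this are called
#'   `"flat"` (default 0.1).
#' @param details If `FALSE`, skip slope p-values and coefficients and
#'   return only `(k, breakpoints, rss, adj_r2, bic)` — used by the
#'   permutation null, where only adjusted R-squared is needed.
#' @return A [SegmentedFits] object (or a plain DataFrame when
#'   `details = FALSE`).
#' @export
fitSegmentedMatrix <- function(Y, t, sex, maxK = 8L, minPerSegment = 2L,
                               slopeAlpha = 0.1, details = TRUE) {
  Y <- as.matrix(Y)
  n <- length(t)
  stopifnot(ncol(Y) == n, length(sex) == n, minPerSegment >= 1)
  if (length(unique(t)) < 2) stop("need at least 2 distinct ages")
  maxK <- as.integer(maxK)
  useSex <- length(unique(sex)) > 1
  G <- nrow(Y)
  Yt <- t(Y)                                  # n x G
  yss <- colSums(Yt^2)
  # baseline model (intercept + sex): adjusted R2 measures the variance the
  # time terms explain beyond it, so sex-driven genes do not score as dynamic
  X0 <- if (useSex) cbind(1, sex) else matrix(1, n, 1)
  q0 <- qr(X0)
  p0 <- q0$rank
  rss0 <- pmax(yss - colSums(crossprod(qr.Q(q0), Yt)^2), 0)

  bestRss <- matrix(Inf, G, maxK + 1L)        # per-k minimum RSS
  bestIdx <- matrix(NA_integer_, G, maxK + 1L)
  placeList <- vector("list", maxK + 1L)
  pPar <- integer(maxK + 1L)

  for (k in 0:maxK) {
    pls <- placements_for_k(t, k, minPerSegment)
    placeList[[k + 1L]] <- pls
    if (!length(pls)) next
    for (i in seq_along(pls)) {
      X <- hinge_design(t, sex, pls[[i]], useSex)
      qrX <- qr(X)
      if (qrX$rank < ncol(X)) next            # rank-deficient candidate: drop
      Q1 <- qr.Q(qrX)
      rss <- pmax(yss - colSums(crossprod(Q1, Yt)^2), 0)
      upd <- rss < bestRss[, k + 1L]
      bestRss[upd, k + 1L] <- rss[upd]
      bestIdx[upd, k + 1L] <- i
      pPar[k + 1L] <- ncol(X)
    }
  }

  feasible <- which(pPar > 0)
  # floor numerically-zero residuals so exact interpolation ties (RSS = 0 at
  # several k up to rounding) resolve toward the smaller model
  rssFloor <- 1e-12 * pmax(rss0, yss / n)
  bic <- matrix(Inf, G, maxK + 1L)
  for (kk in feasible) {
    rk <- ifelse(bestRss[, kk] < rssFloor, 0, bestRss[, kk])
    bic[, kk] <- n * log(rk / n) + pPar[kk] * log(n)
  }
  # ascending k with strict improvement => exact RSS ties go to fewer parameters
  selK <- integer(G); selBic <- rep(Inf, G)
  for (kk in feasible) {
    upd <- bic[, kk] < selBic
    selK[upd] <- kk - 1L
    selBic[upd] <- bic[upd, kk]
  }
  selRss <- unname(bestRss[cbind(seq_len(G), selK + 1L)])
  selP <- pPar[selK + 1L]
  adj <- unname(1 - (selRss / (n - selP)) / (rss0 / (n - p0)))
  adj[rss0 == 0] <- 0
  selBic <- unname(selBic)

  gid <- rownames(Y); if (is.null(gid)) gid <- paste0("g", seq_len(G))
  if (!details) {
    return(S4Vectors::DataFrame(gene_id = gid, k = selK, rss = selRss,
                                adj_r2 = adj, bic = selBic))
  }

  bps <- slopes <- pvals <- dirs <- vector("list", G)
  sexco <- numeric(G)
  key <- paste(selK, bestIdx[cbind(seq_len(G), selK + 1L)])
  for (grp in split(seq_len(G), key)) {
    k <- selK[grp[1]]
    bp <- placeList[[k + 1L]][[bestIdx[grp[1], k + 1L]]]
    X <- hinge_design(t, sex, bp, useSex)
    p <- ncol(X)
    XtXinv <- solve(crossprod(X))
    beta <- XtXinv %*% crossprod(X, Yt[, grp, drop = FALSE])  # p x g
    L <- slope_contrasts(k, p)
    S <- L %*% beta                                           # (k+1) x g slopes
    lvl <- sqrt(diag(L %*% XtXinv %*% t(L)))                  # unscaled contrast SDs
    sigma <- sqrt(selRss[grp] / (n - p))
    for (j in seq_along(grp)) {
      g <- grp[j]
      se <- lvl * sigma[j]
      tv <- ifelse(se > 0, S[, j] / se, ifelse(abs(S[, j]) > 1e-10, Inf, 0))
      pv <- 2 * stats::pt(-abs(tv), df = n - p)
      bps[[g]] <- bp
      slopes[[g]] <- unname(S[, j])
      pvals[[g]] <- unname(pv)
      dirs[[g]] <- ifelse(pv >= slopeAlpha, "flat",
                          ifelse(S[, j] > 0, "up", "down"))
      sexco[g] <- if (useSex) beta[p, j] else NA_real_
    }
  }

  fits <- S4Vectors::DataFrame(
    gene_id = gid, k = selK, breakpoints = I(bps), slopes = I(slopes),
    slope_pvalues = I(pvals), directions = I(dirs), sex_coef = sexco,
    adj_r2 = adj, bic = selBic, rss = selRss)
  methods::new("SegmentedFits", fits = fits, ages = as.numeric(t),
               maxK = maxK, slopeAlpha = slopeAlpha)
}

#' Fit a single gene's segmented regression
#'
#' Convenience wrapper around [fitSegmentedMatrix()] for one expression
#' vector; returns the one-row fit as a list.
#'
#' @param y Expression values, one per sample.
#' @inheritParams fitSegmentedMatrix
#' @return List with `k`, `breakpoints`, `slopes`, `slope_pvalues`,
#'   `directions`, `sex_coef`, `adj_r2`, `bic`, `rss`.
#' @export
fitSegmented <- function(y, t, sex, maxK = 8L, minPerSegment = 2L,
                         slopeAlpha = 0.1) {
  stopifnot(length(y) == length(t))
  f <- fitSegmentedMatrix(matrix(y, 1, dimnames = list("y", NULL)), t, sex,
                          maxK, minPerSegment, slopeAlpha)@fits
  list(k = f$k[1], breakpoints = f$breakpoints[[1]], slopes = f$slopes[[1]],
       slope_pvalues = f$slope_pvalues[[1]], directions = f$directions[[1]],
       sex_coef = f$sex_coef[1], adj_r2 = f$adj_r2[1], bic = f$bic[1],
       rss = f$rss[1])
}

#' Permutation-calibrated adjusted R-squared cutoff
#'
#' Repeatedly permutes the sample-to-age assignment (sex stays attached to
#' its sample), refits the whole matrix, pools the null adjusted R-squared
#' values, and returns their `1 - passFraction` inverse-ECDF quantile, so
#' that the fraction of permuted fits strictly exceeding the cutoff is at
#' most `passFraction` (default 0.01, i.e. fewer than 1% of genes pass under
#' the null).
#'
#' @inheritParams fitSegmentedMatrix
#' @param expr Expression matrix, genes x samples.
#' @param nPerm Number of permutations (default 10).
#' @param passFraction Target null pass fraction (default 0.01).
#' @param seed Optional integer seed for the permutations.
#' @return List with `cutoff` and `null_r2` (all pooled permuted adjusted
#'   R-squared values).
#' @export
permutationR2Cutoff <- function(expr, t, sex, nPerm = 10L, passFraction = 0.01,
                                maxK = 8L, minPerSegment = 2L, seed = NULL) {
  stopifnot(nPerm >= 1, passFraction > 0, passFraction < 1)
  expr <- as.matrix(expr)
  if (nPerm * nrow(expr) < 1 / passFraction)
    warning("too few pooled null fits for a stable quantile at this passFraction")
  if (!is.null(seed)) set.seed(seed)
  null_r2 <- vector("list", nPerm)
  for (b in seq_len(nPerm)) {
    tp <- sample(t)
    f <- fitSegmentedMatrix(expr, tp, sex, maxK, minPerSegment, details = FALSE)
    null_r2[[b]] <- f$adj_r2
  }
  pooled <- unlist(null_r2)
  cutoff <- unname(stats::quantile(pooled, 1 - passFraction, type = 1))
  list(cutoff = cutoff, null_r2 = pooled)
}

overall_trend <- function(dirs) {
  up <- any(dirs == "up"); dn <- any(dirs == "down")
  if (up && !dn) "increasing" else if (dn && !up) "decreasing" else "mixed"
}

#' Call top dynamic genes
#'
#' A gene is top dynamic when its selected model's adjusted R-squared
#' strictly exceeds the cutoff and at least one segment slope is significant
#' (minimum slope p-value below `slopeAlpha`).
#'
#' @param fits A [SegmentedFits] object.
#' @param cutoff Adjusted R-squared cutoff (tissue-specific, or from
#'   [permutationR2Cutoff()]).
#' @param slopeAlpha Segment-slope significance level (default 0.1).
#' @param expressed Number of expressed genes used for the percentage
#'   (defaults to the number of fitted genes).
#' @return List with `calls` (data.frame: `gene_id`, `is_top_dynamic`,
#'   `cutoff_used`, `overall_trend`), `n_dynamic`, `expressed` and
#'   `percent` (one decimal, of expressed genes).
#' @export
selectTopDynamic <- function(fits, cutoff, slopeAlpha = 0.1, expressed = NULL) {
  stopifnot(is.finite(cutoff), slopeAlpha > 0, slopeAlpha < 1)
  f <- fitTable(fits)
  minp <- vapply(f$slope_pvalues, min, numeric(1))
  sel <- f$adj_r2 > cutoff & minp < slopeAlpha
  if (is.null(expressed)) expressed <- nrow(f)
  calls <- data.frame(
    gene_id = f$gene_id, is_top_dynamic = sel, cutoff_used = cutoff,
    overall_trend = vapply(f$directions, overall_trend, character(1)),
    row.names = NULL)
  list(calls = calls, n_dynamic = sum(sel), expressed = expressed,
       percent = round(100 * sum(sel) / expressed, 1))
}

#' Summarize breakpoint times of selected genes
#'
#' Pools every breakpoint of the selected genes, histograms them over the
#' observed age grid, and reports the median breakpoint time, the fraction
#' at or before a reference age (default 15 months), the per-k gene
#' fractions and the monotonic (k = 0) fraction.
#'
#' @param fits A [SegmentedFits] object.
#' @param selected Gene ids to pool (must be a subset of the fitted genes).
#' @param referenceAge Age in months for the early-breakpoint fraction.
#' @return List with `histogram` (named counts per grid age), `median`
#'   (NA when no gene has a breakpoint), `fraction_before_reference`,
#'   `k_fractions`, `monotonic_fraction`, `n_breakpoints`.
#' @export
summarizeBreakpoints <- function(fits, selected, referenceAge = 15) {
  f <- fitTable(fits)
  if (!all(selected %in% f$gene_id)) stop("selected genes must be among the fits")
  f <- f[f$gene_id %in% selected, , drop = FALSE]
  bp <- unlist(f$breakpoints)
  grid <- sort(unique(fits@ages))
  hist <- table(factor(bp, levels = grid))
  kfr <- table(factor(f$k, levels = 0:fits@maxK)) / nrow(f)
  list(histogram = c(hist),
       median = if (length(bp)) stats::median(bp) else NA_real_,
       fraction_before_reference = if (length(bp)) mean(bp <= referenceAge) else NA_real_,
       k_fractions = c(kfr),
       monotonic_fraction = unname(kfr["0"]),
       n_breakpoints = length(bp))
}

#' Compare breakpoint distributions between groups
#'
#' Tie-corrected Kruskal-Wallis test across tissues followed by Dunn's
#' pairwise z-tests on the joint ranks, with multiplicity adjustment
#' (Holm by default).
#'
#' @param groups Named list of numeric breakpoint-time vectors, one per
#'   tissue.
#' @param adjust Adjustment method for the pairwise p-values (any
#'   [stats::p.adjust()] method).
#' @return List with `kruskal` (`statistic`, `p.value`) and `dunn`, a
#'   data.frame of pairwise `z`, `p`, `p_adj`.
#' @export
compareBreakpointDistributions <- function(groups, adjust = "holm") {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 1))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  if (length(unique(x)) == 1) {
    kw <- list(statistic = 0, p.value = 1)
  } else {
    k <- stats::kruskal.test(x, g)
    kw <- list(statistic = unname(k$statistic), p.value = k$p.value)
  }
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  nn <- tapply(r, g, length)
  ties <- table(x)
  Tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2)
  z <- p <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt((N * (N + 1) / 12 - Tcorr) * (1 / nn[[a]] + 1 / nn[[b]]))
    z[i] <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  dunn <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
                     p_adj = stats::p.adjust(p, method = adjust))
  list(kruskal = kw, dunn = dunn)
}

#' Biotype over/under-representation among selected genes
#'
#' For each biotype, tests the 2x2 table (selected vs not) x (biotype vs
#' not) over the reference gene set with a two-sided Fisher exact test
#' (`mode = "chisq"` switches to the chi-squared approximation), reporting
#' the sample odds ratio `ad/bc` and BH-adjusted p-values across biotypes.
#'
#' @param selected Character vector of selected gene ids.
#' @param reference Character vector of all reference gene ids
#'   (`selected` must be a subset).
#' @param biotypes Named character vector mapping every reference gene to a
#'   biotype.
#' @param mode `"fisher"` (default) or `"chisq"`.
#' @return data.frame with `biotype`, `n_selected`, `n_reference`,
#'   `odds_ratio`, `p`, `p_adj`.
#' @export
biotypeEnrichment <- function(selected, reference, biotypes,
                              mode = c("fisher", "chisq")) {
  mode <- match.arg(mode)
  stopifnot(all(selected %in% reference))
  bt <- biotypes[reference]
  if (anyNA(bt)) stop("every reference gene must have a biotype label")
  insel <- reference %in% selected
  out <- lapply(unique(bt), function(b) {
    a <- sum(insel & bt == b);  bb <- sum(insel & bt != b)
    cc <- sum(!insel & bt == b); d <- sum(!insel & bt != b)
    orr <- if (a == 0) 0 else if (bb == 0 || cc == 0) Inf else (a * d) / (bb * cc)
    m <- matrix(c(a, bb, cc, d), 2, byrow = TRUE)
    pv <- if (mode == "fisher") stats::fisher.test(m)$p.value
          else suppressWarnings(stats::chisq.test(m)$p.value)
    data.frame(biotype = b, n_selected = a, n_reference = a + cc,
               odds_ratio = orr, p = pv)
  })
  out <- do.call(rbind, out)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}
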