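#' Assemble a count experiment
#'
#' Bundles a gene x sample integer count matrix with sample metadata and
#' optional gene annotation into a [SummarizedExperiment::SummarizedExperiment]
#' (assay `"counts"`). Sex is recoded to the binary `sex_code` trait
#' (0 = female, 1 = male) used by the module-trait and regression stages.
#'
#' @param counts Non-negative integer matrix, genes x samples, with row and
#'   column names.
#' @param samples data.frame with `sample_id`, `tissue`, `age_months` and
#'   `sex` (`"F"`/`"M"`) or `sex_code` (0/1); one row per sample.
#' @param annotation Optional data.frame with `gene_id`, `symbol`,
#'   `biotype`.
#' @return A `SummarizedExperiment` whose `colData` carries `tissue`,
#'   `age_months`, `sex_code` and `library_size`.
#' @export
makeAgingExperiment <- function(counts, samples, annotation = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene and sample names")
  if (anyDuplicated(rownames(counts))) stop("gene ids must be unique")
  if (anyDuplicated(colnames(counts))) stop("sample ids must be unique")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  samples <- as.data.frame(samples)
  if (anyDuplicated(samples$sample_id)) stop("sample ids must be unique")
  idx <- match(colnames(counts), samples$sample_id)
  if (anyNA(idx)) stop("metadata missing for samples: ",
                       paste(colnames(counts)[is.na(idx)], collapse = ", "))
  samples <- samples[idx, , drop = FALSE]
  if (is.null(samples$sex_code)) {
    if (is.null(samples$sex)) stop("need a sex or sex_code column")
    if (!all(samples$sex %in% c("F", "M"))) stop("sex must be F or M")
    samples$sex_code <- as.integer(samples$sex == "M")
  }
  if (!all(samples$sex_code %in% c(0L, 1L))) stop("sex_code must be 0/1")
  if (any(samples$age_months <= 0)) stop("age_months must be positive")
  samples$library_size <- colSums(counts)
  cd <- S4Vectors::DataFrame(samples, row.names = samples$sample_id)
  rd <- S4Vectors::DataFrame(gene_id = rownames(counts), row.names = rownames(counts))
  if (!is.null(annotation)) {
    annotation <- as.data.frame(annotation)
    m <- match(rownames(counts), annotation$gene_id)
    rd$symbol <- annotation$symbol[m]
    rd$biotype <- annotation$biotype[m]
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd, rowData = rd)
}

counts_of <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) SummarizedExperiment::assay(x, "counts")
  else as.matrix(x)
}

#' Drop shallow libraries
#'
#' Removes samples whose library size (column sum over all genes) is below
#' `minReads`. The default reproduces the 4,000,000-read depth filter used
#' for the aging tissue libraries.
#'
#' @param x Count matrix (genes x samples) or `SummarizedExperiment` with a
#'   `"counts"` assay.
#' @param minReads Minimum total reads per retained sample.
#' @return A list with `counts` (or the subset experiment, matching the
#'   input type) and `qc`, a per-sample data.frame with `sample_id`,
#'   `library_size`, `depth_pass`.
#' @export
filterSamplesByDepth <- function(x, minReads = 4e6) {
  stopifnot(minReads >= 0)
  counts <- counts_of(x)
  libsize <- colSums(counts)
  keep <- libsize >= minReads
  if (!any(keep)) stop("no samples retained by the depth filter")
  qc <- data.frame(sample_id = colnames(counts), library_size = libsize,
                   depth_pass = keep, row.names = NULL)
  out <- if (methods::is(x, "SummarizedExperiment")) x[, keep] else counts[, keep, drop = FALSE]
  list(counts = out, qc = qc)
}

#' Flag outlier samples by standardized network connectivity
#'
#' Builds the Oldham-style sample network on expression columns: pairwise
#' Pearson correlation `r_ij`, adjacency `((1+r_ij)/2)^2`, connectivity
#' `K_i = sum_{j != i} A_ij`, and the standardized connectivity
#' `z.K = (K - mean K)/sd K`. Samples with `|z.K|` above `sdThreshold`
#' (default 2 standard deviations) are flagged as outliers.
#'
#' @param expr Expression matrix (genes x samples), typically on the
#'   variance-stabilized scale, or a `SummarizedExperiment` with a `"vst"`
#'   assay.
#' @param sdThreshold Number of standard deviations of z.K beyond which a
#'   sample is called an outlier.
#' @return data.frame with `sample_id`, `connectivity`, `z_k`, `outlier`.
#' @export
detectOutlierSamples <- function(expr, sdThreshold = 2) {
  if (methods::is(expr, "SummarizedExperiment"))
    expr <- SummarizedExperiment::assay(expr, "vst")
  expr <- as.matrix(expr)
  if (ncol(expr) < 3) stop("need at least 3 samples for the sample network")
  r <- stats::cor(expr)
  A <- ((1 + r) / 2)^2
  diag(A) <- 0
  K <- colSums(A)
  s <- stats::sd(K)
  z <- if (s > 0) (K - mean(K)) / s else rep(0, length(K))
  data.frame(sample_id = colnames(expr), connectivity = K, z_k = z,
             outlier = abs(z) > sdThreshold, row.names = NULL)
}

#' Filter low-count genes
#'
#' Keeps genes whose count exceeds `minCount` in at least `minSamples`
#' samples (`mode = "per_sample"`, the default reading of "read count higher
#' than 10 in at least n samples"), or whose row total exceeds `minCount`
#' (`mode = "row_total"`). `minSamples` conventionally equals the tissue's
#' minimum group size.
#'
#' @inheritParams filterSamplesByDepth
#' @param minCount Count that must be strictly exceeded.
#' @param minSamples Number of samples in which it must be exceeded.
#' @param mode `"per_sample"` or `"row_total"`.
#' @return The filtered matrix or experiment (same type as the input).
#' @export
filterLowCountGenes <- function(x, minCount = 10, minSamples = 1,
                                mode = c("per_sample", "row_total")) {
  mode <- match.arg(mode)
  counts <- counts_of(x)
  if (minSamples > ncol(counts)) stop("minSamples exceeds the sample count")
  keep <- if (mode == "per_sample") {
    rowSums(counts > minCount) >= minSamples
  } else {
    rowSums(counts) > minCount
  }
  if (methods::is(x, "SummarizedExperiment")) x[keep, ] else counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' For each gene with all-positive counts, the geometric mean across
#' samples is the reference; a sample's size factor is the median over
#' those genes of count/reference.
#'
#' @inheritParams filterSamplesByDepth
#' @return Named numeric vector of positive size factors.
#' @export
estimateSizeFactorsMoR <- function(x) {
  counts <- counts_of(x)
  pos <- rowSums(counts == 0) == 0
  if (!any(pos)) stop("no gene with all-positive counts; cannot form the reference")
  lg <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- apply(exp(lg - ref), 2, stats::median)
  stopifnot(all(sf > 0))
  sf
}

#' Fit the dispersion trend for the VST
#'
#' Method-of-moments per-gene dispersions on normalized counts,
#' `alpha_g = (var - mean)/mean^2`, regressed on `1/mean` with a robust
#' (Huber) linear fit so that `alpha(mu) ~ a1/mu + a0`. Negative fitted
#' coefficients are clamped to a small positive floor with a warning.
#'
#' @param counts Count matrix, genes x samples.
#' @param sizeFactors Positive per-sample size factors.
#' @return Numeric `c(a0, a1)`.
#' @export
estimateDispersionTrend <- function(counts, sizeFactors) {
  counts <- counts_of(counts)
  q <- sweep(counts, 2, sizeFactors, "/")
  mu <- rowMeans(q)
  v <- apply(q, 1, stats::var)
  use <- mu > 1 & v > mu           # over-dispersed, expressed genes inform the trend
  if (sum(use) < 10) {
    warning("too few genes to fit a dispersion trend; using a0 = 0.05, a1 = 1")
    return(c(a0 = 0.05, a1 = 1))
  }
  disp <- (v[use] - mu[use]) / mu[use]^2
  xinv <- 1 / mu[use]
  fit <- suppressWarnings(MASS::rlm(disp ~ xinv, maxit = 50))
  a0 <- unname(stats::coef(fit)[1]); a1 <- unname(stats::coef(fit)[2])
  floor_ <- 1e-8
  if (a0 < floor_) { warning("fitted asymptotic dispersion was negative; clamped"); a0 <- floor_ }
  if (a1 < 0) a1 <- 0
  c(a0 = a0, a1 = a1)
}

#' Variance-stabilizing transform for negative-binomial counts
#'
#' Closed-form VST for the mean-dispersion relation
#' `alpha(mu) = a1/mu + a0`, i.e. variance `v(mu) = (1 + a1) mu + a0 mu^2`:
#' the antiderivative of `1/sqrt(v(mu))` applied to normalized counts
#' `q = count/size factor`, scaled and shifted so large counts approach
#' `log2(q)`. With `method = "log2p1"` it computes `log2(q + 1)` instead.
#'
#' @param x Count matrix or `SummarizedExperiment` (assay `"counts"`); for
#'   experiments the result is stored as a `"vst"` assay.
#' @param sizeFactors Per-sample positive size factors; estimated by
#'   [estimateSizeFactorsMoR()] when `NULL`.
#' @param dispersion Numeric `c(a0, a1)`; fitted from the data by
#'   [estimateDispersionTrend()] when `NULL`.
#' @param method `"nbvst"` (default) or `"log2p1"`.
#' @return Transformed matrix, or the input experiment with a `"vst"` assay
#'   added.
#' @export
vstTransform <- function(x, sizeFactors = NULL, dispersion = NULL,
                         method = c("nbvst", "log2p1")) {
  method <- match.arg(method)
  counts <- counts_of(x)
  if (is.null(sizeFactors)) sizeFactors <- estimateSizeFactorsMoR(counts)
  stopifnot(all(sizeFactors > 0), length(sizeFactors) == ncol(counts))
  q <- sweep(counts, 2, sizeFactors, "/")
  if (method == "log2p1") {
    v <- log2(q + 1)
  } else {
    if (is.null(dispersion)) dispersion <- estimateDispersionTrend(counts, sizeFactors)
    a0 <- dispersion[[1]]; a1 <- dispersion[[2]]
    stopifnot(a1 >= 0)
    if (a0 < 1e-8) a0 <- 1e-8
    B <- 1 + a1
    # log2((2 a0 q + B + 2 sqrt(a0 q (a0 q + B))) / (4 a0)) -> log2(q) for large q
    v <- log2((2 * a0 * q + B + 2 * sqrt(a0 * q * (a0 * q + B))) / (4 * a0))
  }
  dimnames(v) <- dimnames(counts)
  if (methods::is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "vst") <- v
    x
  } else v
}

#' PCA on the most variable genes
#'
#' Selects the `nTop` genes with the highest row variance (default 500),
#' centers each gene (no unit-variance scaling by default) and computes
#' principal components over samples.
#'
#' @param expr Expression matrix (genes x samples) or `SummarizedExperiment`
#'   with a `"vst"` assay.
#' @param nTop Number of top-variance genes to keep.
#' @param scaleGenes Scale genes to unit variance before the decomposition.
#' @return List with `scores` (samples x PCs), `percentVar` (per PC, sums to
#'   <= 100), `genes` (the selected gene ids).
#' @export
pcaTopVariable <- function(expr, nTop = 500, scaleGenes = FALSE) {
  if (methods::is(expr, "SummarizedExperiment"))
    expr <- SummarizedExperiment::assay(expr, "vst")
  expr <- as.matrix(expr)
  if (nTop > nrow(expr)) stop("nTop exceeds the number of genes")
  rv <- rowVars_(expr)
  if (max(rv) == 0) stop("expression matrix is constant; PCA undefined")
  sel <- order(rv, decreasing = TRUE)[seq_len(nTop)]
  sub <- expr[sel, , drop = FALSE]
  pc <- stats::prcomp(t(sub), center = TRUE, scale. = scaleGenes)
  pv <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, percentVar = pv, genes = rownames(expr)[sel])
}

rowVars_ <- function(m) {
  cm <- rowMeans(m)
  rowSums((m - cm)^2) / (ncol(m) - 1)
}

#' Run the full pre-processing stage
#'
#' Depth filter, low-count gene filter, size factors, VST, sample-network
#' outlier removal, in that order. Outlier detection runs on the post-filter
#' VST matrix.
#'
#' @param se `SummarizedExperiment` with a `"counts"` assay.
#' @param minReads Depth filter threshold.
#' @param minCount,minSamples Low-count filter (see [filterLowCountGenes()]).
#' @param sdThreshold z.K outlier threshold.
#' @return List with `se` (filtered experiment carrying a `"vst"` assay and
#'   `sizeFactor` column), and `qc` combining the depth and outlier reports.
#' @export
preprocessCounts <- function(se, minReads = 4e6, minCount = 10,
                             minSamples = 1, sdThreshold = 2) {
  depth <- filterSamplesByDepth(se, minReads)
  se <- depth$counts
  se <- filterLowCountGenes(se, minCount, minSamples)
  sf <- estimateSizeFactorsMoR(se)
  se$sizeFactor <- sf
  se <- vstTransform(se, sizeFactors = sf)
  out <- detectOutlierSamples(SummarizedExperiment::assay(se, "vst"), sdThreshold)
  se <- se[, !out$outlier]
  qc <- merge(depth$qc, out, by = "sample_id", all.x = TRUE, sort = FALSE)
  qc$outlier[is.na(qc$outlier)] <- FALSE
  list(se = se, qc = qc)
}
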