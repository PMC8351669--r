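test_that("depth filter keeps samples at or above the threshold and is idempotent", {
  counts <- matrix(c(5e6, 4e6, 3.9e6), nrow = 1,
                   dimnames = list("g1", c("s1", "s2", "s3")))
  res <- filterSamplesByDepth(counts, 4e6)
  expect_equal(colnames(res$counts), c("s1", "s2"))
  expect_equal(res$qc$library_size, c(5e6, 4e6, 3.9e6))
  expect_equal(res$qc$depth_pass, c(TRUE, TRUE, FALSE))
  again <- filterSamplesByDepth(res$counts, 4e6)
  expect_identical(again$counts, res$counts)
  expect_error(filterSamplesByDepth(counts, 1e9), "no samples retained")
  # default threshold is the 4-million-read filter
  expect_equal(formals(filterSamplesByDepth)$minReads, 4e6)
})

test_that("depth filter drops exactly the planted shallow samples", {
  d <- sim_default()
  res <- filterSamplesByDepth(d$se)
  dropped <- setdiff(colnames(d$se), colnames(res$counts))
  expect_setequal(dropped, d$truth$samples$sample_id[d$truth$samples$shallow])
  # column sums recomputed by direct summation
  cs <- apply(SummarizedExperiment::assay(d$se, "counts"), 2, sum)
  expect_equal(res$qc$library_size, unname(cs))
})

test_that("sample-network outlier detection flags only disagreeing samples", {
  set.seed(42)
  base <- rnorm(200)
  expr <- sapply(1:21, function(i) base + rnorm(200, sd = 0.3))
  colnames(expr) <- paste0("s", 1:21)
  expr[, 21] <- sample(expr[, 21])           # destroy correlation, keep values
  qc <- detectOutlierSamples(expr, 2)
  expect_equal(qc$sample_id[qc$outlier], "s21")
  # K recomputed by explicit double loop
  K <- numeric(21)
  r <- cor(expr)
  for (i in 1:21) for (j in 1:21) if (i != j) K[i] <- K[i] + ((1 + r[i, j]) / 2)^2
  expect_equal(qc$connectivity, K, tolerance = 1e-12)
  # z.K standardization
  expect_equal(mean(qc$z_k), 0, tolerance = 1e-12)
  expect_equal(sd(qc$z_k), 1, tolerance = 1e-12)
})

test_that("outlier detection handles degenerate and invariance cases", {
  expr <- matrix(rep(1:10, 4), 10, 4, dimnames = list(NULL, paste0("s", 1:4)))
  qc <- detectOutlierSamples(expr)
  expect_true(all(qc$z_k == 0))
  expect_false(any(qc$outlier))
  expect_error(detectOutlierSamples(expr[, 1:2]), "3 samples")
  set.seed(1)
  expr <- matrix(rnorm(300), 30, 10, dimnames = list(NULL, paste0("s", 1:10)))
  a <- detectOutlierSamples(expr)
  b <- detectOutlierSamples(expr[sample(30), ] + 5)  # reorder genes, shift
  expect_equal(a$z_k, b$z_k, tolerance = 1e-10)
})

test_that("planted outlier samples are flagged at the 2 SD threshold", {
  d <- sim_default()
  keep <- !d$truth$samples$shallow
  se <- d$se[, keep]
  expr <- vstTransform(se)
  qc <- detectOutlierSamples(SummarizedExperiment::assay(expr, "vst"), 2)
  truth <- d$truth$samples$outlier[keep]
  expect_setequal(qc$sample_id[qc$outlier],
                  d$truth$samples$sample_id[keep][truth])
})

test_that("low-count gene filter applies the strict > threshold", {
  counts <- rbind(g1 = c(11, 11, 0, 0), g2 = c(10, 10, 10, 10),
                  g3 = c(100, 0, 0, 0))
  colnames(counts) <- paste0("s", 1:4)
  out <- filterLowCountGenes(counts, minCount = 10, minSamples = 2)
  expect_equal(rownames(out), "g1")
  # row-total alternative mode
  out2 <- filterLowCountGenes(counts, minCount = 10, mode = "row_total")
  expect_setequal(rownames(out2), c("g1", "g2", "g3"))
  # brute-force scan oracle on random counts
  set.seed(3)
  m <- matrix(rpois(600, 8), 60, 10,
              dimnames = list(paste0("g", 1:60), paste0("s", 1:10)))
  kept <- rownames(filterLowCountGenes(m, 10, 3))
  oracle <- rownames(m)[apply(m, 1, function(r) sum(r > 10) >= 3)]
  expect_identical(kept, oracle)
  # idempotence
  expect_identical(filterLowCountGenes(m[kept, ], 10, 3), m[kept, ])
})

test_that("median-of-ratios size factors match the closed form", {
  m <- matrix(c(10, 20, 30, 40), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  m[, 2] <- m[, 1] * 2
  sf <- estimateSizeFactorsMoR(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  same <- matrix(5, 3, 4, dimnames = list(letters[1:3], paste0("s", 1:4)))
  expect_equal(unname(estimateSizeFactorsMoR(same)), rep(1, 4))
  # direct formula oracle on a random NB matrix
  set.seed(8)
  m <- matrix(rnbinom(500, mu = 50, size = 2) + 1, 50, 10,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:10)))
  sf <- estimateSizeFactorsMoR(m)
  geo <- exp(rowMeans(log(m)))
  oracle <- apply(m / geo, 2, median)
  expect_equal(unname(sf), unname(oracle))
  # scale equivariance: scaling one sample by c scales its factor relative
  # to every other sample by c (the reference geometric mean absorbs c^(1/m))
  m2 <- m; m2[, 3] <- m2[, 3] * 4
  sf2 <- estimateSizeFactorsMoR(m2)
  expect_equal(unname(sf2[3] / sf2[1]), unname(4 * sf[3] / sf[1]),
               tolerance = 1e-10)
  expect_error(estimateSizeFactorsMoR(matrix(c(0, 1, 1, 0), 2,
    dimnames = list(c("a", "b"), c("s1", "s2")))), "all-positive")
})

test_that("size factors agree with the reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(4)
  # odd gene count: with an even count the reference averages the two middle
  # ratios geometrically rather than arithmetically
  m <- matrix(rnbinom(810, mu = 100, size = 1) + 1, 81, 10,
              dimnames = list(paste0("g", 1:81), paste0("s", 1:10)))
  ours <- estimateSizeFactorsMoR(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("the VST flattens the mean-variance relation and is monotone", {
  expect_equal(vstTransform(matrix(0, 1, 1, dimnames = list("g", "s")),
                            sizeFactors = 1, method = "log2p1")[1, 1], 0)
  # NB simulation across means 2^2..2^12 with alpha = 2/mu + 0.05
  set.seed(5)
  mus <- 2^(seq(2, 12, length.out = 30))
  counts <- t(sapply(mus, function(m)
    rnbinom(200, mu = m, size = 1 / (2 / m + 0.05))))
  dimnames(counts) <- list(paste0("g", seq_along(mus)), paste0("s", 1:200))
  v <- vstTransform(counts, sizeFactors = rep(1, 200),
                    dispersion = c(0.05, 2))
  sd_vst <- apply(v, 1, sd)
  sd_log <- apply(log2(counts + 1), 1, sd)
  bins <- cut(log2(mus), 5)
  ratio <- function(s) {
    m <- tapply(s, bins, mean)
    max(m) / min(m)
  }
  expect_lt(ratio(sd_vst), 2)
  # the untransformed scale stays strongly mean-dependent
  expect_gt(ratio(sd_log), 2.5)
  expect_gt(ratio(sd_log), 2 * ratio(sd_vst))
  # strictly monotone in the count
  x <- matrix(0:1000, 1, dimnames = list("g", paste0("s", 0:1000)))
  tv <- vstTransform(x, sizeFactors = rep(1, 1001), dispersion = c(0.05, 2))
  expect_true(all(diff(tv[1, ]) > 0))
  # Poisson-like limit: once a0*q >> 1 the transform tracks log2(q) + const
  q <- c(1e4, 1e5, 1e6)
  tv <- vstTransform(matrix(q, 1, dimnames = list("g", paste0("s", 1:3))),
                     sizeFactors = rep(1, 3), dispersion = c(0.01, 0))
  expect_equal(diff(tv[1, ]), diff(log2(q)), tolerance = 1e-2,
               ignore_attr = TRUE)
})

test_that("PCA on top-variance genes matches an SVD oracle", {
  expect_equal(formals(pcaTopVariable)$nTop, 500)
  set.seed(6)
  expr <- matrix(rnorm(3000), 100, 30,
                 dimnames = list(paste0("g", 1:100), paste0("s", 1:30)))
  # one gene block separates two sample groups
  expr[1:20, 1:15] <- expr[1:20, 1:15] + 5
  p <- pcaTopVariable(expr, nTop = 50)
  expect_gt(p$percentVar[1], p$percentVar[2])
  expect_true(all(sign(p$scores[1:15, 1]) != sign(p$scores[16:30, 1])))
  # SVD oracle on the centered selected submatrix
  rv <- apply(expr, 1, var)
  sub <- expr[order(rv, decreasing = TRUE)[1:50], ]
  cen <- t(scale(t(sub), scale = FALSE))
  sv <- svd(t(cen))
  expect_equal(abs(p$scores[, 1]), abs(sv$u[, 1] * sv$d[1]),
               tolerance = 1e-8, ignore_attr = TRUE)
  # orthogonality of scores
  g <- crossprod(p$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  expect_error(pcaTopVariable(matrix(1, 5, 4), nTop = 2), "constant")
})
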