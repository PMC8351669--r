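test_that("bicor behaves as a correlation and tracks Pearson on clean data", {
  set.seed(31)
  x <- rnorm(50)
  expect_equal(bicor(x, x), 1)
  expect_equal(bicor(x, -x), -1)
  # clean bivariate Gaussian: close to Pearson
  n <- 500; rho <- 0.6
  x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  expect_lt(abs(bicor(x, y) - cor(x, y)), 0.05)
  # robustness: a single extreme outlier degrades bicor less than half as
  # much as Pearson
  x2 <- rnorm(100); y2 <- 0.9 * x2 + sqrt(1 - 0.81) * rnorm(100)
  x_out <- x2; y_out <- y2
  x_out[1] <- 30; y_out[1] <- -30
  d_pear <- abs(cor(x2, y2) - cor(x_out, y_out))
  d_bic <- abs(bicor(x2, y2) - bicor(x_out, y_out))
  expect_lt(d_bic, d_pear / 2)
})

test_that("the bicor matrix is symmetric with unit diagonal and constant genes drop", {
  set.seed(32)
  expr <- matrix(rnorm(200), 20, 10, dimnames = list(paste0("g", 1:20), NULL))
  expr[5, ] <- 3                       # constant gene
  expect_warning(r <- bicorMatrix(expr), "constant")
  expect_equal(nrow(r), 19)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 19))
  expect_true(all(abs(r) <= 1 + 1e-12))
  # invariant to positive affine rescaling of a gene
  expr2 <- expr[-5, ]; expr2[3, ] <- 2 * expr2[3, ] + 5
  expect_equal(bicorMatrix(expr2)[3, 7], r[3, 7], tolerance = 1e-10)
})

test_that("signed adjacency matches the scalar formula", {
  expect_equal(adjacencySigned(matrix(1), 3)[1, 1], 1)
  r <- matrix(c(1, -1, -1, 1), 2); diag(r) <- 1
  expect_equal(adjacencySigned(r, 2)[1, 2], 0)
  r <- matrix(c(1, 0, 0, 1), 2)
  expect_equal(adjacencySigned(r, 1)[1, 2], 0.5)
  r <- matrix(c(1, 0.8, 0.8, 1), 2)
  expect_equal(adjacencySigned(r, 6)[1, 2], 0.9^6)
  set.seed(33)
  rr <- cor(matrix(rnorm(100), 10))
  a <- adjacencySigned(rr, 5)
  for (i in 1:10) for (j in 1:10) if (i != j)
    expect_equal(a[i, j], ((1 + rr[i, j]) / 2)^5)
})

test_that("TOM equals the explicit triple-loop oracle", {
  # two genes adjacent only to each other
  a <- diag(2); a[1, 2] <- a[2, 1] <- 1
  expect_equal(tomSimilarity(a)[1, 2], 1)
  set.seed(34)
  r <- cor(matrix(rnorm(50 * 20), 20, 50))
  a <- adjacencySigned(r, 4)
  tom <- tomSimilarity(a)
  expect_equal(tom, slow_tom(a), tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  # identical adjacency rows maximize overlap
  a2 <- a; a2[2, ] <- a2[1, ]; a2[, 2] <- a2[, 1]
  a2[1, 2] <- a2[2, 1] <- max(a[1, -(1:2)])
  tom2 <- tomSimilarity(a2)
  off <- tom2[upper.tri(tom2)]
  expect_equal(max(off), tom2[1, 2])
  # invariance to gene (and sample) reordering
  p <- sample(50)
  expect_equal(tomSimilarity(a[p, p]), tom[p, p], tolerance = 1e-12)
})

test_that("soft threshold selection reports a decreasing mean connectivity", {
  set.seed(35)
  expr <- matrix(rnorm(600), 60, 10, dimnames = list(paste0("g", 1:60), NULL))
  st <- pickSoftThreshold(expr, powers = c(1, 2, 4, 6, 8))
  expect_true(all(diff(st$table$mean_connectivity) < 0))
  # pure noise never reaches the fit cutoff: sample-size fallback applies
  expect_equal(st$power, 16)           # 10 samples -> n < 20 bracket
  # constructed power-law degrees give a high fit index
  set.seed(36)
  k <- (1:500)^(-1.5) * 3000
  fit <- agingnet:::sft_fit(k, nBins = 10)
  expect_gt(fit["rsq"], 0.95)
  expect_lt(fit["slope"], 0)
})

test_that("module detection recovers planted equicorrelated blocks", {
  skip_if_not_installed("mclust")
  set.seed(37)
  n <- 40
  block <- function(sz, rho) {
    f <- rnorm(n)
    t(sapply(seq_len(sz), function(i) sqrt(rho) * f + sqrt(1 - rho) * rnorm(n)))
  }
  expr <- rbind(block(100, 0.8), block(100, 0.8), block(100, 0.8),
                matrix(rnorm(200 * n), 200, n))
  rownames(expr) <- paste0("g", seq_len(nrow(expr)))
  truth <- rep(c("b1", "b2", "b3", "noise"), c(100, 100, 100, 200))
  net <- buildNetwork(expr, beta = 6)
  mods <- detectModules(net, expr, minSize = 50, deepSplit = 2,
                        mergeHeight = 0.15)
  lab <- moduleLabels(mods)
  blocks <- truth != "noise"
  expect_gte(mclust::adjustedRandIndex(lab[blocks], truth[blocks]), 0.8)
  expect_gt(mean(lab[!blocks] == "grey"), 0.5)
  expect_equal(length(lab), nrow(expr))
})

test_that("modules with correlated eigengenes merge below the merge height", {
  set.seed(38)
  n <- 30
  f <- rnorm(n)
  # two blocks driven by almost the same factor: eigengene cor > 0.9
  b1 <- t(sapply(1:60, function(i) f + rnorm(n, sd = 0.3)))
  f2 <- 0.97 * f + sqrt(1 - 0.97^2) * rnorm(n)
  b2 <- t(sapply(1:60, function(i) f2 + rnorm(n, sd = 0.3)))
  other <- t(sapply(1:60, function(i) rnorm(n)))
  expr <- rbind(b1, b2, other)
  rownames(expr) <- paste0("g", 1:180)
  net <- buildNetwork(expr, beta = 6)
  mods <- detectModules(net, expr, minSize = 30, deepSplit = 3,
                        mergeHeight = 0.15)
  lab <- moduleLabels(mods)
  # the two driven blocks end in one module
  expect_equal(length(unique(lab[1:120])), 1)
})

test_that("module eigengenes match an SVD oracle and are sign-oriented", {
  set.seed(39)
  prof <- rnorm(20)
  m <- t(sapply(1:10, function(i) 2 * prof + 1))  # identical genes
  me <- moduleEigengene(m)
  zp <- (prof - mean(prof)) / sd(prof)
  expect_equal(abs(cor(me, zp)), 1, tolerance = 1e-10)
  expect_gte(cor(me, zp), 0)
  expect_equal(sum(me^2), 1)
  # SVD oracle on a random module
  m <- matrix(rnorm(200), 10, 20)
  me <- moduleEigengene(m)
  z <- t(scale(t(m)))
  v <- svd(z)$v[, 1]
  expect_equal(abs(me), abs(v), tolerance = 1e-10)
  # flipping every gene's sign leaves |cor| with any trait unchanged
  me2 <- moduleEigengene(-m)
  trait <- rnorm(20)
  expect_equal(abs(cor(me2, trait)), abs(cor(me, trait)), tolerance = 1e-10)
})

test_that("module-trait association applies the bicor t-test and strict thresholds", {
  set.seed(40)
  n <- 30
  age <- rep(seq(3, 27, 3), length.out = n)
  noise <- matrix(rnorm(n * 3), n, 3)
  labels <- setNames(rep(c("M1", "M2"), each = 50), paste0("g", 1:100))
  # M1 eigengene = scaled age; M2 eigengene = noise
  me <- cbind(M1 = (age - mean(age)) / sqrt(sum((age - mean(age))^2)),
              M2 = noise[, 1] / sqrt(sum(noise[, 1]^2)))
  mods <- new("ModuleSet", labels = labels, eigengenes = me,
              sizes = c(M1 = 50L, M2 = 50L))
  mt <- moduleTraitAssociation(mods, data.frame(age = age))
  m1 <- mt[mt$module == "M1", ]
  expect_equal(m1$bicor, 1, tolerance = 1e-6)
  expect_true(m1$selected)
  expect_false(mt$selected[mt$module == "M2"])
  # t-statistic arithmetic: r = 0.5, m = 30 -> t = 3.055, p ~ 0.0049
  r <- 0.5; m <- 30
  tstat <- r * sqrt((m - 2) / (1 - r^2))
  expect_equal(tstat, 3.0551, tolerance = 1e-4)
  expect_equal(2 * pt(-tstat, m - 2), 0.0049, tolerance = 1e-3)
  expect_error(moduleTraitAssociation(mods, data.frame(c0 = rep(1, n))),
               "constant")
})

test_that("MM/GS statistics and hub calling recover a planted construction", {
  set.seed(41)
  n <- 40
  age <- rep(seq(3, 27, 3), length.out = n)
  drv <- scale(age)[, 1] + rnorm(n, sd = 0.3)     # age-driven module factor
  lam <- runif(60, 0.2, 2)
  expr <- t(sapply(lam, function(l) l * drv + rnorm(n)))
  rownames(expr) <- paste0("g", 1:60)
  labels <- setNames(rep("M1", 60), rownames(expr))
  me <- drv / sqrt(sum(drv^2))
  mods <- new("ModuleSet", labels = labels,
              eigengenes = matrix(me, n, 1, dimnames = list(NULL, "M1")),
              sizes = c(M1 = 60L))
  st <- geneModuleStats(expr, mods, age)
  expect_gt(st$modules$mmgs_r, 0.5)
  expect_true(st$modules$retained)
  # GS of a trait-uncorrelated gene is near zero
  g0 <- geneModuleStats(rbind(expr, null = rnorm(n)),
                        new("ModuleSet",
                            labels = c(labels, null = "grey"),
                            eigengenes = mods@eigengenes,
                            sizes = c(M1 = 60L, grey = 1L)), age)
  expect_lt(g0$genes$gs[g0$genes$gene_id == "null"], 0.35)
  # hub thresholds are strict
  fake <- list(genes = data.frame(gene_id = c("a", "b", "c"),
                                  module = "M1",
                                  mm = c(0.9, 0.8, 0.85),
                                  gs = c(0.3, 0.3, 0.2)))
  expect_equal(hubGenes(fake, 0.2, 0.8)$M1, "a")
  # high-loading genes are the hubs in the construction
  hubs <- hubGenes(st, 0.2, 0.8)$M1
  expect_gt(mean(lam[match(hubs, rownames(expr))]), mean(lam))
})
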