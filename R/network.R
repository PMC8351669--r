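#' Biweight midcorrelation matrix
#'
#' Robust correlation between genes: for each gene `x`,
#' `u_i = (x_i - med(x)) / (9 MAD(x))` (MAD unscaled), weights
#' `w_i = (1 - u_i^2)^2 I(|u_i| < 1)`, `xt_i = (x_i - med(x)) w_i`, and
#' `bicor(x, y) = sum(xt yt) / (||xt|| ||yt||)`. Genes with zero MAD fall
#' back to their Pearson (mean-centred) vector for every pair they enter.
#' Genes constant across samples are excluded with a warning.
#'
#' @param expr Expression matrix, genes x samples (at least 3 samples).
#' @return Symmetric correlation matrix with unit diagonal over the
#'   retained genes.
#' @export
bicorMatrix <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3) stop("need at least 3 samples")
  keep <- rowVars_(expr) > 0
  if (!all(keep)) {
    warning(sum(!keep), " constant gene(s) excluded from the correlation matrix")
    expr <- expr[keep, , drop = FALSE]
  }
  Z <- t(apply(expr, 1, bicor_vector))
  # normalized rows: crossprod gives the correlation directly
  r <- tcrossprod(Z)
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- list(rownames(expr), rownames(expr))
  r
}

# One gene's weighted, centred, unit-norm profile (Pearson fallback on MAD=0).
bicor_vector <- function(x) {
  med <- stats::median(x)
  madx <- stats::median(abs(x - med))
  if (madx == 0) {
    xt <- x - mean(x)
  } else {
    u <- (x - med) / (9 * madx)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    xt <- (x - med) * w
  }
  xt / sqrt(sum(xt^2))
}

#' Biweight midcorrelation of two vectors
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return The bicor value in `[-1, 1]`.
#' @export
bicor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  min(1, max(-1, sum(bicor_vector(x) * bicor_vector(y))))
}

#' Signed soft-threshold adjacency
#'
#' `A_ij = ((1 + r_ij)/2)^beta`, unit diagonal.
#'
#' @param cor Symmetric correlation matrix.
#' @param beta Soft power (>= 1).
#' @return Adjacency matrix in `[0, 1]`.
#' @export
adjacencySigned <- function(cor, beta) {
  stopifnot(beta >= 1)
  a <- ((1 + cor) / 2)^beta
  diag(a) <- 1
  a
}

#' Scale-free topology fit across candidate soft powers
#'
#' For each power, builds the signed adjacency, computes connectivities
#' `k_i`, bins `log10(k)` into ~`nBins` bins and regresses `log10` bin
#' frequency on `log10` mean bin connectivity. The fit index is the R
#' squared of that regression (reported with the slope); the chosen power
#' is the smallest whose index reaches `rsqCut` with negative slope, else a
#' sample-size fallback (`n < 20`: 16, `20-29`: 14, `30-39`: 12,
#' `>= 40`: 9).
#'
#' @param expr Expression matrix, genes x samples.
#' @param powers Candidate integer powers.
#' @param rsqCut Fit index required to accept a power (default 0.8).
#' @param nBins Histogram bins for the degree distribution.
#' @param cor Optional precomputed correlation matrix (else [bicorMatrix()]).
#' @return List with `table` (power, fit_index, slope, mean_connectivity)
#'   and `power`, the chosen soft power.
#' @export
pickSoftThreshold <- function(expr, powers = c(1:10, 12, 14, 16, 18, 20),
                              rsqCut = 0.8, nBins = 10, cor = NULL) {
  stopifnot(all(powers >= 1))
  if (is.null(cor)) cor <- bicorMatrix(expr)
  rows <- lapply(powers, function(b) {
    a <- adjacencySigned(cor, b)
    k <- colSums(a) - 1
    data.frame(power = b, fit_index = sft_fit(k, nBins)["rsq"],
               slope = sft_fit(k, nBins)["slope"], mean_connectivity = mean(k))
  })
  tab <- do.call(rbind, rows); rownames(tab) <- NULL
  ok <- !is.na(tab$fit_index) & tab$fit_index >= rsqCut & tab$slope < 0
  power <- if (any(ok)) min(tab$power[ok]) else {
    n <- ncol(expr)
    if (n < 20) 16 else if (n < 30) 14 else if (n < 40) 12 else 9
  }
  list(table = tab, power = power)
}

sft_fit <- function(k, nBins) {
  k <- k[k > 0]
  br <- seq(min(log10(k)), max(log10(k)), length.out = nBins + 1)
  br[1] <- br[1] - 1e-9
  bin <- cut(log10(k), br)
  freq <- tapply(k, bin, length)
  mk <- tapply(k, bin, mean)
  use <- !is.na(freq) & freq > 0
  if (sum(use) < 3) return(c(rsq = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(freq[use]) ~ log10(mk[use]))
  c(rsq = summary(fit)$r.squared, slope = unname(stats::coef(fit)[2]))
}

#' Topological overlap matrix
#'
#' With `k_i = sum_{u != i} a_iu` and `L_ij = sum_{u != i,j} a_iu a_uj`:
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)`, `TOM_ii = 1`.
#'
#' @param adjacency Symmetric adjacency in `[0, 1]`.
#' @return TOM matrix in `[0, 1]`, unit diagonal; `1 - TOM` is the
#'   clustering dissimilarity.
#' @export
tomSimilarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  diag(a) <- 0
  k <- colSums(a)
  L <- a %*% a                      # zero diagonal removes the u = i, j terms
  kmin <- outer(k, k, pmin)
  tom <- (L + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Build a signed weighted network
#'
#' Convenience wrapper: bicor, signed adjacency at `beta` (auto-selected by
#' [pickSoftThreshold()] when `"auto"`), and TOM.
#'
#' @param expr Expression matrix, genes x samples.
#' @param beta Soft power or `"auto"`.
#' @return A [GeneNetwork] object.
#' @export
buildNetwork <- function(expr, beta = "auto") {
  cor <- bicorMatrix(expr)
  if (identical(beta, "auto")) beta <- pickSoftThreshold(expr, cor = cor)$power
  a <- adjacencySigned(cor, beta)
  tom <- tomSimilarity(a)
  methods::new("GeneNetwork", beta = as.numeric(beta), adjacency = a, tom = tom,
               connectivity = colSums(a) - 1)
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, a static tree cut
#' whose height is a `deepSplit`-dependent fraction of the dendrogram's
#' maximum merge height (presets `0:0.80, 1:0.85, 2:0.90, 3:0.95, 4:0.99`;
#' larger values split more finely), a minimum module size below which
#' genes fall into `"grey"`, and iterative merging of modules whose
#' eigengene dissimilarity `1 - cor(ME_a, ME_b)` is below `mergeHeight`.
#' Final labels are `"M1", "M2", ...` in decreasing size order.
#'
#' @param network A [GeneNetwork] (or a TOM matrix).
#' @param expr Expression matrix, genes x samples, used for eigengenes.
#' @param minSize Minimum module size (default 50).
#' @param deepSplit Split sensitivity preset 0-4 (default 2).
#' @param mergeHeight Eigengene dissimilarity below which modules merge
#'   (default 0.15).
#' @return A [ModuleSet].
#' @export
detectModules <- function(network, expr, minSize = 50, deepSplit = 2,
                          mergeHeight = 0.15) {
  tom <- if (methods::is(network, "GeneNetwork")) tomMatrix(network) else as.matrix(network)
  stopifnot(minSize >= 2, deepSplit %in% 0:4)
  diss <- 1 - tom
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  presets <- c(`0` = 0.80, `1` = 0.85, `2` = 0.90, `3` = 0.95, `4` = 0.99)
  h <- presets[[as.character(deepSplit)]] * max(hc$height)
  raw <- stats::cutree(hc, h = h)
  labels <- as.character(raw)
  small <- names(table(labels))[table(labels) < minSize]
  labels[labels %in% small] <- "grey"
  names(labels) <- rownames(tom)

  labels <- merge_close_modules(labels, expr, mergeHeight)
  # size-ordered final names
  mods <- setdiff(names(sort(table(labels[labels != "grey"]), decreasing = TRUE)), "grey")
  newname <- stats::setNames(paste0("M", seq_along(mods)), mods)
  labels[labels != "grey"] <- newname[labels[labels != "grey"]]
  me <- eigengene_matrix(expr, labels)
  sizes <- table(labels)
  methods::new("ModuleSet", labels = labels, eigengenes = me,
               sizes = stats::setNames(as.integer(sizes), names(sizes)))
}

merge_close_modules <- function(labels, expr, mergeHeight) {
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2) break
    me <- eigengene_matrix(expr, labels)
    d <- 1 - stats::cor(me)
    diag(d) <- Inf
    if (min(d) >= mergeHeight) break
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    a <- colnames(d)[ij[1]]; b <- colnames(d)[ij[2]]
    labels[labels == b] <- a
  }
  labels
}

eigengene_matrix <- function(expr, labels) {
  mods <- setdiff(unique(labels), "grey")
  me <- sapply(mods, function(m)
    module_eigengene(expr[names(labels)[labels == m], , drop = FALSE]))
  if (!length(mods)) me <- matrix(0, ncol(expr), 0)
  me <- matrix(me, nrow = ncol(expr), dimnames = list(colnames(expr), mods))
  me
}

#' Module eigengene
#'
#' First right singular vector over samples of the module's gene-wise
#' z-scored expression, unit norm, sign-oriented so that it correlates
#' non-negatively with the module's mean z-profile.
#'
#' @param expr Expression matrix of the module's genes (genes x samples).
#' @return Numeric vector, one value per sample, unit norm.
#' @export
moduleEigengene <- function(expr) module_eigengene(as.matrix(expr))

module_eigengene <- function(m) {
  z <- t(scale(t(m)))
  z[!is.finite(z)] <- 0
  if (nrow(z) == 1) {
    v <- z[1, ]
  } else {
    v <- svd(z, nu = 0, nv = 1)$v[, 1]
  }
  prof <- colMeans(z)
  if (sum(v * prof) < 0) v <- -v
  v / sqrt(sum(v^2))
}

#' Module-trait association
#'
#' Bicor between each module eigengene and each trait, p-values from the
#' Student-t approximation `t = r sqrt((m - 2)/(1 - r^2))`, BH FDR across
#' modules within each trait. A module is selected for a trait when
#' `|r| >= rMin` and `FDR < alpha`.
#'
#' @param modules A [ModuleSet].
#' @param traits data.frame or matrix of numeric traits over samples (e.g.
#'   `age_months`, `sex_code`), rows aligned with the eigengene samples.
#' @param rMin Minimum absolute correlation (default 0.5).
#' @param alpha FDR threshold (default 0.05).
#' @return data.frame with `module`, `trait`, `bicor`, `p`, `fdr`,
#'   `selected`.
#' @export
moduleTraitAssociation <- function(modules, traits, rMin = 0.5, alpha = 0.05) {
  me <- moduleEigengenes(modules)
  traits <- as.data.frame(traits)
  empty <- data.frame(module = character(), trait = character(),
                      bicor = numeric(), p = numeric(), fdr = numeric(),
                      selected = logical())
  if (ncol(me) == 0) return(empty)
  m <- nrow(me)
  out <- list()
  for (tr in colnames(traits)) {
    tv <- traits[[tr]]
    if (stats::sd(tv) == 0) stop("trait '", tr, "' is constant; association undefined")
    r <- vapply(colnames(me), function(mod) bicor(me[, mod], tv), numeric(1))
    tt <- r * sqrt((m - 2) / pmax(1 - r^2, 1e-300))
    p <- 2 * stats::pt(-abs(tt), df = m - 2)
    fdr <- stats::p.adjust(p, method = "BH")
    out[[tr]] <- data.frame(module = colnames(me), trait = tr, bicor = r,
                            p = p, fdr = fdr,
                            selected = abs(r) >= rMin & fdr < alpha,
                            row.names = NULL)
  }
  do.call(rbind, out)
}

#' Module membership and gene significance
#'
#' `MM_g` is the (signed) Pearson correlation of gene `g` with its module's
#' eigengene; `GS_g` the absolute correlation with the trait. Per module,
#' the correlation of `|MM|` with `GS` and its p-value decide whether the
#' module is retained (`>= mmgsMin` and `p < mmgsAlpha`).
#'
#' @param expr Expression matrix, genes x samples.
#' @param modules A [ModuleSet].
#' @param trait Numeric trait over samples.
#' @param mmgsMin Minimum MM-GS correlation (default 0.5).
#' @param mmgsAlpha p-value threshold for the MM-GS correlation (default
#'   0.05).
#' @return List with `genes` (data.frame: `gene_id`, `module`, `mm`, `gs`)
#'   and `modules` (data.frame: `module`, `mmgs_r`, `mmgs_p`, `retained`).
#' @export
geneModuleStats <- function(expr, modules, trait, mmgsMin = 0.5,
                            mmgsAlpha = 0.05) {
  expr <- as.matrix(expr)
  labels <- moduleLabels(modules)
  me <- moduleEigengenes(modules)
  stopifnot(all(names(labels) %in% rownames(expr)))
  mm <- gs <- rep(NA_real_, length(labels))
  names(mm) <- names(gs) <- names(labels)
  for (g in names(labels)) {
    gs[g] <- abs(stats::cor(expr[g, ], trait))
    if (labels[g] != "grey") mm[g] <- stats::cor(expr[g, ], me[, labels[g]])
  }
  mods <- colnames(me)
  modtab <- lapply(mods, function(m) {
    idx <- names(labels)[labels == m]
    if (length(idx) < 3) {
      warning("module ", m, " has fewer than 3 genes; MM-GS correlation undefined")
      return(data.frame(module = m, mmgs_r = NA_real_, mmgs_p = NA_real_,
                        retained = FALSE))
    }
    ct <- stats::cor.test(abs(mm[idx]), gs[idx])
    data.frame(module = m, mmgs_r = unname(ct$estimate), mmgs_p = ct$p.value,
               retained = ct$estimate >= mmgsMin & ct$p.value < mmgsAlpha)
  })
  modules_df <- if (length(modtab)) do.call(rbind, modtab) else
    data.frame(module = character(), mmgs_r = numeric(), mmgs_p = numeric(),
               retained = logical())
  list(genes = data.frame(gene_id = names(labels), module = unname(labels),
                          mm = unname(mm), gs = unname(gs), row.names = NULL),
       modules = modules_df)
}

#' Intramodular hub genes
#'
#' Genes with gene significance strictly above `gsMin` (default 0.2) and
#' module membership strictly above `mmMin` (default 0.8), per module.
#'
#' @param stats Output of [geneModuleStats()].
#' @param gsMin,mmMin Thresholds on GS and MM.
#' @param modules Optional module names to restrict to (e.g. the selected
#'   ones); defaults to all non-grey modules.
#' @return Named list of hub gene id vectors, one per module.
#' @export
hubGenes <- function(stats, gsMin = 0.2, mmMin = 0.8, modules = NULL) {
  g <- stats$genes
  if (is.null(modules)) modules <- setdiff(unique(g$module), "grey")
  out <- lapply(modules, function(m) {
    sub <- g[g$module == m & !is.na(g$mm), , drop = FALSE]
    sub$gene_id[sub$gs > gsMin & sub$mm > mmMin]
  })
  stats::setNames(out, modules)
}
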