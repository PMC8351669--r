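#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData assay<-
NULL

#' Per-gene segmented regression fits
#'
#' Container for the breakpoint models selected per gene by
#' [fitSegmentedMatrix()]. One row per gene; list columns hold the
#' variable-length breakpoint and segment vectors.
#'
#' @slot fits A [S4Vectors::DataFrame] with columns `gene_id`, `k`,
#'   `breakpoints` (list of numeric, months), `slopes` (list, k+1 segment
#'   slopes in expression units per month), `slope_pvalues` (list),
#'   `directions` (list of `"up"`/`"down"`/`"flat"`), `sex_coef`, `adj_r2`,
#'   `bic`, `rss`.
#' @slot ages Numeric vector of the per-sample ages the models were fit
#'   against (months).
#' @slot maxK Integer, largest breakpoint count searched.
#' @slot slopeAlpha Significance level below which a segment slope is called
#'   non-flat.
#'
#' @seealso [fitSegmented()], [selectTopDynamic()], [summarizeBreakpoints()]
#' @export
setClass("SegmentedFits",
  slots = c(fits = "DataFrame", ages = "numeric", maxK = "integer",
            slopeAlpha = "numeric"))

setValidity("SegmentedFits", function(object) {
  f <- object@fits
  need <- c("gene_id", "k", "breakpoints", "slopes", "slope_pvalues",
            "directions", "sex_coef", "adj_r2", "bic", "rss")
  if (!all(need %in% colnames(f)))
    return(paste("missing columns:", paste(setdiff(need, colnames(f)), collapse = ", ")))
  if (anyDuplicated(f$gene_id)) return("duplicated gene_id")
  if (any(f$adj_r2 > 1 + 1e-12, na.rm = TRUE)) return("adj_r2 > 1")
  for (i in seq_len(nrow(f))) {
    bp <- f$breakpoints[[i]]
    if (length(bp) != f$k[i]) return("k does not match breakpoint count")
    if (length(f$slopes[[i]]) != f$k[i] + 1L) return("need k+1 segment slopes")
    if (is.unsorted(bp, strictly = TRUE)) return("breakpoints not strictly increasing")
    if (length(bp) && (min(bp) <= min(object@ages) || max(bp) >= max(object@ages)))
      return("breakpoints must be interior to the observed time range")
  }
  TRUE
})

#' Weighted signed co-expression network
#'
#' Adjacency and topological overlap for a set of genes, as produced by
#' [buildNetwork()] from a biweight midcorrelation matrix.
#'
#' @slot beta Soft-thresholding power applied to the scaled correlation.
#' @slot adjacency Symmetric matrix in `[0,1]`, `((1+r)/2)^beta`, unit
#'   diagonal.
#' @slot tom Topological overlap matrix in `[0,1]`, unit diagonal.
#' @slot connectivity Per-gene connectivity `k_i = sum_{j != i} a_ij`.
#'
#' @export
setClass("GeneNetwork",
  slots = c(beta = "numeric", adjacency = "matrix", tom = "matrix",
            connectivity = "numeric"))

setValidity("GeneNetwork", function(object) {
  a <- object@adjacency; tm <- object@tom
  if (!isTRUE(all.equal(a, t(a), tolerance = 1e-10))) return("adjacency not symmetric")
  if (!isTRUE(all.equal(tm, t(tm), tolerance = 1e-10))) return("TOM not symmetric")
  if (any(a < -1e-12) || any(a > 1 + 1e-12)) return("adjacency outside [0,1]")
  if (any(tm < -1e-10) || any(tm > 1 + 1e-10)) return("TOM outside [0,1]")
  if (max(abs(diag(tm) - 1)) > 1e-10) return("TOM diagonal must be 1")
  if (length(object@connectivity) != nrow(a)) return("connectivity length mismatch")
  TRUE
})

#' Co-expression modules and their eigengenes
#'
#' Gene-to-module assignment from [detectModules()]. The reserved label
#' `"grey"` holds unassigned genes; all other modules satisfy the minimum
#' size used at detection time.
#'
#' @slot labels Named character vector, one module label per gene.
#' @slot eigengenes Numeric matrix, samples x modules (unit-norm columns),
#'   excluding grey.
#' @slot sizes Named integer vector of module sizes (including grey).
#'
#' @export
setClass("ModuleSet",
  slots = c(labels = "character", eigengenes = "matrix", sizes = "integer"))

setValidity("ModuleSet", function(object) {
  if (is.null(names(object@labels))) return("labels must be named by gene")
  mods <- setdiff(unique(object@labels), "grey")
  if (length(mods) && !all(mods %in% colnames(object@eigengenes)))
    return("every non-grey module needs an eigengene column")
  if (ncol(object@eigengenes)) {
    nrm <- sqrt(colSums(object@eigengenes^2))
    if (any(abs(nrm - 1) > 1e-8)) return("eigengenes must be unit norm")
  }
  tab <- table(object@labels)
  if (!all(names(tab) %in% names(object@sizes))) return("sizes missing a module")
  TRUE
})

#' Term-similarity graph of enriched gene sets
#'
#' Nodes are enriched terms, edges connect pairs whose gene-set similarity
#' reaches the construction cutoff; `cluster` is filled by [mclCluster()].
#'
#' @slot nodes data.frame with `term_id`, `name`, `fdr` and (after
#'   clustering) `cluster`.
#' @slot edges data.frame with `from`, `to`, `similarity`; undirected, no
#'   self edges.
#' @slot cutoff Similarity cutoff used at construction.
#' @slot metric Similarity metric (`"overlap"`, `"jaccard"` or
#'   `"combined"`).
#'
#' @export
setClass("TermGraph",
  slots = c(nodes = "data.frame", edges = "data.frame", cutoff = "numeric",
            metric = "character"))

setValidity("TermGraph", function(object) {
  e <- object@edges
  if (nrow(e)) {
    if (any(as.character(e$from) == as.character(e$to)))
      return("self edges are not allowed")
    if (any(e$similarity < object@cutoff - 1e-12)) return("edge below cutoff")
    if (any(e$similarity > 1 + 1e-12)) return("similarity > 1")
    if (!all(c(as.character(e$from), as.character(e$to)) %in%
             object@nodes$term_id))
      return("edge endpoint not among nodes")
  }
  TRUE
})

#' @describeIn SegmentedFits Number of genes fitted.
#' @param x,object A `SegmentedFits` object.
#' @export
setMethod("length", "SegmentedFits", function(x) nrow(x@fits))

setMethod("show", "SegmentedFits", function(object) {
  f <- object@fits
  cat("SegmentedFits with", nrow(f), "genes over ages",
      paste(range(object@ages), collapse = "-"), "months\n")
  cat("  maxK:", object@maxK, " slope alpha:", object@slopeAlpha, "\n")
  if (nrow(f)) {
    kt <- table(factor(f$k, levels = 0:object@maxK))
    cat("  genes per k:", paste(sprintf("%s:%d", names(kt), kt), collapse = " "), "\n")
    cat("  adj R2: median", signif(stats::median(f$adj_r2), 3),
        "max", signif(max(f$adj_r2), 3), "\n")
  }
})

setMethod("show", "GeneNetwork", function(object) {
  cat("GeneNetwork of", nrow(object@adjacency), "genes, beta =", object@beta, "\n")
  cat("  mean connectivity:", signif(mean(object@connectivity), 4), "\n")
})

setMethod("show", "ModuleSet", function(object) {
  mods <- setdiff(names(object@sizes), "grey")
  cat("ModuleSet:", length(mods), "modules over", length(object@labels), "genes",
      sprintf("(grey: %d)\n", sum(object@labels == "grey")))
  if (length(mods))
    cat(" ", paste(sprintf("%s:%d", mods, object@sizes[mods]), collapse = " "), "\n")
})

setMethod("show", "TermGraph", function(object) {
  cat("TermGraph:", nrow(object@nodes), "terms,", nrow(object@edges),
      sprintf("edges (similarity >= %g, %s)\n", object@cutoff, object@metric))
  if (!is.null(object@nodes$cluster))
    cat("  clusters:", length(unique(object@nodes$cluster)), "\n")
})

#' Accessors for network and module objects
#'
#' @param object A `GeneNetwork`, `ModuleSet` or `SegmentedFits`.
#' @return `adjacencyMatrix` and `tomMatrix` return symmetric matrices;
#'   `moduleLabels` a named character vector; `moduleEigengenes` the
#'   samples x modules eigengene matrix; `fitTable` the per-gene fit
#'   DataFrame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("adjacencyMatrix", function(object) standardGeneric("adjacencyMatrix"))
#' @rdname accessors
#' @export
setMethod("adjacencyMatrix", "GeneNetwork", function(object) object@adjacency)

#' @rdname accessors
#' @export
setGeneric("tomMatrix", function(object) standardGeneric("tomMatrix"))
#' @rdname accessors
#' @export
setMethod("tomMatrix", "GeneNetwork", function(object) object@tom)

#' @rdname accessors
#' @export
setGeneric("moduleLabels", function(object) standardGeneric("moduleLabels"))
#' @rdname accessors
#' @export
setMethod("moduleLabels", "ModuleSet", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("moduleEigengenes", function(object) standardGeneric("moduleEigengenes"))
#' @rdname accessors
#' @export
setMethod("moduleEigengenes", "ModuleSet", function(object) object@eigengenes)

#' @rdname accessors
#' @export
setGeneric("fitTable", function(object) standardGeneric("fitTable"))
#' @rdname accessors
#' @export
setMethod("fitTable", "SegmentedFits", function(object) object@fits)
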