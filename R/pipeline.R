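#' Pipeline parameter set
#'
#' Every named threshold of the analysis in one list: library-depth filter
#' 4e6 reads, z.K outlier threshold 2 SD, low-count filter (count > 10 in
#' at least the minimum group size of samples), segmented-regression maxK 8
#' with the permutation-calibrated ("auto") adjusted R-squared cutoff and
#' segment slope alpha 0.1, soft power "auto", module minimum size 50,
#' merge height 0.15, deepsplit 2, module-trait selection |bicor| >= 0.5 at
#' FDR < 0.05, MM-GS retention 0.5 at p < 0.05, hub thresholds GS > 0.2 and
#' MM > 0.8, ORA set sizes 10-500 at FDR < 0.05, and enrichment-map edge
#' cutoff 0.7 with MCL inflation 2.
#'
#' @param ... Overrides for any default.
#' @return Named list of parameters.
#' @export
pipelineParams <- function(...) {
  p <- list(
    minReads = 4e6, sdThreshold = 2, minCount = 10, minSamples = NULL,
    maxK = 8L, minPerSegment = NULL, cutoff = "auto", nPerm = 10L,
    passFraction = 0.01, slopeAlpha = 0.1,
    beta = "auto", minModuleSize = 50, mergeHeight = 0.15, deepSplit = 2,
    rMin = 0.5, fdrAlpha = 0.05, mmgsMin = 0.5, mmgsAlpha = 0.05,
    hubGs = 0.2, hubMm = 0.8,
    oraMinSize = 10, oraMaxSize = 500, oraAlpha = 0.05,
    mapCutoff = 0.7, mapMetric = "overlap", inflation = 2,
    sexModules = "trended")   # "trended": include sex modules flagged in trendedSexModules
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  p
}

#' Run the full per-tissue analysis
#'
#' Executes, on one tissue, the complete sequence: pre-processing (depth
#' filter, low-count filter, size factors, VST, sample-network outlier
#' removal), segmented regression with BIC breakpoint selection and a
#' permutation-calibrated adjusted R-squared cutoff, signed bicor/TOM
#' network construction and module detection, module-trait association and
#' MM/GS hub calling, intersection of the Trendy and hub gene sets,
#' GO over-representation analysis against the expressed-gene universe, and
#' enrichment-map construction with MCL clustering and meta-node collapse.
#' All stages are deterministic given `seed`.
#'
#' @param se A `SummarizedExperiment` with a `"counts"` assay and colData
#'   columns `tissue`, `age_months`, `sex_code`.
#' @param sets Named list of gene sets (see [readGMT()]).
#' @param tissue Tissue to analyse (defaults to the first in `colData`).
#' @param params A [pipelineParams()] list.
#' @param seed Integer seed for the permutation procedure.
#' @param outDir Optional directory; when given, all stage tables plus
#'   `summary.json` are written there.
#' @param trendedSexModules Names of sex-associated modules judged to have
#'   a discernible time trend; only those enter the integration (an
#'   explicit analyst decision, not automated).
#' @return List with all stage results (`qc`, `fits`, `dynamic`,
#'   `breakpoints`, `network`, `modules`, `moduleTrait`, `stats`, `hubs`,
#'   `overlap`, `enrichment`, `map`, `summary`).
#' @export
runTissuePipeline <- function(se, sets, tissue = NULL,
                              params = pipelineParams(), seed = 1,
                              outDir = NULL, trendedSexModules = character(0)) {
  cd <- SummarizedExperiment::colData(se)
  if (is.null(tissue)) tissue <- as.character(cd$tissue[1])
  se <- se[, cd$tissue == tissue]
  if (ncol(se) == 0) stop("tissue not present: ", tissue)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- preprocess ---------------------------------------------------------
  grp <- table(paste(se$age_months, se$sex_code))
  minGroup <- max(1L, min(grp))
  if (is.null(params$minSamples)) params$minSamples <- minGroup
  if (is.null(params$minPerSegment)) params$minPerSegment <- max(2L, minGroup)
  pp <- stage("preprocess", preprocessCounts(
    se, minReads = params$minReads, minCount = params$minCount,
    minSamples = params$minSamples, sdThreshold = params$sdThreshold))
  sef <- pp$se
  expr <- SummarizedExperiment::assay(sef, "vst")
  t <- sef$age_months; sex <- sef$sex_code
  universe <- rownames(sef)

  # --- trendy -------------------------------------------------------------
  fits <- stage("trendy", fitSegmentedMatrix(
    expr, t, sex, maxK = params$maxK, minPerSegment = params$minPerSegment,
    slopeAlpha = params$slopeAlpha))
  if (identical(params$cutoff, "auto")) {
    pc <- stage("trendy", permutationR2Cutoff(
      expr, t, sex, nPerm = params$nPerm, passFraction = params$passFraction,
      maxK = params$maxK, minPerSegment = params$minPerSegment, seed = seed))
    cutoff <- pc$cutoff
  } else cutoff <- params$cutoff
  dyn <- selectTopDynamic(fits, cutoff, params$slopeAlpha)
  trendyGenes <- dyn$calls$gene_id[dyn$calls$is_top_dynamic]
  bks <- summarizeBreakpoints(fits, trendyGenes)

  # --- network ------------------------------------------------------------
  net <- stage("network", buildNetwork(expr, beta = params$beta))
  netGenes <- rownames(adjacencyMatrix(net))
  modules <- stage("network", detectModules(
    net, expr[netGenes, , drop = FALSE], minSize = params$minModuleSize,
    deepSplit = params$deepSplit, mergeHeight = params$mergeHeight))
  traits <- data.frame(age = t, sex = sex)
  mt <- moduleTraitAssociation(modules, traits, params$rMin, params$fdrAlpha)

  selectedFor <- function(trn) mt$module[mt$trait == trn & mt$selected]
  stats_by_trait <- list(
    age = geneModuleStats(expr[netGenes, , drop = FALSE], modules, t,
                          params$mmgsMin, params$mmgsAlpha),
    sex = geneModuleStats(expr[netGenes, , drop = FALSE], modules, sex,
                          params$mmgsMin, params$mmgsAlpha))
  retained <- lapply(names(stats_by_trait), function(trn) {
    st <- stats_by_trait[[trn]]$modules
    intersect(selectedFor(trn), st$module[st$retained])
  })
  names(retained) <- names(stats_by_trait)
  useSex <- if (identical(params$sexModules, "trended"))
    intersect(retained$sex, trendedSexModules) else retained$sex
  analysisModules <- c(stats::setNames(retained$age, retained$age),
                       stats::setNames(useSex, useSex))
  traitOf <- c(stats::setNames(rep("age", length(retained$age)), retained$age),
               stats::setNames(rep("sex", length(useSex)), useSex))

  hubs <- lapply(names(analysisModules), function(m)
    hubGenes(stats_by_trait[[traitOf[m]]], params$hubGs, params$hubMm, m)[[m]])
  names(hubs) <- names(analysisModules)

  # --- integrate ----------------------------------------------------------
  labels <- moduleLabels(modules)
  overlaps <- lapply(names(analysisModules), function(m)
    intersectGeneSets(trendyGenes, names(labels)[labels == m], hubs[[m]]))
  names(overlaps) <- names(analysisModules)
  signature <- unique(unlist(lapply(overlaps, `[[`, "signature")))

  # --- enrich + map -------------------------------------------------------
  enr <- stage("enrich", ora(signature, universe, sets,
                             params$oraMinSize, params$oraMaxSize,
                             params$oraAlpha))
  sig <- enr[enr$significant, , drop = FALSE]
  map <- NULL
  if (nrow(sig) > 0) {
    tg <- stage("enrichmap", buildTermGraph(sig, sets, universe,
                                            params$mapCutoff,
                                            params$mapMetric))
    tg <- mclCluster(tg, inflation = params$inflation)
    map <- list(graph = tg, meta = collapseToMeta(tg))
  }

  summary <- list(
    tissue = tissue, seed = seed,
    samples_in = ncol(se), samples_kept = ncol(sef),
    genes_kept = nrow(sef),
    adj_r2_cutoff = cutoff,
    n_dynamic = dyn$n_dynamic, percent_dynamic = dyn$percent,
    median_breakpoint = bks$median,
    n_modules = length(setdiff(names(modules@sizes), "grey")),
    selected_age_modules = length(retained$age),
    selected_sex_modules = length(retained$sex),
    n_hub = length(unique(unlist(hubs))),
    signature_size = length(signature),
    n_significant_terms = sum(enr$significant),
    n_meta_nodes = if (is.null(map)) 0L else nrow(map$meta$meta_nodes))

  res <- list(qc = pp$qc, se = sef, fits = fits, cutoff = cutoff,
              dynamic = dyn, breakpoints = bks, network = net,
              modules = modules, moduleTrait = mt, stats = stats_by_trait,
              retained = retained, hubs = hubs, overlap = overlaps,
              signature = signature, enrichment = enr, map = map,
              summary = summary)
  if (!is.null(outDir)) writePipelineOutputs(res, outDir)
  res
}

#' Write pipeline stage outputs
#'
#' Serializes the result of [runTissuePipeline()] as TSV/JSON files under
#' `outDir` (created if needed), including `summary.json`.
#'
#' @param res Result list from [runTissuePipeline()].
#' @param outDir Output directory.
#' @return Invisibly, the output directory.
#' @export
writePipelineOutputs <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) utils::write.table(d, file.path(outDir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(res$qc, "qc.tsv")
  f <- fitTable(res$fits)
  join <- function(col) vapply(col, function(x)
    paste(signif(as.numeric(x), 6), collapse = ","), character(1))
  wt(data.frame(gene_id = f$gene_id, k = f$k,
                breakpoints = join(f$breakpoints), slopes = join(f$slopes),
                slope_pvalues = join(f$slope_pvalues),
                directions = vapply(f$directions, paste, character(1),
                                    collapse = ","),
                sex_coef = f$sex_coef, adj_r2 = f$adj_r2, bic = f$bic),
     "trendy_fits.tsv")
  wt(res$dynamic$calls, "top_dynamic.tsv")
  jsonlite::write_json(res$breakpoints,
                       file.path(outDir, "breakpoint_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  lab <- moduleLabels(res$modules)
  wt(data.frame(gene_id = names(lab), module = unname(lab)), "modules.tsv")
  wt(res$moduleTrait, "module_trait.tsv")
  hub_df <- if (length(res$hubs))
    data.frame(module = rep(names(res$hubs), lengths(res$hubs)),
               gene_id = unlist(res$hubs), row.names = NULL)
  else data.frame(module = character(), gene_id = character())
  wt(hub_df, "hubs.tsv")
  jsonlite::write_json(lapply(res$overlap, function(o)
    list(sizes = as.list(o$sizes), signature = o$signature)),
    file.path(outDir, "intersections.json"), auto_unbox = TRUE, pretty = TRUE)
  enr <- res$enrichment
  enr$hits <- vapply(enr$hits, paste, character(1), collapse = ",")
  wt(enr, "enrichment.tsv")
  if (!is.null(res$map)) {
    wt(res$map$graph@edges, "term_graph_edges.tsv")
    wt(res$map$graph@nodes, "clusters.tsv")
    mn <- res$map$meta$meta_nodes
    mn$members <- vapply(mn$members, paste, character(1), collapse = ",")
    wt(mn, "meta_nodes.tsv")
    wt(res$map$meta$meta_edges, "meta_edges.tsv")
  }
  jsonlite::write_json(res$summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}
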