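#' Simulation configuration
#'
#' Default study conditions for the synthetic aging time course: 9 ages
#' (3 to 27 months, step 3), 2 mice per age and sex (36 samples), 1000
#' genes split into background, piecewise-trajectory ("trendy") and
#' module-driven classes, negative-binomial counts with sample library
#' sizes drawn log-normally around 8 million reads, 2 planted shallow
#' libraries (2 million reads, below the 4-million depth filter) and 1
#' planted outlier sample whose gene labels are permuted. Module latent
#' eigengenes follow a tanh shift in age (or track sex), and a GMT of 40
#' terms carries 2 planted terms composed of 60% age-module hub genes.
#'
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @param ... Overrides for any default listed above (see the source for
#'   field names).
#' @return A list of class `"agingnet_sim_config"`.
#' @export
simulationConfig <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    ages = seq(3, 27, by = 3),
    nPerGroup = 2,                     # mice per age x sex cell
    nGenes = 1000,
    nTrendy = 120,
    modules = list(
      age = list(size = 80, trait = "age", direction = 1, shiftTime = 15,
                 nHub = 30),
      sex = list(size = 80, trait = "sex", direction = 1, shiftTime = NA,
                 nHub = 30)),
    # piecewise trajectories (natural-log scale per month)
    trendySlopeRange = c(0.15, 0.25),
    trendyK1Fraction = 0.8,            # remaining trendy genes are monotone (k = 0)
    # latent eigengene scale and loadings
    moduleAmplitude = 0.45,
    hubLoading = c(0.9, 1.3),
    nonHubLoading = c(0.4, 0.9),
    eigengeneJitter = 0.2,             # shared per-sample jitter
    geneNoiseSd = 0.1,                 # gene x sample log-scale noise
    dispersion = c(a0 = 0.05, a1 = 2),
    meanLogDepth = log(8e6), sdLogDepth = 0.1,
    nShallow = 2, shallowDepth = 2e6,
    nOutlier = 1,
    gmt = list(nTerms = 40, sizeRange = c(10, 60), nPlanted = 2,
               plantedSize = 40, plantedHubFraction = 0.6),
    tissue = "synthetic")
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  msize <- sum(vapply(cfg$modules, function(m) m$size, numeric(1)))
  if (cfg$nTrendy + msize > cfg$nGenes)
    stop("gene classes exceed the gene pool")
  structure(cfg, class = "agingnet_sim_config")
}

#' Simulate an aging time-course count dataset with planted truth
#'
#' Draws negative-binomial counts with mean
#' `mu_gs = depth_s * softmax_g(b_g + f_g(t_s) + gamma_g sex_s +
#' lambda_g e_m(s) + eps_gs)` where `f_g` is a planted piecewise-linear
#' (hinge) log-trajectory for trendy genes, `e_m` a latent module eigengene
#' trajectory (tanh shift in age, or sex-tracking), and dispersion
#' `alpha(mu) = a1/mu + a0`. Shallow libraries are planted below the depth
#' filter; outlier samples get their gene labels permuted (library size
#' preserved, correlation destroyed — exactly what the sample network
#' flags).
#'
#' @param config A [simulationConfig()].
#' @return List with `se` (a `SummarizedExperiment`: `"counts"` assay,
#'   `colData` sample table, `rowData` biotypes), `truth` (per-gene,
#'   per-sample and per-term truth tables), `sets` (the GMT as a named
#'   list) and `config`.
#' @export
simulateAgingData <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "agingnet_sim_config"))
  set.seed(config$seed)
  ages <- config$ages
  samp <- expand.grid(rep = seq_len(config$nPerGroup), sex_code = c(0L, 1L),
                      age_months = ages)
  n <- nrow(samp)
  samp$sample_id <- sprintf("S%02d_a%02d_%s%d", seq_len(n), samp$age_months,
                            c("F", "M")[samp$sex_code + 1L], samp$rep)
  samp$sex <- c("F", "M")[samp$sex_code + 1L]
  samp$tissue <- config$tissue
  t <- samp$age_months; sex <- samp$sex_code

  G <- config$nGenes
  gid <- sprintf("gene%04d", seq_len(G))
  classes <- rep("background", G)
  trendy_idx <- seq_len(config$nTrendy)
  classes[trendy_idx] <- "trendy"
  at <- config$nTrendy
  module_of <- rep(NA_character_, G); hub <- rep(FALSE, G)
  for (mn in names(config$modules)) {
    m <- config$modules[[mn]]
    idx <- at + seq_len(m$size)
    classes[idx] <- "module"; module_of[idx] <- mn
    hub[idx[seq_len(m$nHub)]] <- TRUE
    at <- at + m$size
  }

  # baseline abundance and biotypes
  b <- stats::rnorm(G, 3, 1.5)
  biotype <- sample(c("protein_coding", "lncRNA", "processed_pseudogene"), G,
                    replace = TRUE, prob = c(0.7, 0.2, 0.1))
  biotype[classes != "background"] <- "protein_coding"   # signal genes are coding

  # planted piecewise trajectories
  true_k <- rep(0L, G); true_bp <- rep(NA_real_, G)
  logmu <- matrix(rep(b, n), G, n)
  interior <- ages[-c(1, length(ages))]
  for (g in trendy_idx) {
    s1 <- sample(c(-1, 1), 1) * stats::runif(1, config$trendySlopeRange[1],
                                             config$trendySlopeRange[2])
    if (stats::runif(1) < config$trendyK1Fraction) {
      bp <- sample(interior, 1)
      s2 <- -sign(s1) * stats::runif(1, config$trendySlopeRange[1],
                                     config$trendySlopeRange[2])
      true_k[g] <- 1L; true_bp[g] <- bp
      logmu[g, ] <- logmu[g, ] + s1 * (t - min(t)) + (s2 - s1) * pmax(t - bp, 0)
    } else {
      logmu[g, ] <- logmu[g, ] + s1 * (t - min(t))
    }
  }

  # latent module eigengenes and loadings
  for (mn in names(config$modules)) {
    m <- config$modules[[mn]]
    prof <- if (m$trait == "age") {
      m$direction * tanh((t - m$shiftTime) / 3)
    } else {
      m$direction * (2 * sex - 1)
    }
    e <- config$moduleAmplitude *
      (prof + stats::rnorm(n, 0, config$eigengeneJitter))
    idx <- which(!is.na(module_of) & module_of == mn)
    lam <- numeric(length(idx))
    ih <- hub[idx]
    lam[ih] <- stats::runif(sum(ih), config$hubLoading[1], config$hubLoading[2])
    lam[!ih] <- stats::runif(sum(!ih), config$nonHubLoading[1],
                             config$nonHubLoading[2])
    logmu[idx, ] <- logmu[idx, ] + outer(lam, e)
  }

  logmu <- logmu + matrix(stats::rnorm(G * n, 0, config$geneNoiseSd), G, n)

  # library depths (planted shallow samples stay below the depth filter)
  depth <- stats::rlnorm(n, config$meanLogDepth, config$sdLogDepth)
  shallow <- rep(FALSE, n)
  if (config$nShallow > 0) {
    sh <- sample(n, config$nShallow)
    depth[sh] <- config$shallowDepth
    shallow[sh] <- TRUE
  }

  w <- exp(logmu)
  mu <- sweep(sweep(w, 2, colSums(w), "/"), 2, depth, "*")
  a0 <- config$dispersion[["a0"]]; a1 <- config$dispersion[["a1"]]
  alpha <- a1 / mu + a0
  counts <- matrix(stats::rnbinom(G * n, mu = mu, size = 1 / alpha), G, n,
                   dimnames = list(gid, samp$sample_id))

  outlier <- rep(FALSE, n)
  if (config$nOutlier > 0) {
    cand <- which(!shallow)
    ol <- sample(cand, config$nOutlier)
    for (s in ol) counts[, s] <- counts[sample(G), s]
    outlier[ol] <- TRUE
  }

  sets <- simulate_gmt(config, gid, classes, module_of, hub)
  planted <- grepl("^PLANTED", names(sets))

  annotation <- data.frame(gene_id = gid, symbol = toupper(gid),
                           biotype = biotype)
  se <- makeAgingExperiment(counts, samp[, c("sample_id", "tissue",
                                             "age_months", "sex", "sex_code")],
                            annotation)
  truth <- list(
    genes = data.frame(gene_id = gid, class = classes, true_k = true_k,
                       true_breakpoint = true_bp, module = module_of,
                       hub = hub, row.names = NULL),
    samples = data.frame(sample_id = samp$sample_id, shallow = shallow,
                         outlier = outlier, expected_depth = depth,
                         row.names = NULL),
    terms = data.frame(term_id = names(sets), planted = planted,
                       row.names = NULL))
  S4Vectors::metadata(se)$truth <- truth
  list(se = se, truth = truth, sets = sets, config = config)
}

simulate_gmt <- function(config, gid, classes, module_of, hub) {
  gc <- config$gmt
  sets <- list()
  age_hubs <- gid[!is.na(module_of) & module_of == "age" & hub]
  for (i in seq_len(gc$nPlanted)) {
    nh <- round(gc$plantedHubFraction * gc$plantedSize)
    nh <- min(nh, length(age_hubs))
    members <- c(sample(age_hubs, nh),
                 sample(gid[classes == "background"], gc$plantedSize - nh))
    sets[[sprintf("PLANTED%02d", i)]] <- unique(members)
  }
  for (i in seq_len(gc$nTerms - gc$nPlanted)) {
    sz <- sample(gc$sizeRange[1]:gc$sizeRange[2], 1)
    sets[[sprintf("TERM%03d", i)]] <- sample(gid, sz)
  }
  for (i in seq_along(sets))
    attr(sets[[i]], "description") <- paste("synthetic term", names(sets)[i])
  sets
}

#' Write a simulated dataset as plain-text fixtures
#'
#' Emits the TSV/GMT dialects consumed by the pipeline: `counts.tsv`
#' (header of sample ids, first column `gene_id`), `metadata.tsv`,
#' `annotation.tsv`, `sets.gmt`, and the truth tables
#' (`truth_genes.tsv`, `truth_samples.tsv`, `truth_terms.tsv`).
#'
#' @param dataset Output of [simulateAgingData()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written file paths.
#' @export
writeFixture <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  se <- dataset$se
  counts <- SummarizedExperiment::assay(se, "counts")
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             gmt = file.path(dir, "sets.gmt"),
             truth_genes = file.path(dir, "truth_genes.tsv"),
             truth_samples = file.path(dir, "truth_samples.tsv"),
             truth_terms = file.path(dir, "truth_terms.tsv"))
  cdf <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(cdf, paths["counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  utils::write.table(cd[, c("sample_id", "tissue", "age_months", "sex")],
                     paths["metadata"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rd <- as.data.frame(SummarizedExperiment::rowData(se))
  utils::write.table(rd[, c("gene_id", "symbol", "biotype")],
                     paths["annotation"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gmt_lines <- vapply(names(dataset$sets), function(id) {
    paste(c(id, attr(dataset$sets[[id]], "description"),
            dataset$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(gmt_lines, paths["gmt"])
  for (nm in c("genes", "samples", "terms"))
    utils::write.table(dataset$truth[[nm]], paths[paste0("truth_", nm)],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}

#' Read pipeline input fixtures
#'
#' Counterparts of [writeFixture()]: read the counts, metadata and
#' annotation TSVs into a `SummarizedExperiment`.
#'
#' @param countsPath,metadataPath,annotationPath File paths; annotation is
#'   optional.
#' @return A `SummarizedExperiment` with a `"counts"` assay.
#' @export
readCountFixture <- function(countsPath, metadataPath, annotationPath = NULL) {
  cdf <- utils::read.delim(countsPath, check.names = FALSE)
  counts <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(counts) <- cdf$gene_id
  md <- utils::read.delim(metadataPath)
  ann <- if (!is.null(annotationPath)) utils::read.delim(annotationPath)
  makeAgingExperiment(counts, md, ann)
}
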