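#' Build the term-similarity graph of enriched terms
#'
#' Nodes are enriched terms; edges connect pairs of terms whose gene-set
#' similarity reaches `cutoff` (default 0.7). Similarity metrics:
#' overlap coefficient `|A n B| / min(|A|, |B|)` (default), Jaccard
#' `|A n B| / |A u B|`, or their unweighted mean (`"combined"`). Gene sets
#' are the terms' full in-universe memberships by default
#' (`useHits = TRUE` restricts them to signature hits).
#'
#' @param rows ORA result from [ora()] (needs `term_id`, `name`, `fdr`,
#'   `hits`); typically the significant rows.
#' @param sets Named list of term member vectors (see [readGMT()]).
#' @param universe Expressed-gene universe to restrict member sets to.
#' @param cutoff Edge similarity cutoff (default 0.7).
#' @param metric `"overlap"`, `"jaccard"` or `"combined"`.
#' @param useHits Use signature-hit subsets instead of full member sets.
#' @return A [TermGraph] (unclustered).
#' @export
buildTermGraph <- function(rows, sets, universe = NULL, cutoff = 0.7,
                           metric = c("overlap", "jaccard", "combined"),
                           useHits = FALSE) {
  metric <- match.arg(metric)
  ids <- rows$term_id
  members <- if (useHits) rows$hits else lapply(sets[ids], function(m) {
    if (is.null(universe)) m else intersect(m, universe)
  })
  names(members) <- ids
  nodes <- data.frame(term_id = ids, name = rows$name, fdr = rows$fdr,
                      row.names = NULL)
  edges <- data.frame(from = character(), to = character(),
                      similarity = numeric())
  if (length(ids) > 1) {
    pr <- utils::combn(seq_along(ids), 2)
    sim <- vapply(seq_len(ncol(pr)), function(j) {
      setSimilarity(members[[pr[1, j]]], members[[pr[2, j]]], metric)
    }, numeric(1))
    keep <- sim >= cutoff
    edges <- data.frame(from = ids[pr[1, keep]], to = ids[pr[2, keep]],
                        similarity = sim[keep], row.names = NULL)
  }
  methods::new("TermGraph", nodes = nodes, edges = edges, cutoff = cutoff,
               metric = metric)
}

setSimilarity <- function(a, b, metric) {
  i <- length(intersect(a, b))
  if (i == 0) return(0)
  ov <- i / min(length(a), length(b))
  jc <- i / length(union(a, b))
  switch(metric, overlap = ov, jaccard = jc, combined = 0.5 * jc + 0.5 * ov)
}

#' Markov clustering of a term graph
#'
#' Classic MCL on the similarity-weighted graph: column-stochastic
#' transition matrix with self-loops weighted by each node's maximum
#' incident edge weight, alternating expansion (matrix squaring) and
#' inflation (elementwise power, column renormalization) with pruning of
#' entries below `pruneEps`, until the matrix changes by less than 1e-6 or
#' `maxIter` is hit (then a warning is issued and the current state is
#' interpreted). Clusters are the connected components of the attractor
#' support; singletons are allowed.
#'
#' @param graph A [TermGraph].
#' @param inflation Inflation exponent (> 1, default 2).
#' @param maxIter Iteration cap (default 100).
#' @param pruneEps Entries below this are pruned each step (default 1e-5).
#' @return The graph with `nodes$cluster` filled (integer ids, numbered by
#'   decreasing cluster size).
#' @export
mclCluster <- function(graph, inflation = 2, maxIter = 100, pruneEps = 1e-5) {
  stopifnot(inflation > 1)
  ids <- graph@nodes$term_id
  nn <- length(ids)
  W <- matrix(0, nn, nn, dimnames = list(ids, ids))
  e <- graph@edges
  if (nrow(e)) {
    W[cbind(as.character(e$from), as.character(e$to))] <- e$similarity
    W[cbind(as.character(e$to), as.character(e$from))] <- e$similarity
  }
  selfw <- apply(W, 1, max)
  selfw[selfw == 0] <- 1
  diag(W) <- selfw
  M <- sweep(W, 2, colSums(W), "/")
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    M2 <- M %*% M                         # expansion
    M2 <- M2^inflation                    # inflation
    M2[M2 < pruneEps] <- 0
    M2 <- sweep(M2, 2, pmax(colSums(M2), .Machine$double.xmin), "/")
    if (max(abs(M2 - M)) < 1e-6) { M <- M2; converged <- TRUE; break }
    M <- M2
  }
  if (!converged) warning("MCL did not converge within ", maxIter, " iterations")
  supp <- (M > 0) | (t(M) > 0)
  g <- igraph::graph_from_adjacency_matrix(supp, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  sizes <- sort(table(comp), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  graph@nodes$cluster <- unname(relab[as.character(comp)])
  graph
}

default_stopwords <- function() {
  c("a", "an", "and", "as", "at", "by", "for", "from", "in", "into", "is",
    "its", "of", "on", "or", "the", "to", "via", "with", "process")
}

#' Automatic cluster label from term-name word frequencies
#'
#' Tokenizes the member term names, drops stopwords, and greedily selects
#' up to `maxWords` words: a word's score is its occurrence count across
#' the names plus `adjacencyBonus` for each time it appears adjacent to an
#' already-selected word. If every token is a stopword the highest-count
#' raw token is used.
#'
#' @param names Character vector of term names in the cluster.
#' @param maxWords Maximum words in the label (default 4).
#' @param adjacencyBonus Bonus per adjacency to a selected word (default 8).
#' @param stopwords Words excluded from labels.
#' @return The label: selected words joined by spaces in selection order.
#' @export
labelCluster <- function(names, maxWords = 4, adjacencyBonus = 8,
                         stopwords = default_stopwords()) {
  stopifnot(length(names) >= 1)
  toks <- lapply(tolower(names), function(s)
    strsplit(gsub("[^a-z0-9'-]+", " ", s), " +")[[1]])
  toks <- lapply(toks, function(x) x[nzchar(x)])
  all_tokens <- unlist(toks)
  cand <- setdiff(unique(all_tokens), stopwords)
  if (!length(cand)) {
    tab <- sort(table(all_tokens), decreasing = TRUE)
    return(names(tab)[1])
  }
  counts <- table(factor(all_tokens, levels = cand))
  selected <- character(0)
  while (length(selected) < maxWords && length(cand)) {
    score <- vapply(cand, function(w) {
      adj <- 0
      if (length(selected)) for (tk in toks) {
        pos <- which(tk == w)
        for (p in pos)
          adj <- adj + sum(tk[c(p - 1, p + 1)[c(p - 1, p + 1) >= 1 &
                                              c(p - 1, p + 1) <= length(tk)]]
                           %in% selected)
      }
      counts[[w]] + adjacencyBonus * adj
    }, numeric(1))
    best <- cand[order(-score, -as.numeric(counts[cand]), cand)][1]
    selected <- c(selected, best)
    cand <- setdiff(cand, best)
  }
  paste(selected, collapse = " ")
}

#' Collapse a clustered term graph into meta-nodes
#'
#' One meta-node per cluster, labelled by [labelCluster()], with the member
#' count and a summary FDR (minimum member FDR by default, `"median"`
#' available). Meta-edges connect clusters with at least one cross edge and
#' carry the mean cross-edge similarity.
#'
#' @param graph A clustered [TermGraph] (see [mclCluster()]).
#' @param fdrSummary `"min"` (default) or `"median"`.
#' @param maxWords,adjacencyBonus Label parameters (see [labelCluster()]).
#' @return List with `meta_nodes` (data.frame: `cluster`, `label`,
#'   `n_nodes`, `summary_fdr`, `members` list column) and `meta_edges`
#'   (data.frame: `cluster_a`, `cluster_b`, `mean_similarity`, `n_edges`).
#' @export
collapseToMeta <- function(graph, fdrSummary = c("min", "median"),
                           maxWords = 4, adjacencyBonus = 8) {
  fdrSummary <- match.arg(fdrSummary)
  nd <- graph@nodes
  if (is.null(nd$cluster)) stop("graph is not clustered; run mclCluster() first")
  agg <- if (fdrSummary == "min") min else stats::median
  cl <- sort(unique(nd$cluster))
  meta <- lapply(cl, function(cc) {
    sub <- nd[nd$cluster == cc, , drop = FALSE]
    data.frame(cluster = cc,
               label = labelCluster(sub$name, maxWords, adjacencyBonus),
               n_nodes = nrow(sub), summary_fdr = agg(sub$fdr),
               members = I(list(sub$term_id)), row.names = NULL)
  })
  meta <- do.call(rbind, meta)
  e <- graph@edges
  medges <- data.frame(cluster_a = integer(), cluster_b = integer(),
                       mean_similarity = numeric(), n_edges = integer())
  if (nrow(e)) {
    ca <- nd$cluster[match(e$from, nd$term_id)]
    cb <- nd$cluster[match(e$to, nd$term_id)]
    cross <- ca != cb
    if (any(cross)) {
      lo <- pmin(ca[cross], cb[cross]); hi <- pmax(ca[cross], cb[cross])
      key <- paste(lo, hi)
      medges <- do.call(rbind, lapply(split(seq_along(key), key), function(ii) {
        data.frame(cluster_a = lo[ii[1]], cluster_b = hi[ii[1]],
                   mean_similarity = mean(e$similarity[cross][ii]),
                   n_edges = length(ii))
      }))
      rownames(medges) <- NULL
    }
  }
  list(meta_nodes = meta, meta_edges = medges)
}
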