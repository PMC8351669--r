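#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `term_id`, description,
#' then member gene ids. Duplicate members within a set are dropped.
#'
#' @param path Path to the GMT file.
#' @return Named list of gene-id vectors; each element carries the
#'   description in attribute `"description"`.
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line ", i, ": fewer than 3 fields")
    ids[i] <- f[1]
    members <- unique(f[-(1:2)])
    attr(members, "description") <- f[2]
    out[[i]] <- members
  }
  if (anyDuplicated(ids)) stop("duplicated term ids in GMT")
  stats::setNames(out, ids)
}

#' Hypergeometric over-representation analysis
#'
#' For every gene set (restricted to the universe and filtered to sizes in
#' `[minSize, maxSize]`), tests whether the signature hits it more often
#' than chance: `p = P[X >= k]`, `X ~ Hypergeometric(N, K, n)` with `N`
#' universe genes, `K` in the set, `n` in the signature, `k` hits. BH FDR
#' across tested terms; rows with `fdr < alpha` are flagged significant.
#'
#' @param signature Character vector of gene ids (genes outside the
#'   universe are dropped with a warning).
#' @param universe Character vector of expressed gene ids.
#' @param sets Named list of gene-set member vectors (see [readGMT()]).
#' @param minSize,maxSize In-universe set size bounds (defaults 10, 500).
#' @param alpha FDR significance threshold (default 0.05).
#' @return data.frame with `term_id`, `name`, `k`, `K`, `n`, `N`, `p`,
#'   `fdr`, `significant`, `hits` (list column of hit gene ids), ordered by
#'   p-value.
#' @export
ora <- function(signature, universe, sets, minSize = 10, maxSize = 500,
                alpha = 0.05) {
  universe <- unique(universe)
  signature <- unique(signature)
  drop <- setdiff(signature, universe)
  if (length(drop)) {
    warning(length(drop), " signature gene(s) outside the universe dropped")
    signature <- intersect(signature, universe)
  }
  if (!length(signature)) {
    warning("empty signature; no enrichment computed")
    return(data.frame(term_id = character(), name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(), fdr = numeric(),
                      significant = logical()))
  }
  N <- length(universe); n <- length(signature)
  rows <- lapply(names(sets), function(id) {
    members <- intersect(sets[[id]], universe)
    K <- length(members)
    if (K < minSize || K > maxSize) return(NULL)
    hits <- intersect(signature, members)
    k <- length(hits)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    nm <- attr(sets[[id]], "description")
    data.frame(term_id = id, name = if (is.null(nm)) id else nm,
               k = k, K = K, n = n, N = N, p = p,
               hits = I(list(hits)), row.names = NULL)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    warning("no gene set within the size bounds")
    return(data.frame(term_id = character(), name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(), fdr = numeric(),
                      significant = logical()))
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$fdr < alpha
  out[order(out$p), , drop = FALSE]
}
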