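#' Exclusive intersections of Trendy, module and hub gene sets
#'
#' Computes all seven exclusive regions of the three-set diagram
#' (upset-style) and the Trendy-hub intersection, the signature set carried
#' to functional analysis. Hub genes must be a subset of module genes by
#' construction.
#'
#' @param trendy,module,hub Character vectors of gene ids.
#' @return List with `regions` (named exclusive member lists, names like
#'   `"trendy&hub"`), `sizes`, and `signature` (= `trendy` intersect
#'   `hub`).
#' @export
intersectGeneSets <- function(trendy, module, hub) {
  if (!all(hub %in% module))
    stop("hub genes must be a subset of module genes")
  exclusiveRegions(list(trendy = trendy, module = module, hub = hub),
                   signature = intersect(trendy, hub))
}

#' Exclusive cross-tissue overlaps
#'
#' Upset-style exclusive intersections of per-tissue gene (or term) sets:
#' each element is assigned to the unique region of tissues that all
#' contain it, matching the "in common between only ..." semantics.
#'
#' @param sets Named list (>= 2) of character vectors, one per tissue.
#' @return List with `regions` and `sizes` as in [intersectGeneSets()].
#' @export
crossTissueOverlap <- function(sets) {
  stopifnot(length(sets) >= 2)
  exclusiveRegions(sets)
}

exclusiveRegions <- function(sets, signature = NULL) {
  stopifnot(!is.null(names(sets)), !anyDuplicated(names(sets)))
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(universe, names(sets)))
  key <- apply(member, 1, function(row) paste(names(sets)[row], collapse = "&"))
  regions <- split(universe, key)
  out <- list(regions = regions, sizes = lengths(regions))
  if (!is.null(signature)) out$signature <- signature
  out
}
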