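#' Map essential features to gene symbols
#'
#' Transforms per-omics feature lists into a deduplicated symbol union
#' with provenance: every omics layer contributing a symbol is recorded,
#' so cross-omics redundancy (one symbol reachable from several layers)
#' is visible. Unmapped features are reported, never silently dropped.
#'
#' @param features_by_omics named list, omics type -> feature id vector
#' @param annotation named character vector feature id -> gene symbol
#'   (many-to-one allowed), e.g. from [read_annotation_map()]
#' @return list: `symbols` (deduplicated union, first-seen order),
#'   `provenance` (data.frame symbol, omics), `unmapped` (data.frame
#'   omics, feature_id)
#' @export
map_to_symbols <- function(features_by_omics, annotation) {
  prov <- list()
  unmapped <- list()
  for (ot in names(features_by_omics)) {
    f <- features_by_omics[[ot]]
    sym <- unname(annotation[f])
    bad <- is.na(sym) | !nzchar(sym)
    if (any(bad))
      unmapped[[ot]] <- data.frame(omics = ot, feature_id = f[bad],
                                   stringsAsFactors = FALSE)
    if (any(!bad))
      prov[[ot]] <- data.frame(symbol = unique(sym[!bad]), omics = ot,
                               stringsAsFactors = FALSE)
  }
  prov <- if (length(prov)) do.call(rbind, prov) else
    data.frame(symbol = character(0), omics = character(0))
  rownames(prov) <- NULL
  unmapped <- if (length(unmapped)) do.call(rbind, unmapped) else
    data.frame(omics = character(0), feature_id = character(0))
  rownames(unmapped) <- NULL
  if (nrow(unmapped))
    warnf("%d feature(s) had no symbol annotation", nrow(unmapped))
  list(symbols = unique(prov$symbol), provenance = prov, unmapped = unmapped)
}

#' Compute PPI degrees for a set of gene symbols
#'
#' Degree = number of distinct interaction partners in the (undirected)
#' edge list; self-loops and duplicate edges are ignored. Symbols absent
#' from the network get degree 0 and `annotated = FALSE`.
#'
#' @param symbols gene symbols of interest
#' @param edges data.frame with columns `from`, `to`
#' @param min_degree hub threshold recorded in the `hub` column, default 5
#' @return data.frame: symbol, degree, annotated, hub
#' @export
compute_degrees <- function(symbols, edges, min_degree = 5L) {
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges[, c("from", "to")], directed = FALSE)
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
    deg <- igraph::degree(g)
  } else {
    deg <- integer(0)
  }
  d <- ifelse(symbols %in% names(deg), deg[symbols], 0L)
  out <- data.frame(symbol = symbols, degree = as.integer(d),
                    annotated = symbols %in% names(deg),
                    stringsAsFactors = FALSE)
  out$hub <- out$degree >= min_degree
  out
}

#' Filter hub genes
#'
#' Symbols whose degree meets the threshold, sorted by descending degree
#' and then symbol.
#'
#' @param degree_table a [compute_degrees()] data.frame
#' @param min_degree hub threshold (degree greater than or equal), default 5
#' @return character vector of hub symbols
#' @export
hub_filter <- function(degree_table, min_degree = 5L) {
  hubs <- degree_table[degree_table$degree >= min_degree, , drop = FALSE]
  hubs$symbol[order(-hubs$degree, hubs$symbol)]
}
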