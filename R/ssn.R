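## Sequence similarity networks: 100 %-identity collapsing, e-value
## thresholded edges (D-only networks at 1e-54, all-protein at 1e-30),
## small-component removal, connected components as isofunctional groups.

#' Collapse 100 %-identical proteins into representative nodes
#'
#' Exact-sequence grouping; the representative is the lexicographically
#' smallest member ID and carries the group size as multiplicity.
#'
#' @param proteins Named character vector.
#' @return data.frame with \code{rep_id}, \code{sequence},
#'   \code{multiplicity}, \code{members} (comma-separated IDs), one row per
#'   distinct sequence, ordered by representative ID.
#' @export
collapse_identical <- function(proteins) {
  if (length(proteins) == 0)
    return(data.frame(rep_id = character(), sequence = character(),
                      multiplicity = integer(), members = character(),
                      stringsAsFactors = FALSE))
  groups <- split(names(proteins), unname(proteins))
  out <- do.call(rbind, lapply(names(groups), function(s) {
    ids <- sort(groups[[s]])
    data.frame(rep_id = ids[1], sequence = s, multiplicity = length(ids),
               members = paste(ids, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$rep_id), ]
  rownames(out) <- NULL
  out
}

#' Build a protein sequence similarity network
#'
#' Collapses identical sequences, draws an edge between representatives
#' whose pairwise e-value passes the threshold (\code{<=} by default;
#' \code{strict = TRUE} uses \code{<}), and optionally removes connected
#' components with fewer members than \code{min_component_size} (counting
#' representative nodes by default, or total multiplicity with
#' \code{count_multiplicity = TRUE}). Edge weights carry
#' \eqn{-\log_{10}}(e-value), clamped at machine precision for e-value 0.
#'
#' @param proteins Named character vector.
#' @param threshold E-value threshold (> 0), e.g. 1e-54 for D-only networks
#'   and 1e-30 for all-protein networks.
#' @param min_component_size Optional minimum component size (the published
#'   all-protein networks drop components with fewer than 5 members).
#' @param params \code{\link{scoring_params}}.
#' @param hits Optional precomputed \code{\link{all_vs_all}} hit table over
#'   the representatives (must contain \code{log10_evalue}).
#' @param node_attrs Optional data.frame keyed by \code{id} with extra node
#'   attributes (e.g. role, family, source region) attached to
#'   representatives.
#' @param strict Use strict inequality at the threshold.
#' @param count_multiplicity Count collapsed multiplicity in the component
#'   size filter.
#' @return An igraph graph with vertex attributes \code{name},
#'   \code{multiplicity}, \code{members} (plus any \code{node_attrs}) and
#'   edge attributes \code{evalue}, \code{neglog10e}.
#' @export
build_ssn <- function(proteins, threshold, min_component_size = NULL,
                      params = NULL, hits = NULL, node_attrs = NULL,
                      strict = FALSE, count_multiplicity = FALSE) {
  stopifnot(threshold > 0)
  reps <- collapse_identical(proteins)
  seqs <- stats::setNames(reps$sequence, reps$rep_id)
  if (is.null(hits)) {
    hits <- if (length(seqs) >= 2) all_vs_all(seqs, params = params)
    else data.frame(query = character(), subject = character(),
                    log10_evalue = numeric())
  }
  lt <- log10(threshold)
  keep <- if (strict) hits$log10_evalue < lt else hits$log10_evalue <= lt
  edges <- hits[keep & hits$query %in% reps$rep_id &
                  hits$subject %in% reps$rep_id & hits$query != hits$subject,
                , drop = FALSE]
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(reps$rep_id, multiplicity = reps$multiplicity,
                     members = reps$members)
  if (!is.null(node_attrs)) {
    i <- match(reps$rep_id, node_attrs$id)
    for (col in setdiff(names(node_attrs), "id"))
      g <- igraph::set_vertex_attr(g, col, value = node_attrs[[col]][i])
  }
  if (nrow(edges) > 0) {
    ev <- pmax(10^edges$log10_evalue, .Machine$double.xmin)
    g <- igraph::add_edges(g, rbind(edges$query, edges$subject),
                           evalue = ev,
                           neglog10e = -log10(ev))
  }
  if (!is.null(min_component_size)) {
    comp <- igraph::components(g)
    per_vertex <- if (count_multiplicity) {
      sz <- tapply(igraph::V(g)$multiplicity, comp$membership, sum)
      unname(sz[as.character(comp$membership)])
    } else comp$csize[comp$membership]
    drop <- names(comp$membership)[per_vertex < min_component_size]
    g <- igraph::delete_vertices(g, drop)
  }
  g
}

#' Connected components of a similarity network
#'
#' Isofunctional groups: connected components with deterministic group IDs
#' (the lexicographically smallest member).
#'
#' @param graph igraph graph from \code{\link{build_ssn}}.
#' @return data.frame with \code{node}, \code{component_id}, sorted by
#'   component then node.
#' @export
ssn_components <- function(graph) {
  comp <- igraph::components(graph)
  memb <- comp$membership
  if (length(memb) == 0)
    return(data.frame(node = character(), component_id = character(),
                      stringsAsFactors = FALSE))
  cid <- vapply(split(names(memb), memb), min, character(1))
  out <- data.frame(node = names(memb),
                    component_id = unname(cid[as.character(memb)]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$component_id, out$node), ]
  rownames(out) <- NULL
  out
}

#' Write a similarity network to TSV and GraphML
#'
#' Edge list, node table and (optionally) GraphML for import into network
#' viewers; layout is the viewer's job.
#'
#' @param graph igraph graph.
#' @param edge_tsv,node_tsv,graphml Output paths (any may be \code{NULL} to
#'   skip).
#' @return Invisibly, the paths written.
#' @export
write_ssn <- function(graph, edge_tsv = NULL, node_tsv = NULL,
                      graphml = NULL) {
  written <- character(0)
  if (!is.null(edge_tsv)) {
    el <- igraph::as_data_frame(graph, what = "edges")
    utils::write.table(el, edge_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, edge_tsv)
  }
  if (!is.null(node_tsv)) {
    nl <- igraph::as_data_frame(graph, what = "vertices")
    utils::write.table(nl, node_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, node_tsv)
  }
  if (!is.null(graphml)) {
    igraph::write_graph(graph, graphml, format = "graphml")
    written <- c(written, graphml)
  }
  invisible(written)
}
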