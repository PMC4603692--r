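## MultiGeneBlast-style region comparison: weighted homology-hit count plus
## synteny conservation, then single-linkage grouping into families at a
## strict score threshold of 10.

# gene order index (rank by start) and strands of a region's members
.region_order <- function(region) {
  m <- region$members
  data.frame(gene_id = m$gene_id, pos = seq_len(nrow(m)), strand = m$strand,
             stringsAsFactors = FALSE)
}

#' One-to-one homology hit mapping between two regions
#'
#' Greedy best-score matching of the member proteins of region a to those of
#' region b, among alignment hits passing the comparison filters
#' (identity >= 30 \%, query coverage >= 25 \%, and a permissive e-value
#' cap). Each protein is used at most once; mappings are capped at
#' \code{max_hits}. Ties break deterministically by raw score, then gene
#' order.
#'
#' @param region_a,region_b \code{tomm_region} objects.
#' @param hits Optional precomputed hit table (from
#'   \code{\link{all_vs_all}} over the union of member proteins); computed
#'   on the fly if \code{NULL}.
#' @param params \code{\link{scoring_params}}.
#' @param min_identity_pct,min_coverage_pct,max_evalue Hit filters
#'   (defaults 30, 25, 1e-3).
#' @param max_hits Cap on mapped hits per region pair (default 100).
#' @return data.frame with \code{gene_a}, \code{gene_b}, \code{raw_score},
#'   \code{pos_a}, \code{pos_b} (gene order ranks), \code{strand_a},
#'   \code{strand_b}; zero rows if nothing maps.
#' @export
map_hits <- function(region_a, region_b, hits = NULL, params = NULL,
                     min_identity_pct = 30, min_coverage_pct = 25,
                     max_evalue = 1e-3, max_hits = 100) {
  oa <- .region_order(region_a); ob <- .region_order(region_b)
  if (is.null(hits)) {
    prots <- c(stats::setNames(region_a$members$protein, oa$gene_id),
               stats::setNames(region_b$members$protein, ob$gene_id))
    prots <- prots[!duplicated(names(prots))]
    hits <- all_vs_all(prots, params = params,
                       min_identity_pct = min_identity_pct,
                       min_coverage_pct = min_coverage_pct,
                       max_evalue = max_evalue)
  }
  # orient hits as (gene in a, gene in b); a hit table row covers both
  # orientations of the unordered pair
  h1 <- hits[hits$query %in% oa$gene_id & hits$subject %in% ob$gene_id,
             c("query", "subject", "raw_score")]
  h2 <- hits[hits$subject %in% oa$gene_id & hits$query %in% ob$gene_id,
             c("subject", "query", "raw_score")]
  names(h1) <- names(h2) <- c("gene_a", "gene_b", "raw_score")
  h <- rbind(h1, h2)
  h <- h[h$gene_a != h$gene_b, , drop = FALSE]
  h <- h[!duplicated(paste(h$gene_a, h$gene_b)), , drop = FALSE]
  if (nrow(h) == 0) return(.empty_mapping())
  h$pos_a <- oa$pos[match(h$gene_a, oa$gene_id)]
  h$pos_b <- ob$pos[match(h$gene_b, ob$gene_id)]
  h <- h[order(-h$raw_score, h$pos_a, h$pos_b), ]
  used_a <- character(0); used_b <- character(0); keep <- integer(0)
  for (k in seq_len(nrow(h))) {
    if (length(keep) >= max_hits) break
    if (h$gene_a[k] %in% used_a || h$gene_b[k] %in% used_b) next
    keep <- c(keep, k)
    used_a <- c(used_a, h$gene_a[k]); used_b <- c(used_b, h$gene_b[k])
  }
  h <- h[keep, , drop = FALSE]
  h$strand_a <- oa$strand[match(h$gene_a, oa$gene_id)]
  h$strand_b <- ob$strand[match(h$gene_b, ob$gene_id)]
  h <- h[order(h$pos_a), ]
  rownames(h) <- NULL
  h
}

.empty_mapping <- function() {
  data.frame(gene_a = character(), gene_b = character(),
             raw_score = integer(), pos_a = integer(), pos_b = integer(),
             strand_a = character(), strand_b = character(),
             stringsAsFactors = FALSE)
}

#' Synteny conservation score of a hit mapping
#'
#' Counts consecutive (by gene order in region a) mapped gene pairs whose
#' partners are also adjacent in region b with conserved relative
#' orientation. Adjacency in b may run in either direction, so a whole
#' cluster inversion (order reversed, strands flipped coherently) scores
#' fully; relative orientation of the two genes (same strand vs opposite
#' strands) must match between the regions.
#'
#' @param mapping Output of \code{\link{map_hits}}.
#' @return Non-negative integer, at most \code{max(nrow(mapping) - 1, 0)}.
#' @export
synteny_score <- function(mapping) {
  if (nrow(mapping) < 2) return(0L)
  m <- mapping[order(mapping$pos_a), ]
  s <- 0L
  for (k in seq_len(nrow(m) - 1)) {
    if (m$pos_a[k + 1] != m$pos_a[k] + 1) next
    if (abs(m$pos_b[k + 1] - m$pos_b[k]) != 1) next
    rel_a <- m$strand_a[k] == m$strand_a[k + 1]
    rel_b <- m$strand_b[k] == m$strand_b[k + 1]
    if (rel_a == rel_b) s <- s + 1L
  }
  s
}

#' Weighted homology + synteny score of a region pair
#'
#' \code{total = w_blast * hit_count + w_synteny * synteny_score} with both
#' weights 0.5 by default (the published comparison parameters). In
#' \code{score_mode = "bits"}, the cumulative bit score of the mapped hits
#' replaces the hit count.
#'
#' @param region_a,region_b \code{tomm_region} objects.
#' @param hits Optional precomputed hit table.
#' @param weights Numeric length-2 vector \code{c(blast, synteny)}.
#' @param score_mode \code{"count"} (default) or \code{"bits"}.
#' @param params \code{\link{scoring_params}} (needed for \code{"bits"}).
#' @param ... Filters passed to \code{\link{map_hits}}.
#' @return List of class \code{"tomm_pair_score"} with \code{region_a},
#'   \code{region_b}, \code{hit_count}, \code{synteny_score},
#'   \code{total}, and the \code{mapping}.
#' @export
region_score <- function(region_a, region_b, hits = NULL,
                         weights = c(blast = 0.5, synteny = 0.5),
                         score_mode = c("count", "bits"), params = NULL,
                         ...) {
  score_mode <- match.arg(score_mode)
  mapping <- map_hits(region_a, region_b, hits = hits, params = params, ...)
  syn <- synteny_score(mapping)
  blast_term <- if (score_mode == "count") nrow(mapping) else
    sum(alignment_bitscore(mapping$raw_score, .default_params(params)))
  structure(list(region_a = region_a$region_id,
                 region_b = region_b$region_id,
                 hit_count = nrow(mapping), synteny_score = syn,
                 total = unname(weights[1] * blast_term + weights[2] * syn),
                 mapping = mapping),
            class = "tomm_pair_score")
}

#' Score all unordered region pairs
#'
#' @param regions Named list of \code{tomm_region} objects.
#' @param hits Precomputed hit table over all member proteins (strongly
#'   recommended: compute once with \code{\link{all_vs_all}} using the
#'   comparison filters, then reuse).
#' @param ... Passed to \code{\link{region_score}}.
#' @return data.frame with \code{region_a}, \code{region_b},
#'   \code{hit_count}, \code{synteny_score}, \code{total}, one row per
#'   unordered pair in deterministic order.
#' @export
score_all_regions <- function(regions, hits = NULL, ...) {
  n <- length(regions)
  rows <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      rs <- region_score(regions[[i]], regions[[j]], hits = hits, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        region_a = rs$region_a, region_b = rs$region_b,
        hit_count = rs$hit_count, synteny_score = rs$synteny_score,
        total = rs$total, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(data.frame(
    region_a = character(), region_b = character(), hit_count = integer(),
    synteny_score = integer(), total = numeric(),
    stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}

#' Group regions into families by single linkage
#'
#' Connected components over edges with \code{total} strictly above the
#' threshold (a pair scoring exactly the threshold does not link).
#' Singletons form their own families. The family ID is the
#' lexicographically smallest member region ID.
#'
#' @param pair_scores data.frame from \code{\link{score_all_regions}} (or a
#'   sparse above-threshold subset).
#' @param region_ids All region IDs to assign (so regions with no edges
#'   still appear); defaults to those present in \code{pair_scores}.
#' @param threshold Strict linking threshold (default 10).
#' @return data.frame with \code{family_id}, \code{region_id}, sorted by
#'   family then region.
#' @export
group_families <- function(pair_scores, region_ids = NULL, threshold = 10) {
  if (is.null(region_ids))
    region_ids <- sort(unique(c(pair_scores$region_a, pair_scores$region_b)))
  region_ids <- sort(unique(region_ids))
  edges <- pair_scores[pair_scores$total > threshold, , drop = FALSE]
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(region_ids)
  if (nrow(edges) > 0)
    g <- igraph::add_edges(g, rbind(edges$region_a, edges$region_b))
  comp <- igraph::components(g)
  memb <- comp$membership
  fam <- vapply(split(names(memb), memb), function(ids) min(ids),
                character(1))
  out <- data.frame(family_id = unname(fam[as.character(memb)]),
                    region_id = names(memb), stringsAsFactors = FALSE)
  out <- out[order(out$family_id, out$region_id), ]
  rownames(out) <- NULL
  out
}
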