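## Anchor detection and extraction of 10-kb YcaO-anchored neighbourhoods.

#' Bundled D-protein reference panel for anchor calling
#'
#' The synthetic stand-ins used to locate YcaO/D anchor genes by local
#' alignment: the canonical D seed and the bottromycin-type D seed. Fused
#' cyclodehydratases (CD) anchor through their D half, so no separate CD
#' reference is needed (and including one would wrongly anchor discrete C
#' proteins through its C half).
#'
#' @return Named character vector of reference protein sequences.
#' @export
d_reference_panel <- function() {
  seeds <- role_seed_sequences()
  seeds[c("D", "D_bottromycin")]
}

#' Locate anchor (YcaO/D) genes
#'
#' A gene is an anchor if its best local-alignment e-value against any
#' reference D sequence is at or below the cutoff. Alternatively, anchors
#' may be supplied directly (\code{anchor_ids}) or read from an external
#' domain-search table (\code{domtbl}), mirroring InterPro/HMMER-based
#' retrieval.
#'
#' @param annotations Annotation data.frame (see
#'   \code{\link{read_genome_bundle}}).
#' @param d_references Named character vector of reference D proteins;
#'   defaults to \code{\link{d_reference_panel}}.
#' @param evalue_cutoff Anchor-call e-value cutoff (default 1e-10).
#' @param params \code{\link{scoring_params}}.
#' @param anchor_ids Optional character vector of gene IDs to use as anchors
#'   directly.
#' @param domtbl Optional path to a HMMER domtblout-style file; listed gene
#'   IDs become anchors.
#' @return The subset of \code{annotations} that are anchors, ordered by
#'   genome then coordinate.
#' @export
find_anchors <- function(annotations, d_references = NULL,
                         evalue_cutoff = 1e-10, params = NULL,
                         anchor_ids = NULL, domtbl = NULL) {
  if (nrow(annotations) == 0) return(annotations)
  if (!is.null(domtbl)) anchor_ids <- unique(read_domtblout(domtbl)$gene_id)
  if (is.null(anchor_ids)) {
    if (is.null(d_references)) d_references <- d_reference_panel()
    stopifnot(length(d_references) >= 1)
    prot <- stats::setNames(annotations$protein, annotations$gene_id)
    best <- best_reference_hits(prot, d_references, params = params)
    anchor_ids <- best$query[best$log10_evalue <= log10(evalue_cutoff)]
  }
  out <- annotations[annotations$gene_id %in% anchor_ids, ]
  out <- out[order(out$genome_id, out$start, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Extract the 10-kb neighbourhood around an anchor gene
#'
#' The window is \code{[max(0, anchor_start - window_bp),
#' min(genome_length, anchor_end + window_bp))}. Member proteins are all
#' annotations overlapping the window, included whole (a boundary gene is
#' not clipped), sorted by start. Intergenic segments tile the window minus
#' the annotated CDS spans.
#'
#' @param genome_seq DNA sequence of the replicon (single string).
#' @param annotations Annotation data.frame for this replicon.
#' @param anchor_id Gene ID of the anchor (must be present in
#'   \code{annotations}).
#' @param window_bp Flank size, default 10000.
#' @return Object of class \code{"tomm_region"}: list with
#'   \code{region_id}, \code{genome_id}, \code{anchor_gene_id},
#'   \code{window_start}, \code{window_end} (0-based half-open),
#'   \code{members} (annotation rows sorted by start),
#'   \code{intergenic} (data.frame start/end), and \code{dna} (the window
#'   sequence).
#' @export
extract_region <- function(genome_seq, annotations, anchor_id,
                           window_bp = 10000) {
  i <- match(anchor_id, annotations$gene_id)
  if (is.na(i)) stop("anchor '", anchor_id, "' not found in annotations")
  glen <- nchar(genome_seq)
  ws <- max(0L, annotations$start[i] - as.integer(window_bp))
  we <- min(glen, annotations$end[i] + as.integer(window_bp))
  same <- annotations[annotations$genome_id == annotations$genome_id[i], ]
  members <- same[same$start < we & same$end > ws, ]
  members <- members[order(members$start, members$gene_id), ]
  rownames(members) <- NULL
  # complement of CDS spans within the window
  iv <- members[members$start < we & members$end > ws,
                c("start", "end"), drop = FALSE]
  iv$start <- pmax(iv$start, ws); iv$end <- pmin(iv$end, we)
  iv <- iv[order(iv$start), , drop = FALSE]
  inter <- list(); cur <- ws
  for (k in seq_len(nrow(iv))) {
    if (iv$start[k] > cur)
      inter[[length(inter) + 1L]] <- c(cur, iv$start[k])
    cur <- max(cur, iv$end[k])
  }
  if (cur < we) inter[[length(inter) + 1L]] <- c(cur, we)
  inter <- if (length(inter)) {
    m <- do.call(rbind, inter)
    data.frame(start = m[, 1], end = m[, 2])
  } else data.frame(start = integer(), end = integer())
  structure(list(
    region_id = paste0(annotations$genome_id[i], ":", anchor_id),
    genome_id = annotations$genome_id[i],
    anchor_gene_id = anchor_id,
    window_start = ws, window_end = we,
    members = members, intergenic = inter,
    dna = substr(genome_seq, ws + 1L, we)),
    class = "tomm_region")
}

#' @export
print.tomm_region <- function(x, ...) {
  cat(sprintf("<tomm_region> %s [%d, %d) %d members, %d intergenic segments\n",
              x$region_id, x$window_start, x$window_end, nrow(x$members),
              nrow(x$intergenic)))
  invisible(x)
}

#' Extract regions for every anchor in a genome set
#'
#' @param genomes Named character vector of replicon sequences.
#' @param annotations Annotation data.frame.
#' @param anchors Anchor annotation rows (from \code{\link{find_anchors}}).
#' @param window_bp Flank size.
#' @return Named list of \code{tomm_region} objects (one per anchor; regions
#'   of tandem anchors may overlap).
#' @export
extract_regions <- function(genomes, annotations, anchors,
                            window_bp = 10000) {
  out <- vector("list", nrow(anchors))
  for (k in seq_len(nrow(anchors))) {
    gid <- anchors$genome_id[k]
    ann <- annotations[annotations$genome_id == gid, ]
    out[[k]] <- extract_region(genomes[[gid]], ann, anchors$gene_id[k],
                               window_bp)
  }
  stats::setNames(out, vapply(out, `[[`, "", "region_id"))
}
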