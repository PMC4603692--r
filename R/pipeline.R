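## End-to-end orchestration: anchors -> regions -> precursors -> hits ->
## families -> roles -> verdicts -> networks -> report.

#' Run the full TOMM mining pipeline
#'
#' Chains every stage over one or more genome bundles: anchor detection,
#' 10-kb region extraction, both precursor screens, all-vs-all member
#' protein comparison (computed once and reused for family grouping and the
#' networks), MultiGeneBlast-style family grouping, role calling, the
#' three-rule TOMM decision with family propagation, and the two similarity
#' networks (D-only at \code{d_ssn_evalue}, all-protein at
#' \code{all_ssn_evalue}).
#'
#' @param bundles A \code{tomm_genome_bundle}, a list of them, or the output
#'   of \code{\link{read_genome_bundle}} (a list with \code{genomes} and
#'   \code{annotations}).
#' @param window_bp Region flank (default 10000).
#' @param family_threshold Strict family-linking score threshold
#'   (default 10).
#' @param min_identity_pct,min_coverage_pct Hit-mapping filters
#'   (defaults 30, 25).
#' @param max_hits Mapped-hit cap per region pair (default 100).
#' @param d_ssn_evalue,all_ssn_evalue Network thresholds (defaults 1e-54
#'   and 1e-30).
#' @param min_component_size Small-component filter for the all-protein
#'   network (default 5).
#' @param anchor_evalue Anchor-call cutoff (default 1e-10).
#' @param params \code{\link{scoring_params}}.
#' @param seed Recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return List with \code{anchors}, \code{regions}, \code{precursors}
#'   (candidates + flags), \code{hits}, \code{pair_scores},
#'   \code{families}, \code{role_calls}, \code{verdicts}, \code{ssn_d},
#'   \code{ssn_all}, \code{report}, \code{manifest}.
#' @export
run_tomm_pipeline <- function(bundles, window_bp = 10000,
                              family_threshold = 10,
                              min_identity_pct = 30, min_coverage_pct = 25,
                              max_hits = 100, d_ssn_evalue = 1e-54,
                              all_ssn_evalue = 1e-30,
                              min_component_size = 5,
                              anchor_evalue = 1e-10, params = NULL,
                              seed = NA) {
  if (inherits(bundles, "tomm_genome_bundle")) bundles <- list(bundles)
  if (!is.null(bundles$genomes)) {
    genomes <- bundles$genomes
    annotations <- bundles$annotations
  } else {
    genomes <- stats::setNames(
      vapply(bundles, function(b) b$genome$sequence, character(1)),
      vapply(bundles, function(b) b$genome$id, character(1)))
    annotations <- do.call(rbind, lapply(bundles, `[[`, "annotations"))
  }
  anchors <- find_anchors(annotations, evalue_cutoff = anchor_evalue,
                          params = params)
  regions <- extract_regions(genomes, annotations, anchors,
                             window_bp = window_bp)
  precursors <- scan_all(regions)
  # one global comparison over all member proteins, reused everywhere
  member_prot <- unlist(lapply(regions, function(r)
    stats::setNames(r$members$protein, r$members$gene_id)), use.names = TRUE)
  names(member_prot) <- sub("^.*?\\.", "", names(member_prot))
  member_prot <- member_prot[!duplicated(names(member_prot))]
  sp <- .default_params(params)
  db_size <- sum(nchar(member_prot))
  # alignment detail (identity/coverage) only matters for hits that can
  # reach the family-mapping e-value cap; skip the traceback below that
  detail_cut <- floor((log(sp$K * min(nchar(member_prot)) * db_size) -
                         log(1e-3)) / sp$lambda)
  hits <- all_vs_all(member_prot, params = sp,
                     detail_min_score = max(detail_cut, 0))
  fam_hits <- hits[hits$identity_pct >= min_identity_pct &
                     hits$coverage_pct >= min_coverage_pct &
                     hits$log10_evalue <= -3, ]
  pair_scores <- score_all_regions(regions, hits = fam_hits,
                                   max_hits = max_hits)
  families <- group_families(pair_scores, region_ids = names(regions),
                             threshold = family_threshold)
  role_calls <- do.call(rbind, lapply(regions, function(r) {
    rc <- call_roles(r, params = params)
    rc$region_id <- r$region_id
    rc
  }))
  rownames(role_calls) <- NULL
  bott <- data.frame(
    region_id = names(regions),
    bottromycin_like = vapply(names(regions), function(rid)
      bottromycin_like(regions[[rid]],
                       role_calls[role_calls$region_id == rid, ]),
      logical(1)),
    stringsAsFactors = FALSE)
  verdicts <- classify(families, role_calls, precursors$flags, bott)
  # D-only network over anchor proteins; all-protein network over members
  anchor_prot <- stats::setNames(anchors$protein, anchors$gene_id)
  node_attrs <- data.frame(
    id = role_calls$gene_id, role = role_calls$role,
    region = role_calls$region_id, stringsAsFactors = FALSE)
  node_attrs <- node_attrs[!duplicated(node_attrs$id), ]
  ssn_d <- build_ssn(anchor_prot, threshold = d_ssn_evalue, params = sp,
                     hits = hits, node_attrs = node_attrs)
  ssn_all <- build_ssn(member_prot, threshold = all_ssn_evalue,
                       min_component_size = min_component_size,
                       params = sp, hits = hits, node_attrs = node_attrs)
  report <- family_report(verdicts, role_calls, precursors$candidates)
  list(anchors = anchors, regions = regions, precursors = precursors,
       hits = hits, pair_scores = pair_scores, families = families,
       role_calls = role_calls, verdicts = verdicts, ssn_d = ssn_d,
       ssn_all = ssn_all, report = report,
       manifest = run_manifest(
         params = list(window_bp = window_bp,
                       family_threshold = family_threshold,
                       min_identity_pct = min_identity_pct,
                       min_coverage_pct = min_coverage_pct,
                       max_hits = max_hits, d_ssn_evalue = d_ssn_evalue,
                       all_ssn_evalue = all_ssn_evalue,
                       min_component_size = min_component_size,
                       anchor_evalue = anchor_evalue),
         seed = seed))
}
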