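## Gene role calling and the three-rule TOMM decision with family-level
## label propagation: a family is a TOMM family if ANY member region has a
## C/CD protein, a precursor peptide, or looks bottromycin-like; all member
## regions inherit the verdict.

#' Bundled role reference panels
#'
#' Named list of reference protein sets, one panel per callable role. The
#' C and D panels also drive CD-fusion detection: a gene significantly
#' similar to both is a fused cyclodehydratase.
#'
#' @return Named list of named character vectors.
#' @export
role_reference_panels <- function() {
  seeds <- role_seed_sequences()
  list(C = seeds["C"],
       D = seeds[c("D", "D_bottromycin")],
       B = seeds["B"],
       F = seeds["F"],
       transporter = seeds["transporter"],
       protease = seeds["protease"],
       radical_SAM = seeds["radical_SAM"],
       methyltransferase = seeds["methyltransferase"])
}

# priority used for equal-score ties between role panels
.ROLE_PRIORITY <- c("CD_fusion", "C", "B", "F", "D", "radical_SAM",
                    "transporter", "protease", "methyltransferase", "other")

#' Call gene roles within a region
#'
#' Every member gene (anchor included: fused cyclodehydratases are the
#' anchor) is aligned against each role panel. A gene significantly similar
#' to both the C and D panels is a \code{CD_fusion}; a gene passing the D
#' panel with only partial C-side similarity (above \code{truncated_cd_cutoff}
#' but not \code{evalue_cutoff}) is a truncated fusion
#' (\code{CD_fusion}, \code{truncated = TRUE}), the HCA/haloazolisin case.
#' Otherwise the best passing panel wins; equal-score conflicts break by
#' fixed role priority. Genes passing nothing are \code{other}.
#'
#' An external domain-search table can override similarity calling: rows of
#' \code{domtbl_calls} (from \code{\link{read_domtblout}}) with accession
#' TIGR03603 map to \code{C}, TIGR03882 to \code{CD_fusion}.
#'
#' @param region A \code{tomm_region}.
#' @param panels Role reference panels
#'   (\code{\link{role_reference_panels}}).
#' @param evalue_cutoff Per-role e-value cutoff (default 1e-10).
#' @param truncated_cd_cutoff Reduced C-side cutoff for truncated fusions
#'   (default 1e-4).
#' @param params \code{\link{scoring_params}}.
#' @param domtbl_calls Optional data.frame from \code{\link{read_domtblout}}.
#' @return data.frame with \code{gene_id}, \code{role},
#'   \code{best_reference}, \code{evalue}, \code{truncated}.
#' @export
call_roles <- function(region, panels = role_reference_panels(),
                       evalue_cutoff = 1e-10, truncated_cd_cutoff = 1e-4,
                       params = NULL, domtbl_calls = NULL) {
  stopifnot(inherits(region, "tomm_region"), length(panels) >= 1)
  genes <- stats::setNames(region$members$protein, region$members$gene_id)
  # best log10 e-value per gene per panel
  ev <- matrix(Inf, length(genes), length(panels),
               dimnames = list(names(genes), names(panels)))
  ref <- matrix(NA_character_, length(genes), length(panels),
                dimnames = dimnames(ev))
  for (p in names(panels)) {
    b <- best_reference_hits(genes, panels[[p]], params = params)
    ev[, p] <- b$log10_evalue
    ref[, p] <- b$reference
  }
  cut <- log10(evalue_cutoff)
  tcut <- log10(truncated_cd_cutoff)
  out <- data.frame(gene_id = names(genes), role = "other",
                    best_reference = NA_character_, evalue = NA_real_,
                    truncated = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    eC <- if ("C" %in% names(panels)) ev[i, "C"] else Inf
    eD <- if ("D" %in% names(panels)) ev[i, "D"] else Inf
    if (eD <= cut && eC <= cut) {
      out$role[i] <- "CD_fusion"
      out$best_reference[i] <- ref[i, "D"]
      out$evalue[i] <- 10^max(eC, eD)
    } else if (eD <= cut && eC <= tcut) {
      out$role[i] <- "CD_fusion"
      out$truncated[i] <- TRUE
      out$best_reference[i] <- ref[i, "D"]
      out$evalue[i] <- 10^max(eC, eD)
    } else {
      passing <- names(panels)[ev[i, ] <= cut]
      if (length(passing) > 0) {
        e <- ev[i, passing]
        best <- passing[e == min(e)]
        if (length(best) > 1)
          best <- best[order(match(best, .ROLE_PRIORITY))][1]
        out$role[i] <- best
        out$best_reference[i] <- ref[i, best]
        out$evalue[i] <- 10^ev[i, best]
      }
    }
  }
  if (!is.null(domtbl_calls) && nrow(domtbl_calls) > 0) {
    acc_role <- c(TIGR03603 = "C", TIGR03882 = "CD_fusion")
    dc <- domtbl_calls[domtbl_calls$accession %in% names(acc_role) &
                         domtbl_calls$gene_id %in% out$gene_id, ]
    for (k in seq_len(nrow(dc))) {
      i <- match(dc$gene_id[k], out$gene_id)
      out$role[i] <- unname(acc_role[dc$accession[k]])
      out$best_reference[i] <- dc$accession[k]
      out$evalue[i] <- dc$evalue[k]
    }
  }
  rownames(out) <- NULL
  out
}

#' Bottromycin-likeness of a region
#'
#' TRUE if the region contains two or more D-role genes together with at
#' least one radical-SAM enzyme (the gene-content signature of bottromycin
#' clusters), or if its comparison score against any supplied reference
#' bottromycin region exceeds the family threshold.
#'
#' @param region A \code{tomm_region}.
#' @param role_calls Output of \code{\link{call_roles}} for this region.
#' @param reference_regions Optional list of \code{tomm_region} objects from
#'   known bottromycin producers.
#' @param threshold Family-score threshold for the reference route
#'   (default 10).
#' @param ... Passed to \code{\link{region_score}}.
#' @return Logical flag.
#' @export
bottromycin_like <- function(region, role_calls, reference_regions = NULL,
                             threshold = 10, ...) {
  n_d <- sum(role_calls$role == "D")
  has_rsam <- any(role_calls$role == "radical_SAM")
  if (n_d >= 2 && has_rsam) return(TRUE)
  if (!is.null(reference_regions)) {
    for (ref in reference_regions) {
      if (region_score(region, ref, ...)$total > threshold) return(TRUE)
    }
  }
  FALSE
}

#' Classify families as TOMM or non-TOMM
#'
#' Applies the three evidence rules at the region level, then propagates to
#' the family: a family is a TOMM family if any member region has a C or CD
#' fusion protein, contains a precursor peptide, or is bottromycin-like;
#' every member region inherits the family verdict.
#'
#' @param families data.frame from \code{\link{group_families}}.
#' @param role_calls Combined \code{\link{call_roles}} output with a
#'   \code{region_id} column.
#' @param precursor_flags data.frame \code{region_id},
#'   \code{has_precursor} (from \code{\link{scan_all}}).
#' @param bottromycin_flags Optional data.frame \code{region_id},
#'   \code{bottromycin_like}; missing regions default to FALSE.
#' @return List with \code{families} (data.frame \code{family_id},
#'   \code{is_tomm}, \code{evidence}, \code{n_members}) and \code{regions}
#'   (per-region verdict and evidence detail).
#' @export
classify <- function(families, role_calls, precursor_flags,
                     bottromycin_flags = NULL) {
  stopifnot(all(c("family_id", "region_id") %in% names(families)))
  if (nrow(families) == 0) {
    empty_fam <- data.frame(family_id = character(), is_tomm = logical(),
                            evidence = character(), n_members = integer(),
                            stringsAsFactors = FALSE)
    empty_reg <- data.frame(region_id = character(), family_id = character(),
                            has_C_or_CD = logical(), has_precursor = logical(),
                            bottromycin_like = logical(), is_tomm = logical(),
                            family_evidence = character(),
                            stringsAsFactors = FALSE)
    return(list(families = empty_fam, regions = empty_reg))
  }
  has_c <- tapply(role_calls$role %in% c("C", "CD_fusion"),
                  role_calls$region_id, any)
  reg <- data.frame(region_id = families$region_id,
                    family_id = families$family_id,
                    stringsAsFactors = FALSE)
  reg$has_C_or_CD <- unname(has_c[reg$region_id])
  reg$has_C_or_CD[is.na(reg$has_C_or_CD)] <- FALSE
  reg$has_precursor <- precursor_flags$has_precursor[
    match(reg$region_id, precursor_flags$region_id)]
  reg$has_precursor[is.na(reg$has_precursor)] <- FALSE
  reg$bottromycin_like <- FALSE
  if (!is.null(bottromycin_flags)) {
    i <- match(reg$region_id, bottromycin_flags$region_id)
    reg$bottromycin_like <- !is.na(i) & bottromycin_flags$bottromycin_like[i]
    reg$bottromycin_like[is.na(reg$bottromycin_like)] <- FALSE
  }
  ev_str <- function(c_, p_, b_) {
    e <- c(if (c_) "has_C_or_CD", if (p_) "has_precursor",
           if (b_) "bottromycin_like")
    if (length(e)) paste(e, collapse = ",") else ""
  }
  fam_split <- split(reg, reg$family_id)
  fams <- do.call(rbind, lapply(fam_split, function(d) {
    c_ <- any(d$has_C_or_CD); p_ <- any(d$has_precursor)
    b_ <- any(d$bottromycin_like)
    data.frame(family_id = d$family_id[1], is_tomm = c_ || p_ || b_,
               evidence = ev_str(c_, p_, b_), n_members = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(fams) <- NULL
  reg$is_tomm <- fams$is_tomm[match(reg$family_id, fams$family_id)]
  reg$family_evidence <- fams$evidence[match(reg$family_id, fams$family_id)]
  list(families = fams, regions = reg)
}
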