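## Reporting: cleavage-site heuristic, position frequency matrices of
## precursor core regions, per-family summary tables and run manifests.

#' Estimate the leader/core cleavage site of a precursor
#'
#' Cleavage sites are estimated from length and the presence of a Gly or
#' Ala residue, as in characterized precursors: the core starts right after
#' the last G/A inside the leader search zone (positions between
#' \code{zone[1]} and \code{zone[2]} of the peptide length). If the zone
#' holds no G/A, the core falls back to the C-terminal half (final
#' \code{floor(L/2)} residues).
#'
#' @param precursor Protein string, length >= 10.
#' @param zone Numeric length-2: fractional search zone (default 0.35-0.65).
#' @return 1-based index of the first core residue.
#' @export
estimate_cleavage <- function(precursor, zone = c(0.35, 0.65)) {
  stopifnot(is.character(precursor), length(precursor) == 1)
  L <- nchar(precursor)
  if (L < 10) stop("precursor must be at least 10 residues")
  lo <- max(1L, ceiling(zone[1] * L))
  hi <- min(L - 1L, floor(zone[2] * L))
  ch <- strsplit(precursor, "")[[1]]
  ga <- which(ch %in% c("G", "A"))
  ga <- ga[ga >= lo & ga <= hi]
  if (length(ga) > 0) return(max(ga) + 1L)
  L - L %/% 2 + 1L
}

#' Position frequency matrix of precursor core regions
#'
#' Cores are right-aligned (C-terminus anchored, the shared end of TOMM
#' cores) and padded with gaps to the longest core. Column frequencies are
#' computed over the residues present; gaps are tracked separately and
#' excluded from the residue simplex, so every column with at least one
#' residue sums to 1.
#'
#' @param cores Character vector of core peptides (>= 1).
#' @return Object of class \code{"tomm_pfm"}: list with \code{matrix}
#'   (20 x W residue frequencies), \code{gap_counts} (per column),
#'   \code{n_sequences}, \code{width}.
#' @export
build_pfm <- function(cores) {
  if (length(cores) == 0) stop("no cores supplied")
  W <- max(nchar(cores))
  padded <- vapply(cores, function(s)
    paste0(strrep("-", W - nchar(s)), s), character(1), USE.NAMES = FALSE)
  ch <- do.call(rbind, strsplit(padded, ""))
  mat <- matrix(0, nrow = length(AA20), ncol = W,
                dimnames = list(AA20, NULL))
  gaps <- integer(W)
  for (j in seq_len(W)) {
    col <- ch[, j]
    gaps[j] <- sum(col == "-")
    res <- col[col != "-"]
    if (length(res) > 0) {
      tab <- table(factor(res, levels = AA20))
      mat[, j] <- as.numeric(tab) / length(res)
    }
  }
  structure(list(matrix = mat, gap_counts = gaps,
                 n_sequences = length(cores), width = W),
            class = "tomm_pfm")
}

#' @export
print.tomm_pfm <- function(x, ...) {
  cat(sprintf("<tomm_pfm> %d sequences, width %d\n", x$n_sequences,
              x$width))
  invisible(x)
}

#' Write a PFM as JASPAR-style tab-delimited matrix or JSON
#'
#' @param pfm A \code{tomm_pfm}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_pfm_jaspar <- function(pfm, path) {
  lines <- vapply(rownames(pfm$matrix), function(aa)
    paste0(aa, "  [ ",
           paste(sprintf("%.6f", pfm$matrix[aa, ]), collapse = " "),
           " ]"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pfm_jaspar
#' @export
write_pfm_json <- function(pfm, path) {
  jsonlite::write_json(list(matrix = pfm$matrix,
                            gap_counts = pfm$gap_counts,
                            n_sequences = pfm$n_sequences,
                            width = pfm$width),
                       path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Per-family summary table
#'
#' One row per family: member count, verdict and evidence, role inventory
#' (sorted unique biosynthetic roles seen in member regions, e.g.
#' \code{"CD_fusion+B+F"}), precursor count and mean core C/S/T fraction
#' (cores cut by \code{\link{estimate_cleavage}}).
#'
#' @param verdicts Output of \code{\link{classify}}.
#' @param role_calls Combined role-call table with \code{region_id}.
#' @param candidates Candidate table from \code{\link{scan_all}}.
#' @return data.frame ordered by family ID; zero-row input gives a zero-row
#'   table with the same columns.
#' @export
family_report <- function(verdicts, role_calls, candidates) {
  fam <- verdicts$families
  reg <- verdicts$regions
  show_roles <- c("C", "CD_fusion", "D", "B", "F", "radical_SAM")
  rows <- lapply(seq_len(nrow(fam)), function(i) {
    fid <- fam$family_id[i]
    rids <- reg$region_id[reg$family_id == fid]
    rc <- role_calls[role_calls$region_id %in% rids, , drop = FALSE]
    roles <- intersect(show_roles, unique(rc$role))
    cand <- candidates[candidates$region_id %in% rids, , drop = FALSE]
    mean_cst <- if (nrow(cand) > 0) {
      cores <- vapply(cand$sequence, function(s)
        substr(s, estimate_cleavage(s), nchar(s)), character(1))
      mean(vapply(cores, function(co)
        if (nchar(co) >= 2) cst_fraction(co) else NA_real_, numeric(1)),
        na.rm = TRUE)
    } else NA_real_
    data.frame(family_id = fid, n_members = fam$n_members[i],
               is_tomm = fam$is_tomm[i], evidence = fam$evidence[i],
               architecture = if (length(roles))
                 paste(roles, collapse = "+") else "",
               n_precursors = nrow(cand), mean_core_cst = mean_cst,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(data.frame(
    family_id = character(), n_members = integer(), is_tomm = logical(),
    evidence = character(), architecture = character(),
    n_precursors = integer(), mean_core_cst = numeric(),
    stringsAsFactors = FALSE))))
  out <- out[order(out$family_id), ]
  rownames(out) <- NULL
  out
}

#' Run manifest
#'
#' Parameters, seed and versions for reproducibility records.
#'
#' @param params Named list of run parameters.
#' @param seed The run seed.
#' @return Named list.
#' @export
run_manifest <- function(params = list(), seed = NA) {
  list(package = "tommscan",
       version = as.character(utils::packageVersion("tommscan")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       seed = seed, params = params)
}
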