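## Precursor peptide detection: method 1 screens annotated short genes
## (< 450 bp, C-terminal-half C/S/T >= 45 %); method 2 enumerates six-frame
## ORFs over the whole region window (< 150 aa, >= 65 %). Thresholds follow
## the published screen exactly: the length bounds are strict, the
## composition bounds inclusive.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' C-terminal-half Cys/Ser/Thr fraction
#'
#' The C-terminal half is the final \code{floor(L/2)} residues (documented
#' convention for odd lengths). With \code{include_gly = TRUE}, Gly is
#' counted as well (core regions are often described as Gly/Cys/Ser/Thr
#' rich; the screen itself counts C/S/T only).
#'
#' @param peptide Protein string(s), length >= 2 each.
#' @param include_gly Count Gly too (default FALSE).
#' @return Numeric vector of fractions in [0, 1].
#' @export
cst_fraction <- function(peptide, include_gly = FALSE) {
  stopifnot(is.character(peptide), all(nzchar(peptide)))
  if (any(nchar(peptide) < 2))
    stop("peptide must have length >= 2 (C-terminal half would be empty)")
  vapply(peptide, function(p) {
    L <- nchar(p)
    half <- substr(p, L - L %/% 2 + 1L, L)
    set <- if (include_gly) c("C", "S", "T", "G") else c("C", "S", "T")
    ch <- strsplit(half, "")[[1]]
    sum(ch %in% set) / length(ch)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Method 1: screen annotated short genes
#'
#' Member genes with CDS span strictly smaller than \code{max_len_bp}
#' (450 bp, stop codon included) and C-terminal-half C/S/T fraction of at
#' least \code{min_cst} (0.45) are candidate precursors. The anchor D gene
#' is excluded; additional gene IDs (e.g. genes already role-called as
#' C/CD/B) can be excluded via \code{exclude_ids}.
#'
#' @param region A \code{tomm_region}.
#' @param max_len_bp Strict upper bound on CDS span (default 450).
#' @param min_cst Inclusive composition threshold (default 0.45).
#' @param exclude_ids Gene IDs to exclude beyond the anchor.
#' @param include_gly Passed to \code{\link{cst_fraction}}.
#' @return Candidate data.frame (possibly empty), ordered by coordinate,
#'   with columns \code{region_id}, \code{gene_id}, \code{method},
#'   \code{start}, \code{end}, \code{strand}, \code{frame},
#'   \code{length_aa}, \code{cst_fraction}, \code{sequence}.
#' @export
method1_annotated <- function(region, max_len_bp = 450, min_cst = 0.45,
                              exclude_ids = character(0),
                              include_gly = FALSE) {
  stopifnot(inherits(region, "tomm_region"))
  m <- region$members
  m <- m[!(m$gene_id %in% c(region$anchor_gene_id, exclude_ids)), ]
  if (nrow(m) == 0) return(.empty_candidates())
  span <- m$end - m$start
  keep <- span < max_len_bp & nchar(m$protein) >= 2
  m <- m[keep, ]
  if (nrow(m) == 0) return(.empty_candidates())
  cst <- cst_fraction(m$protein, include_gly = include_gly)
  m <- m[cst >= min_cst, ]
  cst <- cst[cst >= min_cst]
  if (nrow(m) == 0) return(.empty_candidates())
  out <- data.frame(region_id = region$region_id, gene_id = m$gene_id,
                    method = "1_annotated", start = m$start, end = m$end,
                    strand = m$strand, frame = NA_integer_,
                    length_aa = nchar(m$protein), cst_fraction = cst,
                    sequence = m$protein, stringsAsFactors = FALSE)
  out <- out[order(out$start, out$gene_id), ]
  rownames(out) <- NULL
  out
}

.empty_candidates <- function() {
  data.frame(region_id = character(), gene_id = character(),
             method = character(), start = integer(), end = integer(),
             strand = character(), frame = integer(), length_aa = integer(),
             cst_fraction = numeric(), sequence = character(),
             stringsAsFactors = FALSE)
}

# scan one strand's frames of a forward-oriented sequence
.orfs_one_strand <- function(s, min_len_aa, max_len_aa, starts, all_starts) {
  n <- nchar(s)
  res <- list()
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3
    if (ncod < 2) next
    codons <- substring(s, frame + 3 * seq_len(ncod) - 2,
                        frame + 3 * seq_len(ncod))
    valid <- !grepl("[^ACGT]", codons)
    is_stop <- codons %in% .STOP_CODONS & valid
    is_start <- codons %in% starts & valid
    stop_idx <- which(is_stop)
    prev_stop <- 0L
    for (st in stop_idx) {
      cand <- if (st - 1L >= prev_stop + 1L)
        which(is_start[(prev_stop + 1L):(st - 1L)]) + prev_stop
      else integer(0)
      if (length(cand) > 0) {
        use <- if (all_starts) cand else cand[1]
        for (b in use) {
          len_aa <- st - b
          if (len_aa >= min_len_aa && len_aa < max_len_aa) {
            pep <- if (st - 1L >= b + 1L)
              paste(c("M", Biostrings::GENETIC_CODE[
                codons[(b + 1L):(st - 1L)]]), collapse = "")
            else "M"
            res[[length(res) + 1L]] <- list(
              peptide = pep,
              start = frame + 3L * (b - 1L),
              end = frame + 3L * st, # includes the stop codon
              frame = frame)
          }
        }
      }
      prev_stop <- st
    }
  }
  res
}

#' Enumerate open reading frames in all six frames
#'
#' An ORF runs from a start codon (\code{ATG}, \code{GTG}, \code{TTG}; the
#' initiator translates as Met) to the next in-frame stop codon, which must
#' be present. By default the longest ORF per (frame, stop) is reported
#' (first start after the previous stop); \code{all_starts = TRUE}
#' enumerates every start. Codons containing non-ACGT characters translate
#' as X and never act as start or stop.
#'
#' @param dna DNA string.
#' @param min_len_aa Inclusive minimum peptide length (stop excluded).
#' @param max_len_aa Strict maximum peptide length.
#' @param starts Start codon set.
#' @param all_starts Report every start codon per stop.
#' @return data.frame with \code{peptide}, \code{start}, \code{end}
#'   (0-based half-open on the forward strand of \code{dna}, stop codon
#'   included), \code{strand}, \code{frame}, ordered by start coordinate.
#' @export
six_frame_orfs <- function(dna, min_len_aa = 25, max_len_aa = 150,
                           starts = c("ATG", "GTG", "TTG"),
                           all_starts = FALSE) {
  stopifnot(is.character(dna), length(dna) == 1)
  dna <- toupper(dna)
  n <- nchar(dna)
  fwd <- .orfs_one_strand(dna, min_len_aa, max_len_aa, starts, all_starts)
  rev <- .orfs_one_strand(revcomp_dna(dna), min_len_aa, max_len_aa, starts,
                          all_starts)
  rows <- c(
    lapply(fwd, function(o) data.frame(
      peptide = o$peptide, start = o$start, end = o$end, strand = "+",
      frame = o$frame, stringsAsFactors = FALSE)),
    lapply(rev, function(o) data.frame(
      peptide = o$peptide, start = n - o$end, end = n - o$start,
      strand = "-", frame = o$frame, stringsAsFactors = FALSE)))
  if (length(rows) == 0)
    return(data.frame(peptide = character(), start = integer(),
                      end = integer(), strand = character(),
                      frame = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end, out$strand, out$frame), ]
  rownames(out) <- NULL
  out
}

#' Method 2: six-frame ORF screen over the region window
#'
#' Enumerates ORFs over the full window DNA (annotated plus intergenic),
#' keeps peptides strictly shorter than \code{max_len_aa} (150) with
#' C-terminal-half C/S/T fraction of at least \code{min_cst} (0.65), and
#' removes duplicates (identical peptide sequence within the region keeps
#' the first by coordinate). Coordinates are genome coordinates.
#'
#' @param region A \code{tomm_region}.
#' @param min_len_aa Minimum ORF length (default 25 aa; the screen itself
#'   states no minimum, but tiny precursors are ~45 aa).
#' @param max_len_aa Strict maximum (default 150).
#' @param min_cst Inclusive composition threshold (default 0.65).
#' @param include_gly Passed to \code{\link{cst_fraction}}.
#' @param all_starts Passed to \code{\link{six_frame_orfs}}.
#' @return Candidate data.frame as in \code{\link{method1_annotated}}, with
#'   \code{method = "2_sixframe"}.
#' @export
method2_sixframe <- function(region, min_len_aa = 25, max_len_aa = 150,
                             min_cst = 0.65, include_gly = FALSE,
                             all_starts = FALSE) {
  stopifnot(inherits(region, "tomm_region"))
  orfs <- six_frame_orfs(region$dna, min_len_aa = min_len_aa,
                         max_len_aa = max_len_aa, all_starts = all_starts)
  if (nrow(orfs) == 0) return(.empty_candidates())
  cst <- cst_fraction(orfs$peptide, include_gly = include_gly)
  orfs <- orfs[cst >= min_cst, ]
  cst <- cst[cst >= min_cst]
  if (nrow(orfs) == 0) return(.empty_candidates())
  # six_frame_orfs output is already coordinate-sorted: first-by-coordinate
  # wins the dedup
  dup <- duplicated(orfs$peptide)
  orfs <- orfs[!dup, ]; cst <- cst[!dup]
  out <- data.frame(region_id = region$region_id, gene_id = NA_character_,
                    method = "2_sixframe",
                    start = orfs$start + region$window_start,
                    end = orfs$end + region$window_start,
                    strand = orfs$strand, frame = orfs$frame,
                    length_aa = nchar(orfs$peptide), cst_fraction = cst,
                    sequence = orfs$peptide, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Scan regions with both precursor detection methods
#'
#' Union of methods 1 and 2 per region; a method-2 ORF identical in
#' sequence and coordinates to a method-1 gene is merged with
#' \code{method = "both"}. \code{has_precursor} flags regions with at least
#' one candidate.
#'
#' @param regions List of \code{tomm_region} objects.
#' @param min_orf_aa,cst1,cst2,maxlen1_bp,maxlen2_aa Screen thresholds
#'   (defaults 25 aa, 0.45, 0.65, 450 bp, 150 aa).
#' @param exclude_ids Gene IDs excluded from method-1 candidacy (beyond each
#'   region's anchor), e.g. genes role-called as C/CD/B.
#' @param include_gly Count Gly in the composition fraction.
#' @return List with \code{candidates} (combined candidate table) and
#'   \code{flags} (data.frame \code{region_id}, \code{has_precursor}).
#' @export
scan_all <- function(regions, min_orf_aa = 25, cst1 = 0.45, cst2 = 0.65,
                     maxlen1_bp = 450, maxlen2_aa = 150,
                     exclude_ids = character(0), include_gly = FALSE) {
  cands <- list()
  for (r in regions) {
    m1 <- method1_annotated(r, max_len_bp = maxlen1_bp, min_cst = cst1,
                            exclude_ids = exclude_ids,
                            include_gly = include_gly)
    m2 <- method2_sixframe(r, min_len_aa = min_orf_aa,
                           max_len_aa = maxlen2_aa, min_cst = cst2,
                           include_gly = include_gly)
    if (nrow(m1) > 0 && nrow(m2) > 0) {
      key1 <- paste(m1$start, m1$end, m1$strand, m1$sequence)
      key2 <- paste(m2$start, m2$end, m2$strand, m2$sequence)
      shared <- key2 %in% key1
      m1$method[key1 %in% key2] <- "both"
      m2 <- m2[!shared, ]
    }
    cands[[r$region_id]] <- rbind(m1, m2)
  }
  candidates <- do.call(rbind, c(cands, list(.empty_candidates())))
  rownames(candidates) <- NULL
  flags <- data.frame(
    region_id = vapply(regions, `[[`, "", "region_id"),
    has_precursor = vapply(regions, function(r)
      r$region_id %in% candidates$region_id, logical(1)),
    stringsAsFactors = FALSE)
  rownames(flags) <- NULL
  list(candidates = candidates, flags = flags)
}
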