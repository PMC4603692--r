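## similarity engine: Smith-Waterman local alignment + Karlin-Altschul
## statistics. Stand-in for BLAST; constants are configuration, not truth.

.pkg_cache <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.pkg_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$BLOSUM62 <- as.matrix(e$BLOSUM62)
  }
  .pkg_cache$BLOSUM62
}

#' Scoring parameters for local protein alignment
#'
#' Bundles the substitution matrix, affine gap penalties and Karlin-Altschul
#' constants used to convert raw Smith-Waterman scores into bit scores and
#' e-values (\eqn{E = K m n e^{-\lambda S}}). Defaults are the standard gapped
#' BLOSUM62 constants for gap open 11 / extend 1 (\eqn{\lambda = 0.267},
#' \eqn{K = 0.041}).
#'
#' @param matrix Substitution matrix name (only \code{"BLOSUM62"} is bundled)
#'   or a numeric matrix with residue dimnames.
#' @param gap_open,gap_extend Affine gap penalties; a gap of length L costs
#'   \code{gap_open + L * gap_extend}.
#' @param lambda,K Karlin-Altschul constants; must be positive.
#' @return An object of class \code{"tomm_scoring"}.
#' @export
scoring_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041) {
  if (is.character(matrix)) {
    if (matrix != "BLOSUM62") stop("only BLOSUM62 is bundled")
    mat <- .blosum62()
  } else {
    mat <- as.matrix(matrix)
  }
  stopifnot(lambda > 0, K > 0, gap_open >= 0, gap_extend > 0)
  structure(list(matrix = mat, gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K),
            class = "tomm_scoring")
}

.default_params <- function(params = NULL) {
  if (is.null(params)) {
    if (is.null(.pkg_cache$default_params))
      .pkg_cache$default_params <- scoring_params()
    params <- .pkg_cache$default_params
  }
  stopifnot(inherits(params, "tomm_scoring"))
  params
}

# 0-based codes into the matrix row order; unknown letters map to X
.encode_protein <- function(seqs, mat) {
  rn <- rownames(mat)
  xi <- match("X", rn)
  lapply(strsplit(toupper(seqs), "", fixed = TRUE), function(ch) {
    i <- match(ch, rn)
    i[is.na(i)] <- xi
    i - 1L
  })
}

#' Optimal local alignment of two protein sequences
#'
#' Affine-gap Smith-Waterman with deterministic traceback (tie-break
#' diagonal > up > left; best cell is the first maximum in row-major order).
#'
#' @param a,b Protein sequences (single strings). An empty sequence yields
#'   score 0 and an empty alignment.
#' @param params \code{\link{scoring_params}} object.
#' @param traceback If \code{FALSE}, only the raw score is computed.
#' @return A list with \code{raw_score}, \code{bit_score}, alignment span
#'   coordinates (\code{q_start}, \code{q_end}, \code{s_start}, \code{s_end},
#'   1-based inclusive), \code{identity_pct} (identical columns / alignment
#'   columns, gaps included), \code{query_coverage_pct}, and the two aligned
#'   strings \code{aligned_a}, \code{aligned_b}.
#' @export
smith_waterman <- function(a, b, params = NULL, traceback = TRUE) {
  params <- .default_params(params)
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  enc <- .encode_protein(c(a, b), params$matrix)
  S <- .int_matrix(params$matrix)
  r <- .sw_pair_cpp(enc[[1]], enc[[2]], S, params$gap_open, params$gap_extend)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  aa <- ifelse(r$path_a == 0, "-", ca[pmax(r$path_a, 1)])
  ab <- ifelse(r$path_b == 0, "-", cb[pmax(r$path_b, 1)])
  list(raw_score = r$score,
       bit_score = alignment_bitscore(r$score, params),
       q_start = r$qstart, q_end = r$qend,
       s_start = r$sstart, s_end = r$send,
       n_ident = r$nident, aln_len = r$alnlen,
       identity_pct = if (r$alnlen > 0) 100 * r$nident / r$alnlen else 0,
       query_coverage_pct = if (nchar(a) > 0)
         100 * max(r$qend - r$qstart + 1, 0) / nchar(a) else 0,
       aligned_a = paste(aa, collapse = ""),
       aligned_b = paste(ab, collapse = ""))
}

.int_matrix <- function(mat) {
  m <- matrix(as.integer(round(mat)), nrow(mat), ncol(mat))
  dimnames(m) <- dimnames(mat)
  m
}

#' Karlin-Altschul e-value and bit score
#'
#' \code{alignment_evalue} computes \eqn{E = K m n e^{-\lambda S}} for a raw
#' local alignment score; \code{alignment_log10_evalue} returns
#' \eqn{\log_{10} E} (safe from underflow for large scores);
#' \code{alignment_bitscore} returns \eqn{(\lambda S - \ln K)/\ln 2}.
#'
#' @param raw_score Raw alignment score(s).
#' @param m Query length in residues.
#' @param n Effective database size in residues (for all-vs-all use, total
#'   residues in the compared set).
#' @param params \code{\link{scoring_params}}.
#' @return Numeric vector. \code{alignment_evalue} is floored at the smallest
#'   positive double so e-values stay strictly positive.
#' @export
alignment_evalue <- function(raw_score, m, n, params = NULL) {
  params <- .default_params(params)
  stopifnot(all(m > 0), all(n > 0))
  e <- exp(log(params$K) + log(m) + log(n) - params$lambda * raw_score)
  pmax(e, .Machine$double.xmin)
}

#' @rdname alignment_evalue
#' @export
alignment_log10_evalue <- function(raw_score, m, n, params = NULL) {
  params <- .default_params(params)
  stopifnot(all(m > 0), all(n > 0))
  (log(params$K) + log(m) + log(n) - params$lambda * raw_score) / log(10)
}

#' @rdname alignment_evalue
#' @export
alignment_bitscore <- function(raw_score, params = NULL) {
  params <- .default_params(params)
  (params$lambda * raw_score - log(params$K)) / log(2)
}

#' All-vs-all local alignment with BLAST-style hit filters
#'
#' Aligns every unordered pair of input proteins (self-hits excluded) and
#' keeps hits passing all filters. The paper's comparison filters are
#' identity >= 30 \% and query coverage >= 25 \%.
#'
#' @param proteins Named character vector of protein sequences.
#' @param params \code{\link{scoring_params}}.
#' @param min_identity_pct Minimum percent identity over alignment columns.
#' @param min_coverage_pct Minimum percent of the query spanned by the
#'   alignment. With \code{coverage_mode = "both"} the filter must hold for
#'   both sequences of the pair.
#' @param max_evalue Maximum e-value.
#' @param db_size Effective database size in residues; defaults to the total
#'   residue count of \code{proteins}.
#' @param coverage_mode \code{"query"} (default) or \code{"both"}.
#' @param detail_min_score Raw-score cutoff below which alignment detail
#'   (identity, coverage, spans) is not computed (reported as 0); a speed
#'   knob for large batches where weak pairs are discarded anyway. The
#'   default 0 always computes detail.
#' @return data.frame with one row per retained unordered pair, columns
#'   \code{query}, \code{subject}, \code{identity_pct}, \code{coverage_pct},
#'   \code{coverage_pct_subject}, \code{raw_score}, \code{bit_score},
#'   \code{evalue}, \code{log10_evalue} and alignment span coordinates.
#'   Rows are ordered by input position of query then subject.
#' @export
all_vs_all <- function(proteins, params = NULL, min_identity_pct = 0,
                       min_coverage_pct = 0, max_evalue = Inf, db_size = NULL,
                       coverage_mode = c("query", "both"),
                       detail_min_score = 0) {
  params <- .default_params(params)
  coverage_mode <- match.arg(coverage_mode)
  stopifnot(length(proteins) >= 1, !is.null(names(proteins)),
            !anyDuplicated(names(proteins)))
  if (is.null(db_size)) db_size <- sum(nchar(proteins))
  enc <- .encode_protein(proteins, params$matrix)
  S <- .int_matrix(params$matrix)
  if (length(proteins) == 1) {
    hits <- data.frame(i = integer(), j = integer(), raw_score = integer(),
                       n_ident = integer(), aln_len = integer(),
                       q_start = integer(), q_end = integer(),
                       s_start = integer(), s_end = integer())
  } else {
    hits <- .sw_batch_cpp(enc, list(), S, params$gap_open, params$gap_extend,
                          TRUE, as.integer(detail_min_score))
  }
  qlen <- nchar(proteins)[hits$i]
  slen <- nchar(proteins)[hits$j]
  hits$query <- names(proteins)[hits$i]
  hits$subject <- names(proteins)[hits$j]
  hits$identity_pct <- ifelse(hits$aln_len > 0,
                              100 * hits$n_ident / hits$aln_len, 0)
  hits$coverage_pct <- ifelse(qlen > 0,
                              100 * pmax(hits$q_end - hits$q_start + 1, 0) / qlen, 0)
  hits$coverage_pct_subject <- ifelse(slen > 0,
                                      100 * pmax(hits$s_end - hits$s_start + 1, 0) / slen, 0)
  hits$bit_score <- alignment_bitscore(hits$raw_score, params)
  hits$log10_evalue <- alignment_log10_evalue(hits$raw_score, qlen, db_size,
                                              params)
  hits$evalue <- pmax(10^hits$log10_evalue, .Machine$double.xmin)
  keep <- hits$identity_pct >= min_identity_pct &
    hits$coverage_pct >= min_coverage_pct &
    hits$log10_evalue <= log10(max_evalue)
  if (coverage_mode == "both")
    keep <- keep & hits$coverage_pct_subject >= min_coverage_pct
  hits <- hits[keep, c("query", "subject", "identity_pct", "coverage_pct",
                       "coverage_pct_subject", "raw_score", "bit_score",
                       "evalue", "log10_evalue", "q_start", "q_end",
                       "s_start", "s_end")]
  rownames(hits) <- NULL
  hits
}

#' Best local-alignment hits of query proteins against a reference panel
#'
#' Cross-compares queries against references and returns, per query, the best
#' (lowest e-value, ties by higher raw score then reference order) hit.
#' Used for anchor detection and gene role calling.
#'
#' @param queries,references Named character vectors of protein sequences.
#' @param params \code{\link{scoring_params}}.
#' @param db_size Effective database size; defaults to total reference
#'   residues.
#' @return data.frame with columns \code{query}, \code{reference},
#'   \code{raw_score}, \code{evalue}, \code{log10_evalue},
#'   \code{identity_pct}, \code{coverage_pct} (query coverage), one row per
#'   query (best hit), in input query order.
#' @export
best_reference_hits <- function(queries, references, params = NULL,
                                db_size = NULL) {
  params <- .default_params(params)
  stopifnot(length(references) >= 1)
  if (is.null(db_size)) db_size <- sum(nchar(references))
  encq <- .encode_protein(queries, params$matrix)
  encr <- .encode_protein(references, params$matrix)
  S <- .int_matrix(params$matrix)
  h <- .sw_batch_cpp(encq, encr, S, params$gap_open, params$gap_extend, FALSE)
  qlen <- nchar(queries)[h$i]
  h$log10_evalue <- alignment_log10_evalue(h$raw_score, qlen, db_size, params)
  ord <- order(h$i, h$log10_evalue, -h$raw_score, h$j)
  h <- h[ord, ]
  best <- h[!duplicated(h$i), ]
  best <- best[order(best$i), ]
  data.frame(query = names(queries)[best$i],
             reference = names(references)[best$j],
             raw_score = best$raw_score,
             evalue = pmax(10^best$log10_evalue, .Machine$double.xmin),
             log10_evalue = best$log10_evalue,
             identity_pct = ifelse(best$aln_len > 0,
                                   100 * best$n_ident / best$aln_len, 0),
             coverage_pct = ifelse(nchar(queries)[best$i] > 0,
                                   100 * pmax(best$q_end - best$q_start + 1, 0) /
                                     nchar(queries)[best$i], 0),
             stringsAsFactors = FALSE)
}

#' Read an external 12-column tabular alignment file
#'
#' Adapter for precomputed BLAST-style tabular output (outfmt 6: query,
#' subject, identity, alignment length, mismatches, gap opens, qstart, qend,
#' sstart, send, evalue, bitscore), for users who want bit-exact BLAST
#' behaviour in place of the internal engine.
#'
#' @param path Path to the tabular file.
#' @param query_lengths Optional named vector of query lengths used to derive
#'   query coverage; otherwise coverage is NA.
#' @return data.frame in the same shape as \code{\link{all_vs_all}} output.
#' @export
read_alignment_tab <- function(path, query_lengths = NULL) {
  x <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                         col.names = c("query", "subject", "identity_pct",
                                       "aln_len", "mismatch", "gapopen",
                                       "q_start", "q_end", "s_start", "s_end",
                                       "evalue", "bit_score"))
  cov <- rep(NA_real_, nrow(x))
  if (!is.null(query_lengths)) {
    ql <- query_lengths[x$query]
    cov <- 100 * (abs(x$q_end - x$q_start) + 1) / ql
  }
  data.frame(query = x$query, subject = x$subject,
             identity_pct = x$identity_pct, coverage_pct = cov,
             coverage_pct_subject = NA_real_,
             raw_score = NA_integer_, bit_score = x$bit_score,
             evalue = pmax(x$evalue, .Machine$double.xmin),
             log10_evalue = log10(pmax(x$evalue, .Machine$double.xmin)),
             q_start = x$q_start, q_end = x$q_end,
             s_start = x$s_start, s_end = x$s_end,
             stringsAsFactors = FALSE)
}

#' Write a hit table to TSV
#' @param hits Hit table from \code{\link{all_vs_all}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
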