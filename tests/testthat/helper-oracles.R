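# Independent oracles: deliberately written as plain-R reimplementations
# with different formulations from the package internals.

# Affine-gap local alignment via the match-state-anchored three-matrix
# recurrence (best taken over match cells only; a local alignment never ends
# in a gap under positive gap costs).
oracle_sw_score <- function(a, b, params = scoring_params()) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  mat <- params$matrix
  go <- params$gap_open
  ge <- params$gap_extend
  m <- length(A); n <- length(B)
  if (m == 0 || n == 0) return(0)
  M <- matrix(-Inf, m + 1, n + 1)
  Ix <- matrix(-Inf, m + 1, n + 1)
  Iy <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      s <- mat[A[i], B[j]]
      M[i + 1, j + 1] <- s + max(0, M[i, j], Ix[i, j], Iy[i, j])
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - go - ge, Ix[i, j + 1] - ge)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - go - ge, Iy[i + 1, j] - ge)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# Quadratic ORF enumerator: tests every position as a start codon, scans
# forward for the next in-frame stop and backwards to confirm the start is
# the first after the previous stop.
oracle_orfs <- function(dna, min_len_aa, max_len_aa,
                        starts = c("ATG", "GTG", "TTG")) {
  stops <- c("TAA", "TAG", "TGA")
  rows <- list()
  n <- nchar(dna)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else revcomp_dna(dna)
    for (p in seq_len(max(n - 2, 0))) {
      if (!substr(s, p, p + 2) %in% starts) next
      q <- p + 3; stop_at <- NA
      while (q + 2 <= n) {
        if (substr(s, q, q + 2) %in% stops) { stop_at <- q; break }
        q <- q + 3
      }
      if (is.na(stop_at)) next
      r <- p - 3; first <- TRUE
      while (r >= 1) {
        cod <- substr(s, r, r + 2)
        if (cod %in% stops) break
        if (cod %in% starts) { first <- FALSE; break }
        r <- r - 3
      }
      if (!first) next
      len <- (stop_at - p) / 3
      if (len < min_len_aa || len >= max_len_aa) next
      body <- if (len > 1) {
        cods <- substring(s, seq(p + 3, stop_at - 3, by = 3),
                          seq(p + 5, stop_at - 1, by = 3))
        aa <- Biostrings::GENETIC_CODE[cods]
        aa[is.na(aa)] <- "X"
        paste(aa, collapse = "")
      } else ""
      start0 <- if (strand == "+") p - 1 else n - (stop_at + 2)
      end0 <- if (strand == "+") stop_at + 2 else n - (p - 1)
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = paste0("M", body), start = as.integer(start0),
        end = as.integer(end0), strand = strand,
        frame = as.integer((p - 1) %% 3), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(peptide = character(), start = integer(),
                      end = integer(), strand = character(),
                      frame = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$start, out$end, out$strand, out$frame), , drop = FALSE]
}

# adjacency-conservation count straight from the definition
oracle_synteny <- function(mapping) {
  m <- mapping[order(mapping$pos_a), , drop = FALSE]
  s <- 0L
  if (nrow(m) < 2) return(s)
  for (k in seq_len(nrow(m) - 1)) {
    adjacent_a <- m$pos_a[k + 1] == m$pos_a[k] + 1
    adjacent_b <- abs(m$pos_b[k + 1] - m$pos_b[k]) == 1
    same_rel <- (m$strand_a[k] == m$strand_a[k + 1]) ==
      (m$strand_b[k] == m$strand_b[k + 1])
    if (adjacent_a && adjacent_b && same_rel) s <- s + 1L
  }
  s
}

# union-find connected components over an edge list
oracle_components <- function(nodes, edges_from, edges_to) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (k in seq_along(edges_from)) {
    a <- find(edges_from[k]); b <- find(edges_to[k])
    if (a != b) parent[[a]] <- b
  }
  vapply(nodes, find, character(1))
}

random_protein <- function(len, alphabet = tommscan::AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
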