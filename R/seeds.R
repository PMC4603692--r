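## Bundled synthetic seed proteins, back-translation table and the low-level
## sequence samplers used by the genome generator. All seeds are SYNTHETIC
## stand-ins for real reference proteins (which cannot be redistributed):
## random sequences drawn once from fixed internal seeds. They deliberately
## contain no Cys/Ser/Thr so that gene interiors and filler can never satisfy
## the precursor composition filters by construction.

#' The standard 20-letter amino-acid alphabet
#' @format Character vector of the 20 one-letter residue codes.
#' @export
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# residues used for seed/backbone sampling: the 20-letter alphabet minus C/S/T
.AA_NO_CST <- setdiff(AA20, c("C", "S", "T"))

# Run code with a locally seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

.random_protein <- function(len, alphabet = .AA_NO_CST) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# deterministic sub-seed derived from a label (kept below 2^31)
.seed_from_label <- function(label, base = 900100L) {
  s <- sum(as.numeric(utf8ToInt(label)) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(base) + s * 2654435) %% 2147483647)
}

#' Bundled synthetic role seed proteins
#'
#' One seed protein per biosynthetic gene role. Seeds are fixed synthetic
#' sequences: homolog families in generated genomes are realized by mutating
#' them to a target identity (\code{\link{mutate_protein}}), giving a
#' controllable similarity structure without shipping real database
#' sequences. \code{D_bottromycin} is a second, independent YcaO lineage so
#' bottromycin-type clusters form their own similarity-network component, as
#' stand-alone-D clusters do in real data. \code{CD} is the concatenation of
#' the C and D seeds (a fused cyclodehydratase).
#'
#' @return Named character vector of protein sequences with roles
#'   \code{C}, \code{D}, \code{D_bottromycin}, \code{CD}, \code{B}, \code{F},
#'   \code{transporter}, \code{protease}, \code{radical_SAM},
#'   \code{methyltransferase}.
#' @export
role_seed_sequences <- function() {
  if (!is.null(.pkg_cache$role_seeds)) return(.pkg_cache$role_seeds)
  lens <- c(C = 270L, D = 310L, D_bottromycin = 300L, B = 190L, F = 160L,
            transporter = 260L, protease = 210L, radical_SAM = 230L,
            methyltransferase = 200L)
  seeds <- vapply(names(lens), function(role) {
    .with_seed(.seed_from_label(paste0("role:", role)),
               .random_protein(lens[[role]]))
  }, character(1))
  seeds <- c(seeds, CD = unname(paste0(seeds["C"], seeds["D"])))
  .pkg_cache$role_seeds <- seeds
  seeds
}

# archetype-specific accessory ("hypothetical protein") seed
.accessory_seed <- function(archetype, k, len = 240L) {
  .with_seed(.seed_from_label(sprintf("acc:%s:%d", archetype, k)),
             .random_protein(len))
}

#' Mutate a protein to an exact target identity
#'
#' Returns a sequence of equal length whose identity to \code{seq} is exactly
#' \code{round(target_identity * nchar(seq))} matching positions.
#' Substitution positions are drawn uniformly; each replacement residue is
#' drawn from the 20-letter alphabet excluding the original residue.
#'
#' @param seq Protein sequence (non-empty, standard alphabet).
#' @param target_identity Fraction in (0, 1].
#' @param seed Optional integer seed (RNG state is restored afterwards); if
#'   \code{NULL}, the ambient RNG stream is used.
#' @return Mutated protein string.
#' @export
mutate_protein <- function(seq, target_identity, seed = NULL) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (nchar(seq) == 0) stop("seq must be non-empty")
  if (!is.numeric(target_identity) || target_identity <= 0 ||
      target_identity > 1)
    stop("target_identity must be in (0, 1]")
  ch <- strsplit(seq, "")[[1]]
  if (!all(ch %in% AA20)) stop("seq must use the standard 20-letter alphabet")
  n_sub <- nchar(seq) - round(target_identity * nchar(seq))
  .with_seed(seed, {
    if (n_sub > 0) {
      pos <- sample.int(length(ch), n_sub)
      for (p in pos) ch[p] <- sample(setdiff(AA20, ch[p]), 1)
    }
    paste(ch, collapse = "")
  })
}

#' Sample a synthetic TOMM precursor peptide
#'
#' Builds leader + poly-Gly linker + core. The leader starts with Met and is
#' drawn from a composition containing no Cys/Ser/Thr; the core ends with a
#' block of heterocyclizable residues (C/S/T) sized so that the C-terminal
#' half of the full peptide (final \code{floor(L/2)} residues) has a C/S/T
#' fraction of at least \code{target_cst_fraction}.
#'
#' @param leader_length,core_length Segment lengths in residues (> 0).
#' @param target_cst_fraction Required C-terminal-half C/S/T fraction, in
#'   [0, 1].
#' @param gly_linker Length of the poly-Gly linker between leader and core.
#' @param seed Optional integer seed.
#' @return Protein string of length
#'   \code{leader_length + gly_linker + core_length}.
#' @export
sample_precursor <- function(leader_length, core_length, target_cst_fraction,
                             gly_linker = 0, seed = NULL) {
  stopifnot(leader_length > 0, core_length > 0, gly_linker >= 0,
            target_cst_fraction >= 0, target_cst_fraction <= 1)
  L <- leader_length + gly_linker + core_length
  half <- L %/% 2
  n_cst <- ceiling(target_cst_fraction * half)
  if (n_cst > core_length)
    stop("core too short to satisfy target_cst_fraction: needs at least ",
         n_cst, " residues")
  .with_seed(seed, {
    leader <- c("M", sample(.AA_NO_CST, leader_length - 1, replace = TRUE))
    core_head <- sample(.AA_NO_CST, core_length - n_cst, replace = TRUE)
    core_tail <- sample(c("C", "S", "T"), n_cst, replace = TRUE)
    paste(c(leader, rep("G", gly_linker), core_head, core_tail),
          collapse = "")
  })
}

## --- back-translation -----------------------------------------------------

# one fixed codon per residue (frequent E. coli usage, bacterial code);
# deterministic so translation round-trips exactly
.CODON_OF <- c(A = "GCG", R = "CGC", N = "AAC", D = "GAT", C = "TGC",
               Q = "CAG", E = "GAA", G = "GGC", H = "CAT", I = "ATT",
               L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCG",
               S = "AGC", T = "ACC", W = "TGG", Y = "TAT", V = "GTG")

#' Back-translate a protein with the fixed codon table
#'
#' Uses one deterministic codon per residue and appends a TAA stop, so that
#' translating the emitted CDS with the standard (bacterial) genetic code
#' reproduces the protein exactly.
#'
#' @param protein Protein string over the 20-letter alphabet.
#' @return DNA string of length \code{3 * (nchar(protein) + 1)}.
#' @export
back_translate <- function(protein) {
  ch <- strsplit(protein, "")[[1]]
  if (!all(ch %in% AA20)) stop("unknown residue in protein")
  paste(c(.CODON_OF[ch], "TAA"), collapse = "")
}

#' Reverse complement of a DNA string
#' @param dna DNA string(s) over A/C/G/T/N.
#' @return Character vector of reverse complements.
#' @export
revcomp_dna <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(dna)))
}

# translate a CDS (no frame shifting); codons with non-ACGT letters become X;
# stop codons become *
.translate_dna <- function(dna) {
  n <- nchar(dna) %/% 3
  if (n == 0) return("")
  codons <- substring(dna, 3 * seq_len(n) - 2, 3 * seq_len(n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
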