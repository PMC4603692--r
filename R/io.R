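## File I/O: FASTA via Biostrings, GFF3 parsing via rtracklayer (with a
## line-numbered validation pass), GFF3 writing done in-package so emitted
## files are byte-deterministic. Internal coordinates are 0-based half-open;
## GFF3 files are 1-based inclusive.

#' Write an annotation table as GFF3
#'
#' Emits one CDS feature per annotation row with \code{ID} and
#' \code{product} attributes, converting internal 0-based half-open
#' coordinates to GFF3 1-based inclusive.
#'
#' @param annotations Annotation data.frame (columns \code{gene_id},
#'   \code{genome_id}, \code{start}, \code{end}, \code{strand},
#'   \code{product}).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_gff3 <- function(annotations, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\ttommscan\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;product=%s",
                     annotations$genome_id, annotations$start + 1L,
                     annotations$end, annotations$strand,
                     annotations$gene_id, annotations$product))
  writeLines(lines, path)
  invisible(path)
}

#' Write a protein set as FASTA
#' @param proteins Named character vector.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_protein_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Write a generated genome bundle to disk
#'
#' Emits genome FASTA, GFF3 annotation, protein FASTA, the truth table as
#' TSV and JSON, and the generator config as JSON.
#'
#' @param bundle A \code{tomm_genome_bundle} from
#'   \code{\link{generate_genome}}.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix; defaults to the genome id.
#' @return Invisibly, a named vector of the written paths.
#' @export
write_genome_bundle <- function(bundle, dir, prefix = NULL) {
  stopifnot(inherits(bundle, "tomm_genome_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(prefix)) prefix <- bundle$genome$id
  p <- function(ext) file.path(dir, paste0(prefix, ext))
  dna <- Biostrings::DNAStringSet(stats::setNames(bundle$genome$sequence,
                                                  bundle$genome$id))
  Biostrings::writeXStringSet(dna, p(".fna"))
  write_gff3(bundle$annotations, p(".gff3"))
  write_protein_fasta(bundle$proteins, p(".faa"))
  utils::write.table(bundle$truth, p(".truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$truth, p(".truth.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(bundle$config, p(".config.json"), auto_unbox = TRUE,
                       digits = NA)
  paths <- c(fasta = p(".fna"), gff3 = p(".gff3"), proteins = p(".faa"),
             truth_tsv = p(".truth.tsv"), truth_json = p(".truth.json"),
             config = p(".config.json"))
  invisible(paths)
}

# 9-column structural validation; reports the first malformed line by number
.validate_gff3 <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9)
      stop("malformed GFF3 line ", i, ": expected 9 tab-separated fields, ",
           "got ", length(f))
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e) || s < 1 || e < s)
      stop("malformed GFF3 line ", i, ": bad coordinates '", f[4], "'..'",
           f[5], "'")
  }
  invisible(TRUE)
}

#' Read a genome bundle (FASTA + GFF3 + protein FASTA)
#'
#' Parses the three files into the internal representation: genome sequences
#' plus an annotation table with 0-based half-open coordinates. CDS features
#' are linked to their protein translations by \code{ID}; a CDS whose ID is
#' missing from the protein FASTA triggers a warning and an on-the-fly
#' translation from the genome (trailing stop removed).
#'
#' @param fasta Genome FASTA path.
#' @param gff3 GFF3 path (1-based inclusive coordinates; CDS features used).
#' @param protein_fasta Protein multi-FASTA keyed by gene ID; optional.
#' @return List with \code{genomes} (named character vector of DNA) and
#'   \code{annotations} (data.frame \code{gene_id}, \code{genome_id},
#'   \code{start}, \code{end}, \code{strand}, \code{product},
#'   \code{protein}).
#' @export
read_genome_bundle <- function(fasta, gff3, protein_fasta = NULL) {
  stopifnot(file.exists(fasta), file.exists(gff3))
  dna <- Biostrings::readDNAStringSet(fasta)
  genomes <- stats::setNames(as.character(dna),
                             sub("\\s.*$", "", names(dna)))
  .validate_gff3(gff3)
  gr <- rtracklayer::import(gff3, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0) stop("no CDS features in ", gff3)
  md <- S4Vectors::mcols(gr)
  ann <- data.frame(
    gene_id = as.character(md$ID),
    genome_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = if ("product" %in% colnames(md))
      as.character(md$product) else NA_character_,
    stringsAsFactors = FALSE)
  prots <- character(0)
  if (!is.null(protein_fasta) && file.exists(protein_fasta)) {
    aa <- Biostrings::readAAStringSet(protein_fasta)
    prots <- stats::setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  }
  ann$protein <- unname(prots[ann$gene_id])
  missing <- which(is.na(ann$protein))
  if (length(missing) > 0) {
    warning(length(missing), " CDS feature(s) missing from the protein ",
            "FASTA; translating on the fly")
    for (i in missing) {
      cds <- substr(genomes[[ann$genome_id[i]]], ann$start[i] + 1L,
                    ann$end[i])
      if (ann$strand[i] == "-") cds <- revcomp_dna(cds)
      ann$protein[i] <- sub("\\*$", "", .translate_dna(cds))
    }
  }
  list(genomes = genomes, annotations = ann)
}

#' Read anchor gene IDs from a HMMER domtblout-style table
#'
#' Adapter mirroring domain-based anchor retrieval: gene IDs listed in an
#' externally produced domain-search table are treated as anchors (or role
#' calls, keyed by model accession).
#'
#' @param path Path to a HMMER \code{--domtblout}-style whitespace-delimited
#'   file (comment lines start with \code{#}; column 1 is the target gene
#'   ID, column 4 the query model name, column 5 the model accession,
#'   column 7 the full-sequence e-value).
#' @return data.frame with columns \code{gene_id}, \code{model},
#'   \code{accession}, \code{evalue}.
#' @export
read_domtblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(gene_id = character(), model = character(),
                      accession = character(), evalue = numeric()))
  f <- strsplit(trimws(lines), "\\s+")
  data.frame(gene_id = vapply(f, `[`, "", 1),
             model = vapply(f, `[`, "", 4),
             accession = vapply(f, `[`, "", 5),
             evalue = as.numeric(vapply(f, `[`, "", 7)),
             stringsAsFactors = FALSE)
}
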