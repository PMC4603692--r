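# tiny hand-made genome: gene "MK" on the plus strand and its
# reverse-complement locus on the minus strand, with filler between
.tiny_bundle_files <- function(dir) {
  fill <- strrep("TTAATTAATTAA", 4)
  plus_cds <- "ATGAAATAA"
  minus_cds <- revcomp_dna("ATGAAATAA")
  genome <- paste0(plus_cds, fill, minus_cds)
  ann <- data.frame(
    gene_id = c("gA", "gB"), genome_id = "chr",
    start = c(0L, 9L + nchar(fill)),
    end = c(9L, 9L + nchar(fill) + 9L),
    strand = c("+", "-"), product = c("p1", "p2"),
    stringsAsFactors = FALSE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(chr = genome)), file.path(dir, "g.fna"))
  write_gff3(ann, file.path(dir, "g.gff3"))
  write_protein_fasta(c(gA = "MK", gB = "MK"), file.path(dir, "g.faa"))
  list(dir = dir, ann = ann, genome = genome)
}

test_that("GFF3 coordinates convert 1-based inclusive <-> 0-based half-open", {
  d <- withr::local_tempdir()
  tb <- .tiny_bundle_files(d)
  rb <- read_genome_bundle(file.path(d, "g.fna"), file.path(d, "g.gff3"),
                           file.path(d, "g.faa"))
  expect_equal(rb$annotations$start, tb$ann$start)
  expect_equal(rb$annotations$end, tb$ann$end)
  # first line of the written GFF3 body is 1-based inclusive
  l <- strsplit(readLines(file.path(d, "g.gff3"))[2], "\t")[[1]]
  expect_equal(as.integer(l[4:5]), c(1L, 9L))
  # strand symmetry: both strands translate to MK
  expect_equal(rb$annotations$protein, c("MK", "MK"))
})

test_that("missing proteins are translated on the fly with a warning", {
  d <- withr::local_tempdir()
  tb <- .tiny_bundle_files(d)
  write_protein_fasta(c(gA = "MK"), file.path(d, "g.faa")) # drop gB
  expect_warning(
    rb <- read_genome_bundle(file.path(d, "g.fna"), file.path(d, "g.gff3"),
                             file.path(d, "g.faa")),
    "translating on the fly")
  expect_equal(rb$annotations$protein[rb$annotations$gene_id == "gB"], "MK")
})

test_that("malformed GFF3 is reported with its line number", {
  d <- withr::local_tempdir()
  tb <- .tiny_bundle_files(d)
  lines <- readLines(file.path(d, "g.gff3"))
  lines[3] <- "chr\tbroken line with no tabs"
  writeLines(lines, file.path(d, "g.gff3"))
  expect_error(read_genome_bundle(file.path(d, "g.fna"),
                                  file.path(d, "g.gff3")),
               "line 3")
})

test_that("window arithmetic clamps at contig edges", {
  genome <- strrep("A", 100000)
  ann <- data.frame(gene_id = c("a1", "a2"), genome_id = "chr",
                    start = c(15000L, 3000L), end = c(16000L, 3900L),
                    strand = "+", product = "D",
                    protein = strrep("M", 333), stringsAsFactors = FALSE)
  r1 <- extract_region(genome, ann, "a1")
  expect_equal(c(r1$window_start, r1$window_end), c(5000L, 26000L))
  r2 <- extract_region(genome, ann, "a2")
  expect_equal(r2$window_start, 0L)
  expect_equal(r2$window_end, 13900L)
  expect_error(extract_region(genome, ann, "nope"), "not found")
})

test_that("intergenic segments tile the window without overlap", {
  b <- generate_genome(list(cluster_archetype("discrete_CD")), seed = 9,
                       genome_id = "gt")
  anc <- find_anchors(b$annotations)
  r <- extract_region(b$genome$sequence, b$annotations, anc$gene_id[1])
  # member genes sorted, included whole
  expect_true(!is.unsorted(r$members$start))
  spans <- rbind(
    data.frame(start = pmax(r$members$start, r$window_start),
               end = pmin(r$members$end, r$window_end)),
    r$intergenic)
  spans <- spans[order(spans$start), ]
  expect_equal(spans$start[1], r$window_start)
  expect_equal(spans$end[nrow(spans)], r$window_end)
  expect_true(all(spans$start[-1] == spans$end[-nrow(spans)]))
  # no overlap among intergenic segments
  ig <- r$intergenic[order(r$intergenic$start), ]
  if (nrow(ig) > 1) expect_true(all(ig$start[-1] >= ig$end[-nrow(ig)]))
})

test_that("round-trip: write members to GFF3 and re-read identically", {
  b <- generate_genome(list(cluster_archetype("fused_CD_with_F")), seed = 8,
                       genome_id = "gr")
  anc <- find_anchors(b$annotations)
  r <- extract_region(b$genome$sequence, b$annotations, anc$gene_id[1])
  d <- withr::local_tempdir()
  write_gff3(r$members, file.path(d, "m.gff3"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(b$genome$sequence, "gr")),
    file.path(d, "m.fna"))
  write_protein_fasta(stats::setNames(r$members$protein, r$members$gene_id),
                      file.path(d, "m.faa"))
  rb <- read_genome_bundle(file.path(d, "m.fna"), file.path(d, "m.gff3"),
                           file.path(d, "m.faa"))
  back <- rb$annotations[match(r$members$gene_id, rb$annotations$gene_id), ]
  expect_equal(back$start, r$members$start)
  expect_equal(back$end, r$members$end)
  expect_equal(back$strand, r$members$strand)
})

test_that("anchors on a seeded genome equal the truth-table D genes", {
  b <- generate_genome(list(cluster_archetype("discrete_CD"),
                            cluster_archetype("fused_CD"),
                            cluster_archetype("standalone_D_bottromycin"),
                            cluster_archetype("decoy_nonTOMM")),
                       seed = 5, genome_id = "gm")
  anc <- find_anchors(b$annotations)
  truth_anchors <- sort(b$truth$gene_id[b$truth$is_anchor])
  expect_equal(sort(anc$gene_id), truth_anchors)
  # anchor-list and domtbl adapters bypass alignment
  expect_equal(find_anchors(b$annotations,
                            anchor_ids = truth_anchors)$gene_id,
               find_anchors(b$annotations)$gene_id)
  d <- withr::local_tempdir()
  writeLines(c("# comment",
               sprintf("%s - 310 ycao IPR003776 100 1e-50", truth_anchors)),
             file.path(d, "hits.domtbl"))
  expect_equal(sort(find_anchors(b$annotations,
                                 domtbl = file.path(d, "hits.domtbl"))$gene_id),
               truth_anchors)
  # empty annotations give an empty result
  expect_equal(nrow(find_anchors(b$annotations[0, ])), 0)
})
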