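test_that("mutate_protein honours the exact-identity contract", {
  expect_equal(mutate_protein("MKTAYIAKQR", 1.0, seed = 5), "MKTAYIAKQR")
  set.seed(21)
  seed_seq <- random_protein(100)
  mut <- mutate_protein(seed_seq, 0.70, seed = 1)
  expect_equal(nchar(mut), 100)
  matches <- sum(strsplit(seed_seq, "")[[1]] == strsplit(mut, "")[[1]])
  expect_equal(matches, 70)
  # determinism
  expect_identical(mutate_protein(seed_seq, 0.5, seed = 7),
                   mutate_protein(seed_seq, 0.5, seed = 7))
  expect_error(mutate_protein("", 0.5), "non-empty")
  expect_error(mutate_protein("MK", 0), "target_identity")
  expect_error(mutate_protein("MK", 1.2), "target_identity")
})

test_that("sample_precursor places heterocyclizable residues as promised", {
  p1 <- sample_precursor(20, 20, 1.0, 0, seed = 2)
  expect_equal(nchar(p1), 40)
  tail20 <- strsplit(substr(p1, 21, 40), "")[[1]]
  expect_true(all(tail20 %in% c("C", "S", "T")))
  p2 <- sample_precursor(20, 20, 0.65, 5, seed = 3)
  expect_gte(cst_fraction(p2), 0.65)
  p3 <- sample_precursor(20, 20, 0.0, 0, seed = 4)
  half <- substr(p3, nchar(p3) - nchar(p3) %/% 2 + 1, nchar(p3))
  expect_false(any(strsplit(half, "")[[1]] %in% c("C", "S", "T")))
  expect_error(sample_precursor(50, 5, 0.9, 0), "core too short")
})

test_that("identical (config, seed) reproduce byte-identical output", {
  a <- generate_genome(list(cluster_archetype("fused_CD")), seed = 42)
  b <- generate_genome(list(cluster_archetype("fused_CD")), seed = 42)
  expect_identical(a$genome$sequence, b$genome$sequence)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$truth, b$truth)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_genome_bundle(a, d1)
  p2 <- write_genome_bundle(b, d2)
  for (k in seq_along(p1))
    expect_identical(readLines(p1[k]), readLines(p2[k]))
  # different seed changes the sequence
  c_ <- generate_genome(list(cluster_archetype("fused_CD")), seed = 43)
  expect_false(identical(a$genome$sequence, c_$genome$sequence))
})

test_that("translating each emitted CDS reproduces the emitted protein", {
  b <- generate_genome(list(cluster_archetype("discrete_CD"),
                            cluster_archetype("standalone_D_bottromycin")),
                       seed = 7, genome_id = "tt")
  for (i in seq_len(nrow(b$annotations))) {
    a <- b$annotations[i, ]
    cds <- substr(b$genome$sequence, a$start + 1, a$end)
    if (a$strand == "-") cds <- revcomp_dna(cds)
    # independent oracle: Biostrings translation
    tr <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                             no.init.codon = TRUE))
    expect_identical(sub("\\*$", "", tr), a$protein, info = a$gene_id)
    expect_equal(nchar(a$protein), (a$end - a$start) / 3 - 1)
  }
})

test_that("filler DNA yields zero ORFs at the default minimum length", {
  set.seed(31)
  for (len in c(500, 5000, 20000)) {
    f <- tommscan:::.filler_dna(len)
    expect_equal(nchar(f), len)
    expect_equal(nrow(six_frame_orfs(f, min_len_aa = 25)), 0)
  }
})

test_that("precursor placement modes land in the truth table correctly", {
  ann_b <- generate_genome(list(cluster_archetype("discrete_CD")), seed = 3,
                           genome_id = "ga")
  tp <- ann_b$truth[ann_b$truth$element == "precursor", ]
  expect_equal(tp$expected_detection, "1")
  expect_true(tp$gene_id %in% ann_b$annotations$gene_id)

  un_b <- generate_genome(list(cluster_archetype("fused_CD")), seed = 3,
                          genome_id = "gb")
  tp <- un_b$truth[un_b$truth$element == "precursor", ]
  expect_equal(tp$expected_detection, "2")
  expect_true(is.na(tp$gene_id)) # not annotated
  planted <- substr(un_b$genome$sequence, tp$start + 1, tp$end)
  prec <- tommscan:::.archetype_precursor(cluster_archetype("fused_CD"))
  expect_identical(planted, back_translate(prec)) # present in the DNA

  dec <- generate_genome(list(cluster_archetype("decoy_nonTOMM")), seed = 3,
                         genome_id = "gc")
  expect_false(any(dec$truth$is_tomm))
  expect_false(any(dec$truth$element == "precursor"))

  dist <- generate_genome(list(cluster_archetype(
    "fused_CD", precursor_plan = "distal")), seed = 3, genome_id = "gd")
  tp <- dist$truth[dist$truth$element == "precursor", ]
  anchor <- dist$truth[dist$truth$is_anchor, ]
  expect_equal(tp$expected_detection, "none")
  expect_gte(tp$start, anchor$end + 10000) # planted beyond the window
})

test_that("archetype invariants are enforced", {
  bad_decoy <- tommscan:::.default_gene_plans()$decoy_nonTOMM
  bad_decoy$role[1] <- "C"
  expect_error(cluster_archetype("decoy_nonTOMM", gene_plan = bad_decoy),
               "no C/CD")
  pp <- tommscan:::.default_precursor_params("discrete_CD")
  pp$target_cst_fraction <- 1.5
  expect_error(cluster_archetype("discrete_CD", precursor_params = pp),
               "target_cst_fraction")
  expect_error(cluster_archetype("no_such_archetype"), "unknown archetype")
})
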