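test_that("cst_fraction counts the final floor(L/2) residues", {
  expect_equal(cst_fraction("AAAASSSS"), 1.0)
  expect_equal(cst_fraction("SSSSAAAA"), 0.0)
  expect_equal(cst_fraction("MAGCSTAGCS"), 3 / 5) # half = "TAGCS"
  # odd length: half = final floor(L/2)
  expect_equal(cst_fraction("AAAAASS"), 2 / 3)
  expect_equal(cst_fraction("GGGG", include_gly = TRUE), 1.0)
  expect_equal(cst_fraction("GGGG"), 0.0)
  expect_error(cst_fraction("M"), "length >= 2")
})

test_that("method-1 thresholds are pinned at 450 bp (strict) / 0.45 (incl.)", {
  # CDS span includes the stop: span = 3 * (len_aa + 1)
  at_450 <- sample_precursor(75, 74, 1.0, 0, seed = 1)   # 149 aa -> 450 bp
  under <- sample_precursor(50, 49, 1.0, 0, seed = 1)    # 99 aa -> 300 bp
  exactly_045 <- {
    # 40 aa, half = 20: exactly 9/20 = 45% C/S/T in the half
    p <- sample_precursor(20, 20, 0.90, 0, seed = 2)
    stopifnot(cst_fraction(p) == 0.9) # 18/20
    head_ <- substr(p, 1, 20)
    tail_ <- strsplit(substr(p, 21, 40), "")[[1]]
    cst_pos <- which(tail_ %in% c("C", "S", "T"))
    tail_[cst_pos[1:9]] <- "A" # 18 -> 9
    paste0(head_, paste(tail_, collapse = ""))
  }
  expect_equal(cst_fraction(exactly_045), 0.45)
  just_below <- sub("S|T|C", "A", exactly_045) # knock one more out
  prot <- c(anchor = strrep("M", 100), g450 = at_450, g045 = exactly_045,
            g044 = just_below, gok = under)
  r <- make_region(prot, "gZ:anchor")
  got <- method1_annotated(r)
  expect_setequal(got$gene_id, c("g045", "gok"))
  # inclusive at exactly 0.45; strict below 450 bp; anchor never a candidate
  expect_true(all(got$end - got$start < 450))
})

test_that("six_frame_orfs handles the smallest case on both strands", {
  got <- six_frame_orfs("ATGAAATAA", min_len_aa = 2, max_len_aa = 150)
  expect_equal(nrow(got), 1)
  expect_equal(got$peptide, "MK")
  expect_equal(c(got$start, got$end), c(0, 9))
  expect_equal(got$strand, "+")
  expect_equal(got$frame, 0)
  rc <- six_frame_orfs(revcomp_dna("ATGAAATAA"), min_len_aa = 2,
                       max_len_aa = 150)
  expect_equal(rc$peptide, "MK")
  expect_equal(rc$strand, "-")
  expect_equal(c(rc$start, rc$end), c(0, 9))
})

test_that("six_frame_orfs equals the brute-force enumerator", {
  set.seed(41)
  for (k in 1:30) {
    dna <- random_dna(300)
    got <- six_frame_orfs(dna, min_len_aa = 2, max_len_aa = 150)
    exp <- oracle_orfs(dna, min_len_aa = 2, max_len_aa = 150)
    rownames(got) <- rownames(exp) <- NULL
    expect_equal(got, exp, info = paste("seq", k))
  }
  # non-ACGT codons never start an ORF
  withN <- six_frame_orfs("ATNAAATAAATGAAATAA", min_len_aa = 2)
  expect_false(any(withN$start == 0 & withN$strand == "+"))
})

test_that("method-2 pins 150 aa strict, 0.65 inclusive, and dedups", {
  pep149 <- paste0("M", strrep("S", 148))
  pep150 <- paste0("M", strrep("S", 149))
  sep <- strrep("TTAATTAATTAA", 2)
  dna <- paste0(sep, back_translate(pep149), sep, back_translate(pep150),
                sep, back_translate(pep149), sep)
  r <- make_dna_region(dna)
  got <- method2_sixframe(r)
  # the 150-aa ORF is excluded; the two identical 149-aa copies dedup to one
  expect_equal(nrow(got), 1)
  expect_equal(got$length_aa, 149)
  expect_equal(got$sequence, pep149)
  expect_equal(got$start, nchar(sep)) # first copy kept
  # raising the threshold never adds candidates
  lo <- method2_sixframe(r, min_cst = 0.5)
  hi <- method2_sixframe(r, min_cst = 0.9)
  expect_true(all(hi$sequence %in% lo$sequence))
  # exactly 0.65 is included
  p65 <- sample_precursor(20, 20, 0.65, 0, seed = 6)
  stopifnot(abs(cst_fraction(p65) - 0.65) < 1e-9)
  r65 <- make_dna_region(paste0(sep, back_translate(p65), sep))
  expect_equal(nrow(method2_sixframe(r65, min_cst = 0.65)), 1)
})

test_that("scan_all merges methods and flags regions", {
  b <- generate_genome(list(cluster_archetype("discrete_CD"),
                            cluster_archetype("decoy_nonTOMM")),
                       seed = 6, genome_id = "gs")
  anc <- find_anchors(b$annotations)
  regs <- extract_regions(stats::setNames(b$genome$sequence, "gs"),
                          b$annotations, anc)
  sc <- scan_all(regs)
  truth_prec <- b$truth[b$truth$element == "precursor", ]
  expect_equal(nrow(sc$candidates), 1)
  expect_equal(sc$candidates$start, truth_prec$start)
  expect_equal(sc$candidates$method, "1_annotated")
  dec_region <- grep("decoy", names(regs), value = TRUE)
  # the decoy cluster has no precursor at all
  decoy_anchor <- b$truth$gene_id[b$truth$is_anchor &
                                    b$truth$archetype == "decoy_nonTOMM"]
  dflag <- sc$flags[grepl(decoy_anchor, sc$flags$region_id), ]
  expect_false(dflag$has_precursor)
})
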