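# construct homologous region pairs from random proteins
.twin_regions <- function(n_genes, seed = 1, strands = NULL,
                          reverse_b = FALSE) {
  set.seed(seed)
  prots <- stats::setNames(replicate(n_genes, random_protein(120)),
                           sprintf("a%02d", seq_len(n_genes)))
  if (is.null(strands)) strands <- rep("+", n_genes)
  ra <- make_region(prots, "gA:a01", strands = strands)
  prots_b <- stats::setNames(prots, sprintf("b%02d", seq_len(n_genes)))
  strands_b <- strands
  if (reverse_b) {
    prots_b <- rev(prots_b)
    strands_b <- rev(ifelse(strands == "+", "-", "+"))
  }
  rb <- make_region(prots_b, "gB:b01", strands = strands_b)
  list(a = ra, b = rb)
}

test_that("identical regions map fully and score by the stated formula", {
  tw <- .twin_regions(8)
  m <- map_hits(tw$a, tw$b)
  expect_equal(nrow(m), 8)
  expect_equal(synteny_score(m), 7)
  rs <- region_score(tw$a, tw$b)
  expect_equal(rs$total, 0.5 * 8 + 0.5 * 7)
  # the spec's 21-gene example: 0.5*21 + 0.5*20 = 20.5
  tw21 <- .twin_regions(21, seed = 2)
  expect_equal(region_score(tw21$a, tw21$b)$total, 20.5)
})

test_that("unrelated regions score zero", {
  set.seed(3)
  ra <- make_region(stats::setNames(replicate(5, random_protein(100)),
                                    paste0("a", 1:5)), "gA:a1")
  rb <- make_region(stats::setNames(replicate(5, random_protein(100)),
                                    paste0("b", 1:5)), "gB:b1")
  rs <- region_score(ra, rb)
  expect_equal(rs$hit_count, 0)
  expect_equal(rs$total, 0)
})

test_that("mapping is one-to-one even with duplicated genes", {
  set.seed(4)
  p <- random_protein(150)
  near <- mutate_protein(p, 0.9, seed = 1)
  ra <- make_region(c(a1 = p, a2 = random_protein(150)), "gA:a1")
  rb <- make_region(c(b1 = p, b2 = near), "gB:b1")
  m <- map_hits(ra, rb)
  # a1 maps to the best copy (exact match b1) exactly once
  expect_equal(sum(m$gene_a == "a1"), 1)
  expect_equal(m$gene_b[m$gene_a == "a1"], "b1")
})

test_that("synteny tolerates whole-cluster inversion and matches brute force", {
  strands <- c("+", "+", "-", "+", "+", "-", "+", "+")
  tw <- .twin_regions(8, seed = 5, strands = strands, reverse_b = TRUE)
  m <- map_hits(tw$a, tw$b)
  expect_equal(nrow(m), 8)
  expect_equal(synteny_score(m), 7) # inversion-tolerant
  expect_equal(synteny_score(m), oracle_synteny(m))
  # random permutations against the brute-force adjacency count
  set.seed(6)
  for (k in 1:20) {
    perm <- sample(8)
    mp <- data.frame(gene_a = paste0("a", 1:8), gene_b = paste0("b", perm),
                     raw_score = 100, pos_a = 1:8, pos_b = perm,
                     strand_a = sample(c("+", "-"), 8, TRUE),
                     strand_b = sample(c("+", "-"), 8, TRUE),
                     stringsAsFactors = FALSE)
    expect_equal(synteny_score(mp), oracle_synteny(mp))
  }
})

test_that("region scores are symmetric", {
  set.seed(7)
  for (k in 1:3) {
    base <- replicate(6, random_protein(110))
    pa <- stats::setNames(vapply(base, mutate_protein, "", 0.8),
                          paste0("a", 1:6))
    pb <- stats::setNames(vapply(base, mutate_protein, "", 0.8),
                          paste0("b", 1:6))
    ra <- make_region(pa, "gA:a1")
    rb <- make_region(pb, "gB:b1")
    expect_equal(region_score(ra, rb)$total, region_score(rb, ra)$total)
  }
})

test_that("grouping is strict at the threshold and single-linkage", {
  scores <- data.frame(region_a = c("r1", "r2", "r1"),
                       region_b = c("r2", "r3", "r3"),
                       hit_count = 0L, synteny_score = 0L,
                       total = c(10.0, 10.5, 2.0))
  fam <- group_families(scores, region_ids = c("r1", "r2", "r3"))
  # exactly 10.0 does not link: r1 alone, r2-r3 together
  expect_equal(sort(unique(fam$family_id)), c("r1", "r2"))
  expect_equal(fam$family_id[fam$region_id == "r1"], "r1")
  expect_equal(fam$family_id[fam$region_id == "r3"], "r2")
  # chain a-b, b-c above, a-c below: one family
  chain <- data.frame(region_a = c("a", "b", "a"),
                      region_b = c("b", "c", "c"),
                      total = c(11, 11, 1))
  fc <- group_families(chain)
  expect_equal(length(unique(fc$family_id)), 1)
})

test_that("families partition the regions deterministically", {
  set.seed(8)
  ids <- paste0("r", 1:12)
  pairs <- t(combn(ids, 2))
  scores <- data.frame(region_a = pairs[, 1], region_b = pairs[, 2],
                       total = sample(c(0, 5, 12, 20), nrow(pairs), TRUE))
  fam <- group_families(scores, region_ids = ids)
  expect_setequal(fam$region_id, ids)
  expect_equal(anyDuplicated(fam$region_id), 0) # partition
  # input order invariance
  shuf <- scores[sample(nrow(scores)), ]
  expect_identical(group_families(shuf, region_ids = sample(ids)), fam)
  # raising the threshold only splits, never merges
  fam_hi <- group_families(scores, region_ids = ids, threshold = 15)
  for (f in unique(fam_hi$family_id)) {
    members <- fam_hi$region_id[fam_hi$family_id == f]
    expect_equal(length(unique(fam$family_id[fam$region_id %in% members])),
                 1)
  }
})
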