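# Shared fixtures, built in code at test time.

# Hand-build a tomm_region from proteins (no genome DNA needed for the
# family/classifier operations; dna/intergenic left empty).
make_region <- function(proteins, region_id, strands = NULL,
                        anchor = names(proteins)[1], dna = "",
                        window = c(0L, 0L), spacing = 1000L) {
  n <- length(proteins)
  if (is.null(strands)) strands <- rep("+", n)
  starts <- as.integer(seq(0, by = spacing, length.out = n))
  members <- data.frame(
    gene_id = names(proteins), genome_id = sub(":.*$", "", region_id),
    start = starts, end = starts + 3L * (nchar(proteins) + 1L),
    strand = strands, product = "protein", protein = unname(proteins),
    stringsAsFactors = FALSE)
  structure(list(region_id = region_id,
                 genome_id = sub(":.*$", "", region_id),
                 anchor_gene_id = anchor,
                 window_start = window[1], window_end = window[2],
                 members = members,
                 intergenic = data.frame(start = integer(), end = integer()),
                 dna = dna),
            class = "tomm_region")
}

# region whose window DNA is exactly the given sequence (for ORF screens)
make_dna_region <- function(dna, region_id = "gX:anchor",
                            anchor = "anchor") {
  structure(list(region_id = region_id, genome_id = "gX",
                 anchor_gene_id = anchor, window_start = 0L,
                 window_end = nchar(dna),
                 members = data.frame(
                   gene_id = character(), genome_id = character(),
                   start = integer(), end = integer(),
                   strand = character(), product = character(),
                   protein = character(), stringsAsFactors = FALSE),
                 intergenic = data.frame(start = 0L, end = nchar(dna)),
                 dna = dna),
            class = "tomm_region")
}

# the acceptance cohort: 33 planted clusters spanning every archetype,
# built once per test run and reused (generation + full pipeline are the
# expensive steps)
.fixture_env <- new.env(parent = emptyenv())

acceptance_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_cohort(
      c(discrete_CD = 6, fused_CD = 6, fused_CD_with_F = 6,
        standalone_D_bottromycin = 6, decoy_nonTOMM = 6,
        fused_CD_distal = 3),
      seed = 20260910)
  }
  .fixture_env$cohort
}

acceptance_pipeline <- function() {
  if (is.null(.fixture_env$pipeline)) {
    .fixture_env$pipeline <- run_tomm_pipeline(acceptance_cohort()$bundles,
                                               seed = 20260910)
  }
  .fixture_env$pipeline
}
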