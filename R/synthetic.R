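## Synthetic genome generator: plants TOMM-like gene clusters of the
## canonical architectures (discrete C+D, fused CD, CD+B+F, stand-alone-D
## bottromycin-like) plus decoy non-TOMM YcaO contexts into filler DNA, and
## emits the ground truth alongside, so the whole pipeline is testable
## without downloads.

# 12-mer carrying a stop codon in all six reading frames (it is its own
# reverse complement). Filler is laced with it so no spurious ORF can reach
# the six-frame scanner's default minimum length.
.STOP_CASSETTE <- "TTAATTAATTAA"

.rand_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# filler DNA of exact length n: alternating stop cassettes and short random
# stretches (<= 36 bp), starting with a cassette. In-frame stops in every
# frame on both strands occur at least every ~20 codons.
.filler_dna <- function(n) {
  if (n <= 0) return("")
  cas <- .STOP_CASSETTE
  if (n <= 24) return(substr(strrep(cas, 2), 1, n))
  parts <- list(cas)
  len <- 12L
  while (len + 12L <= n) {
    rand_len <- min(36L, n - len - 12L)
    if (rand_len > 0) {
      parts <- c(parts, .rand_dna(rand_len))
      len <- len + rand_len
    }
    parts <- c(parts, cas)
    len <- len + 12L
  }
  s <- paste(unlist(parts), collapse = "")
  if (nchar(s) < n) s <- paste0(s, substr(cas, 1, n - nchar(s)))
  s
}

.plan_row <- function(role, strand = "+", seed = role) {
  data.frame(role = role, strand = strand, seed = seed,
             stringsAsFactors = FALSE)
}

.default_gene_plans <- function() {
  g <- .plan_row
  list(
    discrete_CD = rbind(
      g("accessory", "+", "acc1"), g("transporter"), g("precursor"),
      g("C"), g("D"), g("B"), g("protease", "-"),
      g("accessory", "+", "acc2"), g("accessory", "-", "acc3"),
      g("accessory", "+", "acc4"), g("accessory", "+", "acc5"),
      g("accessory", "+", "acc6")),
    fused_CD = rbind(
      g("accessory", "+", "acc1"), g("accessory", "-", "acc2"),
      g("transporter"), g("precursor"), g("CD"), g("B"),
      g("accessory", "+", "acc3"), g("protease"),
      g("accessory", "-", "acc4"), g("accessory", "+", "acc5"),
      g("accessory", "+", "acc6"), g("accessory", "+", "acc7"),
      g("accessory", "+", "acc8")),
    fused_CD_with_F = rbind(
      g("accessory", "+", "acc1"), g("F"), g("CD"), g("B"),
      g("methyltransferase"), g("transporter", "-"), g("precursor"),
      g("accessory", "+", "acc2"), g("accessory", "+", "acc3"),
      g("accessory", "-", "acc4"), g("accessory", "+", "acc5"),
      g("accessory", "+", "acc6")),
    standalone_D_bottromycin = rbind(
      g("precursor"), g("D", "+", "D_bottromycin"),
      g("D", "+", "D_bottromycin"), g("radical_SAM"),
      g("methyltransferase"), g("accessory", "+", "acc1"),
      g("protease", "-"), g("accessory", "+", "acc2"),
      g("accessory", "+", "acc3"), g("accessory", "+", "acc4"),
      g("accessory", "+", "acc5"), g("accessory", "+", "acc6")),
    decoy_nonTOMM = rbind(
      g("accessory", "+", "acc1"), g("D"), g("transporter", "-"),
      g("protease"), g("methyltransferase"), g("accessory", "+", "acc2"),
      g("accessory", "+", "acc3"), g("accessory", "-", "acc4"),
      g("accessory", "+", "acc5"), g("accessory", "+", "acc6"),
      g("accessory", "+", "acc7"), g("accessory", "+", "acc8")))
}

.default_precursor_params <- function(name) {
  switch(name,
         discrete_CD = list(leader_length_aa = 20, core_length_aa = 22,
                            target_cst_fraction = 0.50, gly_linker_length = 3),
         fused_CD = list(leader_length_aa = 18, core_length_aa = 23,
                         target_cst_fraction = 0.70, gly_linker_length = 4),
         fused_CD_with_F = list(leader_length_aa = 22, core_length_aa = 24,
                                target_cst_fraction = 0.50,
                                gly_linker_length = 2),
         standalone_D_bottromycin = list(leader_length_aa = 10,
                                         core_length_aa = 34,
                                         target_cst_fraction = 0.10,
                                         gly_linker_length = 0),
         NULL)
}

.default_precursor_plan <- function(name) {
  switch(name,
         discrete_CD = "annotated",
         fused_CD = "unannotated_intergenic",
         fused_CD_with_F = "annotated",
         standalone_D_bottromycin = "annotated",
         decoy_nonTOMM = "absent")
}

#' Define a planted cluster archetype
#'
#' An archetype is the ground-truth plan for one planted gene cluster: an
#' ordered, stranded gene plan plus the precursor placement mode and
#' composition parameters. The five bundled archetype names mirror the
#' canonical TOMM architectures (discrete C+D, fused CD, CD+B+F,
#' stand-alone-D bottromycin-like) plus a decoy non-TOMM YcaO context.
#'
#' @param name One of \code{discrete_CD}, \code{fused_CD},
#'   \code{fused_CD_with_F}, \code{standalone_D_bottromycin},
#'   \code{decoy_nonTOMM}.
#' @param precursor_plan One of \code{annotated} (a real, annotated gene),
#'   \code{unannotated_intergenic} (present in the DNA, missing from the
#'   annotation), \code{absent}, or \code{distal} (planted > 10 kb from the
#'   anchor, emulating distally encoded precursors); defaults per archetype.
#' @param precursor_params List with \code{leader_length_aa},
#'   \code{core_length_aa}, \code{target_cst_fraction},
#'   \code{gly_linker_length}; defaults per archetype.
#' @param gene_plan Optional data.frame(role, strand, seed) overriding the
#'   bundled plan (gene order within clusters is not biologically fixed).
#' @return Object of class \code{"tomm_archetype"}.
#' @export
cluster_archetype <- function(name,
                              precursor_plan = NULL,
                              precursor_params = NULL,
                              gene_plan = NULL) {
  plans <- .default_gene_plans()
  if (is.null(gene_plan)) {
    if (!name %in% names(plans))
      stop("unknown archetype '", name, "' and no gene_plan given")
    gene_plan <- plans[[name]]
  }
  if (is.null(precursor_plan)) precursor_plan <- .default_precursor_plan(name)
  if (is.null(precursor_params)) precursor_params <-
      .default_precursor_params(name)
  precursor_plan <- match.arg(precursor_plan,
                              c("annotated", "unannotated_intergenic",
                                "absent", "distal"))
  n_d <- sum(gene_plan$role == "D" & gene_plan$role != "precursor") +
    sum(gene_plan$role == "CD")
  is_tomm <- name != "decoy_nonTOMM"
  if (name == "decoy_nonTOMM") {
    if (any(gene_plan$role %in% c("C", "CD")) ||
        any(gene_plan$role == "precursor"))
      stop("decoy_nonTOMM must contain no C/CD gene and no precursor")
    if (!any(gene_plan$role == "D")) stop("decoy_nonTOMM needs a D gene")
  } else if (name == "standalone_D_bottromycin") {
    if (sum(gene_plan$role == "D") != 2)
      stop("standalone_D_bottromycin requires exactly two D-role genes")
  } else if (is_tomm && n_d != 1) {
    stop("archetype '", name, "' must contain exactly one D or CD gene")
  }
  pp <- precursor_params
  if (!is.null(pp) && (pp$target_cst_fraction < 0 ||
                       pp$target_cst_fraction > 1))
    stop("target_cst_fraction must be in [0, 1]")
  if (precursor_plan != "absent" && is.null(pp))
    stop("precursor_params required when a precursor is planted")
  structure(list(name = name, gene_plan = gene_plan,
                 precursor_plan = precursor_plan, precursor_params = pp,
                 is_tomm = is_tomm),
            class = "tomm_archetype")
}

#' @export
print.tomm_archetype <- function(x, ...) {
  cat(sprintf("<tomm_archetype> %s: %d genes, precursor %s, %s\n",
              x$name, nrow(x$gene_plan), x$precursor_plan,
              if (x$is_tomm) "TOMM" else "non-TOMM"))
  invisible(x)
}

# the archetype-level precursor peptide (identical across cluster instances,
# like the near-identical precursors of real MccB17/faecalisin families)
.archetype_precursor <- function(arch) {
  pp <- arch$precursor_params
  sample_precursor(pp$leader_length_aa, pp$core_length_aa,
                   pp$target_cst_fraction, pp$gly_linker_length,
                   seed = .seed_from_label(paste0("prec:", arch$name)))
}

.seed_protein_for <- function(arch, seed_key) {
  if (grepl("^acc", seed_key)) {
    k <- as.integer(sub("^acc", "", seed_key))
    .accessory_seed(arch$name, k)
  } else {
    seeds <- role_seed_sequences()
    if (!seed_key %in% names(seeds)) stop("unknown seed key: ", seed_key)
    unname(seeds[[seed_key]])
  }
}

# expected detection method given the peptide, its CDS span and placement
.expected_detection <- function(peptide, span_bp, plan,
                                min_orf_aa = 25) {
  L <- nchar(peptide)
  cst <- cst_fraction(peptide)
  if (plan == "annotated" && span_bp < 450 && cst >= 0.45) return("1")
  if (plan %in% c("annotated", "unannotated_intergenic") &&
      L < 150 && L >= min_orf_aa && cst >= 0.65) return("2")
  "none"
}

#' Generate a synthetic genome with planted clusters
#'
#' Lays out each archetype's genes in plan order, back-translated with the
#' fixed codon table, separated by stop-cassette-laced filler DNA. Annotated
#' genes (including \code{annotated} precursors) go into the annotation
#' table; \code{unannotated_intergenic} precursors are present in the DNA
#' only; \code{distal} precursors are planted > 10 kb from the anchor gene.
#' Filler contains in-frame stop codons every ~20 codons in all six frames,
#' so no spurious ORF of >= 25 codons can arise from it.
#'
#' @param archetypes List of \code{\link{cluster_archetype}} objects (or a
#'   character vector of archetype names).
#' @param spacing_bp Filler length between planted clusters (and flanking
#'   each end); >= 0, default 12000 so neighbouring cluster windows never
#'   overlap.
#' @param seed Integer seed; identical (config, seed) give byte-identical
#'   output.
#' @param identity Per-gene mutation identity to the role seed (homolog
#'   family realization); default 0.85, giving ~72 \% pairwise identity
#'   between instances.
#' @param genome_id Replicon identifier.
#' @param intergene_bp Filler length between genes within a cluster.
#' @return Object of class \code{"tomm_genome_bundle"}: list with
#'   \code{genome} (list \code{id}, \code{sequence}), \code{annotations}
#'   (0-based half-open coordinates, CDS spans include the stop codon),
#'   \code{proteins} (named vector), \code{truth} (the truth table) and
#'   \code{config}.
#' @export
generate_genome <- function(archetypes, spacing_bp = 12000, seed = 1,
                            identity = 0.85, genome_id = "synth_g1",
                            intergene_bp = 108) {
  if (is.character(archetypes))
    archetypes <- lapply(archetypes, cluster_archetype)
  stopifnot(length(archetypes) >= 1, spacing_bp >= 0)
  lapply(archetypes, function(a) stopifnot(inherits(a, "tomm_archetype")))
  .with_seed(seed, {
    parts <- character(0)
    pos <- 0L
    add <- function(s) {
      parts[[length(parts) + 1L]] <<- s
      pos <<- pos + nchar(s)
    }
    ann <- list(); truth <- list(); prots <- character(0)
    add(.filler_dna(spacing_bp))
    for (ci in seq_along(archetypes)) {
      arch <- archetypes[[ci]]
      cluster_id <- sprintf("%s_c%02d", genome_id, ci)
      plan <- arch$gene_plan
      prec_seq <- if (arch$precursor_plan != "absent")
        .archetype_precursor(arch) else NULL
      anchor_end <- NA_integer_
      for (k in seq_len(nrow(plan))) {
        role <- plan$role[k]
        is_prec <- role == "precursor"
        if (is_prec && arch$precursor_plan %in% c("absent", "distal")) next
        if (is_prec && arch$precursor_plan == "unannotated_intergenic") {
          # plant in intergenic DNA: cassette guarantees the ORF starts at
          # the planted ATG; omit from the annotation table
          dna <- back_translate(prec_seq)
          add(.filler_dna(60))
          add(.STOP_CASSETTE)
          p_start <- pos
          add(dna)
          truth[[length(truth) + 1L]] <- data.frame(
            genome_id = genome_id, cluster_id = cluster_id,
            archetype = arch$name, element = "precursor", role = "precursor",
            gene_id = NA_character_, start = p_start, end = pos,
            strand = "+", is_anchor = FALSE, is_tomm = arch$is_tomm,
            expected_detection = .expected_detection(
              prec_seq, nchar(dna), "unannotated_intergenic"),
            stringsAsFactors = FALSE)
          add(.filler_dna(60))
          next
        }
        protein <- if (is_prec) prec_seq else
          mutate_protein(.seed_protein_for(arch, plan$seed[k]), identity)
        dna <- back_translate(protein)
        if (plan$strand[k] == "-") dna <- revcomp_dna(dna)
        gene_id <- sprintf("%s_g%02d_%s", cluster_id, k, role)
        g_start <- pos
        add(dna)
        is_anchor <- role %in% c("D", "CD")
        if (is_anchor) anchor_end <- pos
        ann[[length(ann) + 1L]] <- data.frame(
          gene_id = gene_id, genome_id = genome_id, start = g_start,
          end = pos, strand = plan$strand[k], product = role,
          protein = protein, stringsAsFactors = FALSE)
        prots[gene_id] <- protein
        truth[[length(truth) + 1L]] <- data.frame(
          genome_id = genome_id, cluster_id = cluster_id,
          archetype = arch$name,
          element = if (is_prec) "precursor" else "gene", role = role,
          gene_id = gene_id, start = g_start, end = pos,
          strand = plan$strand[k], is_anchor = is_anchor,
          is_tomm = arch$is_tomm,
          expected_detection = if (is_prec) .expected_detection(
            prec_seq, nchar(dna), "annotated") else NA_character_,
          stringsAsFactors = FALSE)
        if (k < nrow(plan)) add(.filler_dna(intergene_bp))
      }
      # trailing spacer, with the distal precursor planted > 10 kb out
      if (arch$precursor_plan == "distal") {
        if (is.na(anchor_end)) stop("distal precursor requires an anchor")
        dna <- back_translate(prec_seq)
        pad <- (anchor_end + 10000L + 300L) - pos
        if (pad < 24) stop("overlapping planted elements: no room for ",
                           "distal precursor")
        add(.filler_dna(pad - 12L))
        add(.STOP_CASSETTE)
        p_start <- pos
        add(dna)
        truth[[length(truth) + 1L]] <- data.frame(
          genome_id = genome_id, cluster_id = cluster_id,
          archetype = arch$name, element = "precursor", role = "precursor",
          gene_id = NA_character_, start = p_start, end = pos, strand = "+",
          is_anchor = FALSE, is_tomm = arch$is_tomm,
          expected_detection = "none", stringsAsFactors = FALSE)
        rest <- spacing_bp - (pad + nchar(dna))
        add(.filler_dna(max(rest, 60L)))
      } else {
        add(.filler_dna(spacing_bp))
      }
    }
    sequence <- paste(parts, collapse = "")
    annotations <- do.call(rbind, ann)
    truth <- do.call(rbind, truth)
    rownames(annotations) <- rownames(truth) <- NULL
    # invariant: planted elements must not overlap and must fit the genome
    el <- truth[order(truth$start), ]
    if (any(el$end[-nrow(el)] > el$start[-1]) ||
        any(el$end > nchar(sequence)))
      stop("overlapping planted elements")
    structure(list(
      genome = list(id = genome_id, sequence = sequence),
      annotations = annotations, proteins = prots, truth = truth,
      config = list(archetypes = vapply(archetypes, `[[`, "", "name"),
                    precursor_plans = vapply(archetypes, `[[`, "",
                                             "precursor_plan"),
                    spacing_bp = spacing_bp, seed = seed,
                    identity = identity, intergene_bp = intergene_bp)),
      class = "tomm_genome_bundle")
  })
}

#' @export
print.tomm_genome_bundle <- function(x, ...) {
  cat(sprintf("<tomm_genome_bundle> %s: %d bp, %d genes, %d planted clusters\n",
              x$genome$id, nchar(x$genome$sequence), nrow(x$annotations),
              length(unique(x$truth$cluster_id))))
  invisible(x)
}

#' Generate a cohort of single-cluster genomes
#'
#' One genome per planted cluster, cycling over the requested archetypes.
#' Names of \code{counts} may carry a \code{"_distal"} suffix to request the
#' distal-precursor variant of an archetype.
#'
#' @param counts Named integer vector: clusters per archetype, e.g.
#'   \code{c(discrete_CD = 6, fused_CD = 6, fused_CD_with_F = 6,
#'   standalone_D_bottromycin = 6, decoy_nonTOMM = 6, fused_CD_distal = 3)}.
#' @param seed Integer master seed; each genome gets a derived sub-seed.
#' @param identity Per-gene mutation identity (see
#'   \code{\link{generate_genome}}).
#' @param spacing_bp Flanking filler per genome.
#' @return List with \code{bundles} (list of genome bundles) and
#'   \code{truth} (combined truth table).
#' @export
generate_cohort <- function(counts, seed = 1, identity = 0.85,
                            spacing_bp = 12000) {
  stopifnot(length(counts) >= 1, !is.null(names(counts)))
  specs <- rep(names(counts), counts)
  bundles <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    nm <- specs[i]
    distal <- grepl("_distal$", nm)
    base <- sub("_distal$", "", nm)
    arch <- cluster_archetype(base,
                              precursor_plan = if (distal) "distal" else NULL)
    bundles[[i]] <- generate_genome(
      list(arch), spacing_bp = spacing_bp,
      seed = (seed * 1000L + i) %% .Machine$integer.max,
      identity = identity, genome_id = sprintf("g%03d", i))
  }
  truth <- do.call(rbind, lapply(bundles, `[[`, "truth"))
  rownames(truth) <- NULL
  list(bundles = bundles, truth = truth)
}
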