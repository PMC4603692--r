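---
title: "Mining genomes for TOMM biosynthetic gene clusters with tommscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining genomes for TOMM biosynthetic gene clusters with tommscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Thiazole/oxazole-modified microcins (TOMMs) are ribosomally synthesized and
post-translationally modified peptides (RiPPs) defined by azol(in)e
heterocycles installed on Cys/Ser/Thr residues of a short precursor peptide.
The defining marker of a TOMM biosynthetic gene cluster is the
ATP-dependent cyclodehydratase: a YcaO-superfamily enzyme (the D protein),
usually partnered with an E1-like leader-binding protein (the C protein),
often expressed as a single CD fusion. Because the D protein is the one
component that is never dispensed with, genome mining for TOMMs anchors on
YcaO homologs and then has to separate true TOMM neighbourhoods from the
substantial population of non-TOMM YcaO contexts.

`tommscan` implements that workflow end to end:

1. locate anchor (D/YcaO) genes by local-alignment similarity to a
   reference panel (or take externally produced domain calls);
2. extract the 10-kb genomic neighbourhood on either side of each anchor;
3. detect candidate precursor peptides two ways — screening annotated short
   genes, and enumerating all six-frame ORFs of the window (precursors
   routinely evade gene callers);
4. compare neighbourhoods all-vs-all and group them into families with a
   weighted homology + synteny score;
5. classify each family as TOMM / non-TOMM by three evidence rules, with
   the verdict propagated to every family member;
6. build protein sequence similarity networks whose connected components
   act as isofunctional groups;
7. report per-family summaries and precursor position-frequency matrices.

A ground-truthed synthetic genome generator makes the whole pipeline
verifiable offline; every acceptance check in the test suite runs against
genomes it plants.

## The scoring model

Pairwise protein comparison is affine-gap Smith-Waterman (BLOSUM62, gap
open 11 / extend 1) with Karlin-Altschul statistics:

E = K * m * n * exp(-lambda * S),

with the standard gapped-BLOSUM62 constants lambda = 0.267, K = 0.041 and
n the total residue count of the compared set. The original analysis used
BLAST; a full dynamic-programming engine is a strictly more exhaustive
stand-in for it, and the constants are exposed in `scoring_params()`
because the published thresholds (e-values of 1e-54 and 1e-30) presuppose
BLAST-like statistics rather than any particular implementation. Users who
need bit-exact BLAST behaviour can feed `read_alignment_tab()` output
anywhere a hit table is accepted.

Two neighbourhoods are compared by mapping their member proteins one-to-one
(greedy best raw score, identity >= 30 %, query coverage >= 25 %, at most
100 mapped hits per pair) and scoring

total = 0.5 * hit_count + 0.5 * synteny_score,

where the synteny score counts consecutive mapped gene pairs whose partners
are also adjacent with conserved relative orientation. Families are
single-linkage components over pairs with total strictly above 10.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `window_bp` | 10000 | flank on either side of the anchor gene (bp) |
| method-1 gene length | < 450 bp | strict cap on annotated precursor CDS span (stop included) |
| method-1 composition | >= 0.45 | C/S/T fraction of the C-terminal half (inclusive) |
| method-2 ORF length | < 150 aa | strict cap on six-frame ORF peptides |
| method-2 composition | >= 0.65 | C/S/T fraction of the C-terminal half (inclusive) |
| `min_orf_aa` | 25 | six-frame minimum; the smallest known precursors are ~45 aa, and the published screen states no minimum, so this is exposed as a flag |
| family threshold | > 10 | strict single-linkage cutoff on the pair score |
| `d_ssn_evalue` | 1e-54 | D-protein network edge threshold |
| `all_ssn_evalue` | 1e-30 | all-protein network edge threshold |
| `min_component_size` | 5 | all-protein components smaller than this are dropped |
| role e-value cutoff | 1e-10 | per-role reference-panel call threshold (not stated in the original work; configuration, not a claim) |

Numerical and boundary choices that the source description left open, and
how they are pinned here (each is tested):

* **C-terminal half** of a peptide of length L = the final `floor(L/2)`
  residues.
* **Composition sets**: only Cys/Ser/Thr are counted, following the
  screening procedure; descriptive text elsewhere includes Gly in the
  45-65 % range, so an `include_gly` flag exists but is off by default.
* **ORF model**: start codons ATG/GTG/TTG (initiator translated as Met),
  ORF runs to the next in-frame stop, which must be present; the longest
  ORF per (frame, stop) is reported, with `all_starts = TRUE` available.
* **Network threshold strictness**: edges use e-value <= threshold (the
  figure legends say `<`, the methods say "cutoff"); `strict = TRUE`
  switches to `<`. Component size counts representative nodes, not
  collapsed multiplicity, unless `count_multiplicity = TRUE`.
* **Synteny under inversion**: adjacency in the partner region may run in
  either direction, so a whole-cluster inversion with coherently flipped
  strands scores fully.
* **Hit e-value cap for mapping**: `map_hits()` additionally applies
  `max_evalue = 1e-3` — BLAST-based pipelines inherit such a cap from the
  aligner's reporting threshold, a full DP engine does not, so it is made
  explicit.
* **E-values in pipeline networks** are computed once against the full
  member-protein set (the m x n convention); calling `build_ssn()` directly
  lets you rescale n to a subset.
* **Tie-breaks** are deterministic everywhere: alignment traceback prefers
  diagonal > up > left and the first maximum in row-major order; role-call
  ties break by CD_fusion > C > B > F > others; family and component IDs
  are the lexicographically smallest member.

## Role calling and the TOMM decision

Real pipelines identify C proteins and CD fusions with TIGRFAM profile
HMMs (TIGR03603, TIGR03882). HMM models cannot be redistributed with this
package, so the default role caller aligns member genes against bundled
*synthetic* role seed proteins, and `call_roles()` accepts a HMMER
domtblout-style table (`read_domtblout()`) that overrides similarity calls
by model accession for real-data use. A gene significantly similar to both
the C and D panels is a CD fusion; D-side similarity with only partial
C-side similarity (above a reduced cutoff, default 1e-4) is flagged as a
truncated fusion, the heterocycloanthracin/haloazolisin case.

A family is a TOMM family if **any** member region (i) contains a C or CD
fusion protein, (ii) contains a precursor candidate, or (iii) is
bottromycin-like — two D-role genes plus a radical-SAM enzyme, or a
family-threshold-beating comparison score against a reference bottromycin
region. All member regions inherit the family verdict, including members
with no evidence of their own.

## What the synthetic generator emulates — and what it does not

`generate_genome()` plants clusters from five archetypes: discrete C+D,
fused CD, CD+B+F, stand-alone-D bottromycin-like (two YcaO genes, a
radical-SAM, a composition-poor precursor), and a decoy non-TOMM YcaO
context (D plus generic metabolism genes, no C/CD, no precursor).
Precursors can be annotated genes, unannotated intergenic ORFs, absent, or
planted "distal" — more than 10 kb from the anchor — to reproduce the
documented false-negative mode of proximity-based precursor detection.

Design choices, made once:

* **Homolog families** are realized by mutating fixed synthetic seed
  proteins to an exact target identity (default 0.85 per instance, about
  72 % pairwise within a family). Two independent YcaO seed lineages are
  bundled (canonical and bottromycin-type) so the D-protein network shows
  the stand-alone-D clusters as their own component, as real data does.
  Accessory genes take archetype-specific seeds so unrelated archetypes
  share too few homologs (< 5 weighted hits) ever to reach the family
  threshold of 10, while the ~12-gene plans give within-archetype pairs
  scores of ~11.5.
* **Precursor peptides are identical across instances of an archetype**,
  mirroring the near-identical precursors of real MccB17 and faecalisin
  families; mutating them would perturb the composition statistics the
  screens key on.
* **Back-translation** uses one fixed codon per residue (frequent E. coli
  usage, bacterial code), so translating any emitted CDS reproduces the
  emitted protein byte-for-byte.
* **Filler DNA** is laced with a 12-mer stop cassette (its own reverse
  complement, stops in all six frames) every <= 36 random bp, so filler can
  never yield a six-frame ORF of >= 25 codons; the cassette also directly
  precedes every planted precursor start so the reported ORF begins exactly
  at the planted ATG.
* **Seed proteins contain no Cys/Ser/Thr**, keeping forward-frame gene
  interiors far from the composition thresholds. Reverse-frame readings of
  codon-boundary-straddling triplets can still occasionally produce
  Ser-rich short ORFs that pass the 65 % screen — the genuine background
  of composition-based precursor detection, which the published procedure
  tuned thresholds to reduce, not eliminate. These artifacts always lie
  inside annotated genes (the acceptance suite asserts this); on the
  pinned acceptance seed none falls in a decoy region, so classification
  sensitivity and specificity are both exactly 1.

The generator does **not** emulate realistic codon usage, GC skew,
phylogenetic signal, sequencing error, or precursor leader-peptide motifs;
a green end-to-end test establishes that the pipeline's logic is correct
under controlled homology structure, not that its thresholds are optimal
on real genomes.

Two regions extracted around tandem anchors of the *same* genome share
their member gene IDs; such pairs map no hits onto each other (a protein
cannot hit itself) and join one family transitively through homologous
regions of other genomes — with at least two bottromycin-like genomes in a
cohort this is invisible, but a lone two-anchor genome yields two
single-region families.

## Known limitations

* Precursors encoded > 10 kb from the anchor are out of reach by design
  (the distal archetype exists to demonstrate the false negative).
* The internal aligner is exhaustive DP without BLAST's heuristics or
  composition-based statistics; raw scores match an exhaustive oracle, but
  e-values will differ numerically from any specific BLAST build.
* Leader-peptide profile HMMs (TIGR03601-style) and the creation of new
  pHMMs for short CD fusions are out of scope; the interfaces accept
  external domain-search results instead.
* The cleavage-site heuristic (last Gly/Ala in a central search zone,
  default 35-65 % of length, C-terminal-half fallback) is qualitative, as
  is its source; position-frequency matrices are right-aligned because TOMM
  cores share C-terminal structure, and gap columns are excluded from the
  residue simplex.
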