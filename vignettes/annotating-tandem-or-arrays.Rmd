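---
title: "Annotating tandem OR arrays from spliced protein-to-genome alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating tandem OR arrays from spliced protein-to-genome alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olfactoR)
```

## The annotation model

Insect olfactory receptor (OR) genes occur in tandem arrays of diverged
copies. Homology-based annotation of such arrays starts from many
redundant spliced protein-to-genome alignments (Exonerate
`protein2genome`, run with a stringent intron cap so that alignments do
not leap across gene boundaries). Three pathologies dominate that input:

* many queries align to the same locus (redundancy),
* a gene whose intron exceeds the aligner's cap is reported as two or
  more fragments,
* fragment boundaries are wrongly extended into the flanking intron, so
  the same query residues appear in two successive fragments.

The pipeline's model of a locus is deliberately minimal. A **virtual
scaffold** counts, per nucleotide, how many aligned exon bases cover it;
maximal positive runs are **alignment islands**. Because introns
contribute no coverage and intron caps are stringent, islands separate
tandem copies. Within each island the alignment with the highest score
wins, and its query becomes the island's *best query*; every other query
is treated as redundant evidence and discarded from model building. All
alignments of a best query on the scaffold are then candidate fragments
of one gene.

### Stitching at GT–AG sites

Two congruent fragments (same strand, target order consistent with
transcription, query spans advancing without nesting) whose query spans
overlap by $k > 0$ residues are merged by enumerating every cut of the
constant-length $3k$-nt overlap window: cut offsets $d \in \{0,\dots,3k\}$
assign the first $d$ nt to the upstream exon and the remaining $3k-d$ nt
to the downstream exon, keeping the stitched overlap contribution exactly
$3k$ nt. A candidate is admissible only if the upstream cut is followed by
`gt` and the downstream cut preceded by `ag` on the coding strand. Among
admissible candidates the translated overlap is scored against the
query's overlapping residues with BLOSUM62 and the maximum wins; ties go
to the 5'-most donor (the smallest offset), for determinism. Fragments
with non-overlapping query spans are concatenated directly, the gap
becoming an intron. A junction with no admissible candidate splits the
chain into separate models with a warning — inventing a non-canonical
splice would be worse than reporting two fragments.

Candidates are enumerated at nucleotide granularity, i.e. phase-1/2
introns are representable; split codons translate by joining the flanking
nucleotides. Restricting cuts to codon boundaries would miss real introns
that interrupt codons.

### Finalization and classification

Each stitched model is finalized by scanning up to 20 codons (the
terminal search window) upstream, in frame, for an ATG — abandoning the
scan at an intervening in-frame stop — and up to 20 codons downstream for
a stop codon, extending the terminal exons accordingly. Neither scan
crosses a scaffold end. The CDS is then translated (in-frame stops render
as `*`). Defects recorded: `inframe_stop` for a `*` strictly inside the
protein, `frameshift` when the CDS length is not a multiple of 3 or a
stitched junction gap fell below the minimum intron length. Any defect
marks the model pseudogenous. Completeness is a pure length rule: protein
length (terminal stop excluded) at or above the cutoff is `complete`,
otherwise `partial`. Names encode location and status:
`scaffold:start-end(strand)OR<serial>` with suffixes `_NTE` (no start),
`_PSE` (pseudo), `_P` (partial).

Overlapping models are resolved by the isoform rule: if the overlap is
below 20 % of *both* models, both are kept (putative isoforms or
duplicated exons); otherwise the better model wins, ranked by
completeness, then protein length, then non-pseudogenous status, then
presence of a START. For two models of the same query the overlap
fraction is measured on the aligned query intervals (the natural reading
for duplicated exons); models of different queries have no shared query
coordinate system, so the same rule is applied to genomic exonic overlap
relative to each model's exonic length.

### Refinement (P1/P2)

An optional second pass re-predicts each preliminary (P1) model with an
external one-to-one aligner (a GeneWise-class tool) over a locus extended
by `min(hit span, max_extension)` per side. The extension rule is the
simplest monotone reading of "extension depends on hit length, capped at
6000 bp": short fragments should not drag in a whole neighbouring gene,
while the cap reflects typical insect intergenic distances. The refiner
interface is pluggable (an R function or an executable printing GFF3 in
slice coordinates); when absent the pipeline is P1-only and the merge is
the identity. Overlapping P1/P2 pairs (any shared exonic base, same
strand — span overlap would fuse tandem neighbours) are resolved by the
ranking above, with P2 provenance as the final tie-break.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_complete_len` | 300 | aa | complete/partial cutoff |
| `max_extension` | 6000 | nt | per-side locus extension cap for refinement |
| `terminal_search_window` | 20 | codons | START/STOP scan range |
| `isoform_overlap_frac` | 0.20 | fraction | keep-both threshold (strictly below, for both models) |
| `eval_tolerance` | 10 | nt | terminal free-end tolerance in evaluation |
| `min_intron` | 30 | nt | floor for a stitched intron; below it, a frameshift defect |
| `consensus_min_helix` | 9 | residues | minimum consensus TMH length |

The 300-aa completeness default, 6000-nt cap, 20-codon window, 20 % rule
and 10-nt evaluation tolerance are the method's published operating
point; the 30-nt intron floor and the 9-residue consensus-helix minimum
are biologically conservative floors chosen here (a shorter "intron" is
more plausibly an alignment artifact; membrane-spanning helices are
~18–25 residues, so 9 is a permissive lower bound for a majority-vote
run).

## Evaluation semantics

`compare_annotations()` follows the conventions of transcript-comparison
tools. Base level counts shared exonic bases per scaffold and strand.
Exon level matches *distinct* exon intervals one-to-one, greedily from
the left; internal boundaries must match exactly, and a boundary gets the
tolerance only when it is a transcript-terminal free end in both exons —
the symmetric reading, which makes swapping predicted/reference exactly
swap sensitivity and precision. Locus level clusters transcripts by
exonic overlap; a reference locus is a true positive when one of its
transcripts is fully matched (identical intron chain, terminal free ends
within tolerance) by a predicted transcript. Locus precision is reported
from the predicted side (matched predicted loci / all predicted loci), as
one predicted locus can match several reference loci; the tabulated locus
TP is the matched reference-locus count. Printed percentages are rounded
half-up to one decimal.

## What the generator emulates — and what it does not

The synthetic-data module implants ATG-initiated, stop-terminated,
`gt..ag`-spliced genes (4–9 exons by default, matching the exon-count
range of Hymenoptera OR subfamilies; introns capped at 2000 nt; tandem
copies separated by 0.5–3 kb gaps) on uniform-ACGT scaffolds, on both
strands. It emits exact self-alignments per gene plus mutated decoy
queries with lower scores, reproduces fragmentation by splitting a
self-alignment at an intron with ceil(k/2)/floor(k/2) codons of wrong
extension per side, and can mutate genes with one in-frame TGA or a 1-nt
frameshift. For stitching tests it re-draws intron-end bases so the true
`gt`/`ag` pair is the unique admissible candidate in the overlap window,
which makes exact-recovery checks well-posed.

It does **not** emulate: sequence divergence between query and target
(self-alignments are exact, so best-query selection is only exercised
against decoys), non-uniform genome composition, repeats, non-canonical
splice sites, alternative isoforms, or alignment noise beyond boundary
jitter. Passing the end-to-end tests therefore demonstrates that the
*algorithmic* steps are correct under their own assumptions — not that
real, diverged alignments will reach the same accuracy. Exon lengths are
drawn in whole codons, so implanted introns are phase 0; the stitcher
itself enumerates all nucleotide offsets and is tested for phase-agnostic
arithmetic, but phase-1/2 junction recovery is not exercised end-to-end.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive on the forward strand throughout
  (the R/Bioconductor convention); 0-based half-open appears only in
  BED12 output. Minus-strand motif checks and translation always operate
  on the coding strand via reverse complement.
* All aa↔nt arithmetic lives in one utility; query coordinates stay
  1-based amino-acid positions.
* Tie-breaks are total orders everywhere (score, then query id, then
  leftmost position for island winners; smallest offset for splice
  candidates; rank then leftmost for overlap resolution), so results are
  order-independent and deterministic.
* Degenerate inputs: empty alignment files yield empty (but valid)
  annotations; vulgar/cigar-only Exonerate files are rejected with an
  actionable message; records whose exons escape their gene span are
  dropped with a warning; models with no exons are write errors.
* The simulator is driven by a single integer seed through R's RNG under
  `withr::with_seed`, leaving global RNG state untouched.

## Problem sizes used by the test-suite

The suites run on implanted arrays of 2–5 scaffolds × 1–8 genes
(up to 40 genes, proteins of roughly 180–800 aa), 200 random toy
annotation pairs for the evaluator-vs-oracle equivalence, and 25–50
randomized cases per property check. These sizes give exhaustive
brute-force oracles (per-position recounts, full candidate enumeration,
transitive-closure clustering) room to verify every quantity exactly
while the whole suite stays in the minutes range on one CPU.

## Known limitations

* Non-canonical (`gc–ag`, `at–ac`) introns are never stitched; such
  junctions surface as split models with warnings.
* The isoform rule can suppress a genuine tandem copy when one query is
  best for two neighbouring islands and both alignments are near-complete;
  in practice distinct copies recruit distinct best queries.
* Exon-level matching is greedy; with clustered boundaries within the
  tolerance of one another the one-to-one matching may differ from a
  maximum matching (the evaluator mirrors the comparison tool it models
  rather than solving assignment optimally).
* The external refiner and the validation tools (domain search, TMH
  predictors, motif scans) are adapters over their output files; their
  availability and quality are outside the package's control.
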