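---
title: "Dissecting rearranged mitogenome architectures with mitoarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting rearranged mitogenome architectures with mitoarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoarch)
```

## The problem

Vertebrate mitochondrial genomes are compact circles of ~16--20 kb
carrying 13 protein-coding genes (PCGs), 22 tRNAs, two rRNAs, a control
region (CR) and the light-strand replication origin (O~L~). Most frogs
keep the canonical vertebrate gene order, but rhacophorid tree frogs
(and *Polypedates* in particular) are a showcase of architectural
change: ND5 translocated downstream of the control region, the
ancestral "LTPF" tRNA cluster shuffled into "TLPF", the control region
duplicated on both flanks of ND5 (CR1, ND5, CR2), and the ATP8 gene
lost entirely, leaving a non-coding region (NCR) at its old locus
between tRNA-Lys and ATP6. `mitoarch` packages the comparative analyses
used to characterize such genomes into tested, reusable functions, plus
a seeded synthetic-genome generator so every stage can be validated
against known ground truth.

## Data model

`MitoGenome` stores the heavy-strand (H) sequence and an ordered,
strand-aware feature table. Internally coordinates are 0-based
half-open, which keeps circular arithmetic trivial; feature TSV and
GenBank flat files use the 1-based inclusive convention of those
formats, and the readers convert. Wrap across the origin is encoded as
`end < start` and at most one feature may wrap, which keeps sorting
well-defined. Light-strand features are stored by their H-strand
coordinates plus a strand flag; `extractFeatureSequence()` returns the
reverse complement for them, i.e. always the coding/gene sequence.

GenBank naming is inconsistent across depositors, so the reader maps
names through a shipped, editable synonym table
(`labelSynonyms()`). An undisambiguated "tRNA-Leu" or "tRNA-Ser" is
kept verbatim with a warning rather than silently assigned to an
isoacceptor.

## Composition and strand skews

AT skew is $(A-T)/(A+T)$ and GC skew $(G-C)/(G+C)$, computed from raw
counts, never from pre-rounded percentages, and reported at 3 decimals.
N bases are excluded from every denominator (above 5% N a warning is
raised). One published quirk is worth documenting: the running text for
*P. impresus* prints C: 14.7%, G: 24.3% alongside a genome GC skew of
−0.246, which under the formula above requires C > G — the printed C/G
pair appears transposed. `mitoarch` applies the formula literally to
whatever composition it is given and does not special-case the sign.

`regionCompositionReport()` emits one row per region class (whole
genome, pooled PCGs, pooled codon positions 1/2/3 in the strand-aware
reading frame, tRNAs, rRNAs, CR1, CR2); region classes missing from an
annotation are reported as absent rather than dropped, so single-CR
genomes keep an explicit CR2 row.

## Codon usage

`codonUsage()` counts complete in-frame codons over all PCGs under the
vertebrate mitochondrial code (AGA/AGG are stops, ATA is Met, TGA is
Trp). Relative synonymous codon usage is
$\mathrm{RSCU}_c = n_c \cdot |F| / \sum_{c' \in F} n_{c'}$ for codon
$c$ in synonymous family $F$. Because the vertebrate mitochondrial
translation merges the leucine and serine subfamilies, Leu and Ser are
single 6-codon families. Stop codons are counted but carry no RSCU;
truncated terminal codons are not complete codons and are skipped.
Truncated stops themselves ("T--", "TA-") are the business of
`startStopCodons()`, which records starts verbatim (flagging non-ATN
starts such as GTG) and classifies CDS tails by length mod 3.

## Junction accounting

`junctionScan()` walks circularly consecutive features and classifies
each junction by the signed gap `next.start − prev.end`: positive =
intergenic spacer, negative = overlap, zero = abutting (reported in
neither list). Control regions and NCRs are excluded from the
accounting by default because published spacer/overlap totals count
only gene-to-gene junctions — the gap that holds an NCR *is* the NCR —
while O~L~ is included because its 3-bp overlap with tRNA-Cys is part
of those totals. A junction whose gap hosts an excluded feature is
dropped entirely rather than booked as a giant spacer.

The shipped fixture `impresusJunctionGenome()` reproduces the published
*P. impresus* junction pattern (10 spacers / 28 bp, 7 overlaps / 29 bp,
maximum 13 bp). The source lists the tRNA-Ser(UCN)/tRNA-Asp junction
both as a 1-bp spacer and as the 13-bp longest overlap, which cannot
both hold; the fixture follows the overlap list there and places the
leftover 1-bp spacer at the tRNA-Asp/COII junction so that both printed
totals are reproduced simultaneously.

## The TDRL rearrangement model

Tandem duplication–random loss is the canonical mechanism of
mitochondrial gene-order change: a contiguous block is duplicated in
tandem and, for every gene, one redundant copy decays. `applyTDRL()`
implements exactly that on an anchored circular order; the result is
the block's genes retained in the first copy, in order, followed by
those retained in the second copy. Orders are compared after anchoring
at 12S (circular equality = equality of the anchored linearization),
matching how rearrangement pathways are conventionally drawn.

A useful theorem falls out of the definition: the orders reachable in
one TDRL step are precisely the concatenations of two complementary
subsequences of the original order. The test suite verifies
`inferSingleTDRL()` — an exhaustive enumeration over blocks and
retention vectors, deduplicated by trimming block edges that do not
move — against an independent subset-merge oracle on every order of up
to six labels. Enumeration is refused above 14 labels (the retention
space doubles per gene).

Non-TDRL events (duplication that keeps both copies, degeneration of a
gene into an NCR) are represented in `PathwayScript`s as annotated
segment-replacement steps: they are replayed by `verifyPathway()` but
never inferred. The shipped script
`rhacophoridRearrangementPathway()` (also in
`inst/extdata/rearrangement_pathway.yaml`) replays the five-step
reconstruction from the canonical vertebrate order to the derived
dual-CR *Polypedates* order; the intermediate after step 2 is the
*Buergeria*-like LTPF single-CR state. The literature credits the
individual steps to prior work without printing every intermediate
order, so the script encodes the most parsimonious reading and is
documented as a reconstruction.

## Control-region dissection

`findTandemRepeats()` is a deterministic period scan, not a
reimplementation of any external tool's stochastic scoring: for each
candidate period the sequence is compared with itself shifted by that
period, runs of adjacent-copy agreement become candidate arrays, and a
per-column majority consensus validates each candidate. The acceptance
rule is the conventional one for control-region repeats: consensus
match above 90%, at least 2 copies, periods 10--2000 bp (clamped to
half the sequence). Two subtleties: the candidate screen runs at
$2f-1$ where $f$ is the consensus threshold, because two copies each
diverged ~$\mu$ from the consensus agree with each other only
~$1-2\mu$; and period ties (an array explained at period $p$ and $2p$)
go to the smallest period, applied before the longest-span /
highest-match resolution of genuinely overlapping calls. Copy numbers
are reported raw and rounded. `maskRepeats()` excises (not N-masks)
repeat spans, producing the "conserved" CR used for cross-species
work; re-scanning the masked output finds nothing at the same
threshold, a property the tests check.

`findMotifs()` does Hamming-distance motif search (via
`Biostrings::matchPattern`, IUPAC-aware). The shipped library carries
the two O~L~ stem motifs — CTTCT (exact) and GCCGG with one mismatch
allowed, catching the GCCAG variant seen in some lineages. TAS and CSB
motifs are identified in practice by comparison against close relatives,
so they are user-supplied.

`crPairwiseIdentity()` reports identity over *alignable sites*:
gap-free aligned columns only, with gaps counting as neither matches
nor substitutions. That makes the published substitution counts (e.g.
133 substitutions in 1496 alignable sites = 91.1%) reproducible
exactly from pre-aligned input, the recommended path when alignment
parameters of the original analysis are unknown. For unaligned input
the default global alignment uses match +1, mismatch −1, gap open −5,
gap extend −1 — a declared choice, since the original analyses do not
state their parameters.

## The concerted-evolution test

Duplicated control regions can evolve independently (each copy tracks
the species tree separately; CR1s and CR2s form separate clusters) or
in concert (homogenization keeps the two copies within a genome more
similar than their orthologs; paralogs form cherries). The decisive
statistic is topological: on a tree of all CR copies rooted with a
single-CR outgroup, does every two-copy species form a two-leaf clade?

The original analyses used Bayesian and maximum-likelihood inference
under TVM+I+G. At desk scale `mitoarch` substitutes neighbor joining on
p or K2P distances with a column-resampling bootstrap — a deliberate
method substitution, justified because the verdict depends on a coarse
topological feature (paralog cherries), not on branch-length or
model-sensitive quantities; the suite's simulations confirm the
NJ-based verdict separates the two regimes cleanly. NJ itself and
bipartition counting come from `ape` (`nj`, `prop.clades`); distances
from `ape::dist.dna` with pairwise deletion.

`simulateCREvolution()` provides the matching generator: a duplication
on a 0.5-long stem above the species root, i.i.d. substitutions at 0.2
per site per unit branch length with a 2:1 transition bias, and, in
concerted mode, whole-CR gene-conversion events at 20 per unit branch
length (direction random per event). The default species tree is a
fixed ultrametric 7-taxon tree of depth 1 whose terminal branches are
at least 0.3 — long enough that the expected number of terminal
conversions per lineage is ≥ 6, so concerted lineages are synchronized
essentially always, which is the biological regime the test targets
(homogenization fast relative to speciation). Sequences are 800 bp
with no indels, so simulated sets are born aligned and "alignable
sites" is well-defined. Whole-CR conversion is a documented
simplification of gene conversion / unequal crossover, which in real
genomes can homogenize partial tracts.

## NCR remnant scan

`classifyNCR()` distinguishes the two documented routes to an NCR at
the ATP8 locus. Duplication-degeneration (the large-NCR route): the
COII--tRNA-Lys region duplicated in tandem and the supernumerary COII
tail, tRNA-Lys and ATP8 copies decayed, so the NCR still aligns locally
to genes besides ATP8 — a putative tRNA-Lys pseudogene inside the large
NCR is the signature case, and `anticodonLoopCheck()` covers its
structural symptom (an anticodon loop short of the canonical 7 unpaired
bases). Direct-mutation (the small-NCR route): ATP8 decayed in place,
so only ATP8 aligns. No remnant at all leaves the region unclassified.

Remnants are found with Smith–Waterman local alignment (match +2,
mismatch −1, gap −2). The reporting threshold is half the maximum
attainable score ($0.5 \times 2|ref|$). This value was calibrated on
the score regimes rather than guessed: under this scoring, spurious
local alignments between unrelated sequences plateau near
$0.6\mbox{--}0.65 \times |ref|$ even for tRNA-sized references, while
a genuine remnant decayed at rate $\mu$ scores about
$(2-3\mu)|ref|$ — above half-maximal for $\mu \le 0.3$. The planted
recovery tests (90%+ at $\mu = 0.2$) run at exactly these settings.

## The synthetic generator

`generateGenome()` realizes a `syntheticSpec()`: one of the three
gene-order templates (canonical / LTPF-single-CR / TLPF-dual-CR),
region base frequencies derived from target AT content and skews, PCGs
with valid starts, stop-free bodies and planted truncated stops,
control regions with a planted 5' tandem repeat (38 bp × 3 by default,
the size class seen at real *Polypedates* CR 5' ends), CR paralogs at
a planted divergence, and an NCR built by either loss pathway. Every
artifact comes with a `truth` record of the planted values as
realized, and every generated genome validates under the data model.
All randomness flows through a mandatory integer seed and the
generator restores the caller's RNG state, so runs are reproducible
byte-for-byte.

What the generator does *not* emulate: codon-level selection (bodies
are i.i.d. codons, not realistic protein sequences), indels outside
explicit repeat structure, within-genome composition gradients, and
tRNA secondary structure. Passing the recovery tests therefore shows
the analyzers are correct on data matching their assumptions, not that
they are robust to every artifact of real sequences — real-data
validation still requires real annotated genomes via
`readGenBank()`/`readFeatureTable()`.

## Numerical choices and degenerate inputs

* Skews are `NA` when the denominator is zero; all-N sequences are an
  error, empty regions are "absent" rows, truncated codon tails that do
  not end in T/TA are flagged rather than coerced.
* Repeat-finder ties: smallest period wins at equal span; overlapping
  distinct calls resolve longest-span-then-highest-match.
* NJ tie-breaks follow `ape::nj` (deterministic for a fixed label
  order); the verdict is invariant to leaf permutations, which the
  tests check explicitly.
* p-distances may mildly violate the triangle inequality; NJ does not
  require it. A pair with zero gap-free overlap is an error, not a 0.
* TDRL inference refuses orders above 14 labels; the practical region
  of interest (tRNA-Ser(AGY) through 12S) is far below that.
* Problem sizes in the test suite were chosen as the smallest that
  exercise each property cleanly: 50 seeded simulations per mode for
  the verdict accuracy check, 100 planted arrays for repeat recovery,
  exhaustive TDRL enumeration up to 6 labels, 50 planted NCRs per
  pathway.

## Known limitations

* The GenBank reader covers the single-record subset used by
  mitogenome submissions (plain, `complement()`, and two-segment
  origin-wrapping `join()` locations); it is not a general flat-file
  parser.
* De novo annotation, RNA folding, dot-plots and map drawing are out
  of scope; structures for `anticodonLoopCheck()` must come from an
  external folding tool.
* The concerted-evolution verdict is purely topological; it does not
  estimate conversion rates or tract lengths.
* Multiple alignment of more than two CRs is delegated to external
  aligners; the package consumes aligned FASTA (or the born-aligned
  simulator output).
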