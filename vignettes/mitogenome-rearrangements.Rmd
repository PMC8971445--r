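---
title: "Detecting and quantifying mitochondrial gene-order rearrangements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying mitochondrial gene-order rearrangements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorearr)
```

## The model

A vertebrate mitochondrial genome is treated as a circular sequence of
signed gene occurrences drawn from a fixed 37-gene vocabulary: 22 tRNAs,
2 rRNAs and 13 protein-coding genes. The sign records the coding strand as
annotated (`+` heavy, `−` light); the two non-coding elements (control
region / D-loop and the light-strand replication origin) are stripped on
construction and never counted among the 37, because they are missing,
unannotated or duplicated in a large fraction of deposited genomes and
would otherwise dominate the comparison. The baseline is the ancestral
vertebrate arrangement — trnF first, then rrnS, trnV, rrnL, and so on
around the heavy strand, with exactly nine genes (trnQ, trnA, trnN, trnC,
trnY, trnS2, nad6, trnE, trnP) on the light strand. Numbering the
ancestral genes 1..37 turns any complete single-copy genome into a signed
permutation, with the ancestral order as the identity.

Three assumptions matter. First, strand assignments in the input are taken
at face value (no reflection normalization): mitogenome deposition fixes
the heavy strand, so a sign mismatch is either a real inversion or a
wrong-strand annotation, and distinguishing the two is the screening
stage's job, not the encoder's. Second, the circular reading frame is
arbitrary, so every architecture is canonicalized by rotating a fixed
anchor (the heavy-strand trnF copy; if absent, the present gene with the
smallest ancestral index) to the front. Third, one copy of a duplicated
gene is "the" gene and the others are duplications; we choose the copy
whose signed neighbourhood shares the most adjacencies with the ancestral
context, which keeps tandem duplicates stable (the first copy wins ties).

## Moved genes as a minimal explanation

The rearranged gene set of a genome is defined as the complement of a
maximum-cardinality common signed circular subsequence between the genome
and the ancestral order: the smallest set of occurrences whose removal
makes the remaining circular orders identical, signs included. Genes on
the wrong strand can never be part of the common subsequence and are
therefore always moved. The computation anchors the circular subsequence
at each possible first element and solves a longest
circularly-increasing-subsequence problem on the ancestral indices; at 37
genes this is exact and fast.

Maximum common subsequences are not unique — after an adjacent exchange,
either participant explains the difference. We break ties
deterministically toward the kept set whose sorted ancestral indices are
lexicographically smallest, i.e. the *larger*-index gene is reported as
moved. That convention reads the reptilian trnS1/trnH exchange as a trnS1
transposition, matching how that arrangement is conventionally described,
and makes every result reproducible. The test suite verifies the whole
definition — minimality and tie-break — against a brute-force
minimal-removal search, exhaustively over all signed circular permutations
of up to six genes.

Classification is per occurrence: extra copies of a symbol are
duplications; canonical symbols with no non-pseudo copy are deletions
(pseudogene copies never count as presence, and are tallied separately
rather than treated as gene content); moved occurrences are inversions
when their sign differs from the ancestral strand and translocations
otherwise. The two reporting categories `dup`/`del` and the lumped
`inv_tra` follow the field's usual bookkeeping.

## Screening annotation errors

Apparent rearrangements are reconciled with an external evidence table —
the distilled output of sequence-level verification (alignment identity to
the gene expected at a locus, strand checks, gene searches in unannotated
regions). The rules are:

* an **inversion** is refuted as a wrong-strand annotation when the
  verified strand equals the ancestral sign and the identity fraction is
  at least the threshold;
* a **deletion** is refuted when the gene sequence was located in the
  genome (`located = TRUE`);
* a **translocation or duplication** is refuted as a misnamed gene when
  the annotated sequence matches the gene expected at that ancestral
  position at or above the threshold.

The identity threshold defaults to 0.80 (fraction of aligned identity, in
(0, 1]), the conventional cut-off for calling two mitochondrial gene
sequences the same gene in congeneric comparisons. Events without evidence
are confirmed by default: only demonstrable errors are refuted, so an
empty evidence table reproduces the uncurated analysis.

## Proportions and hotspots

Per-taxon rates use `PRo = NRo/(NE × 37) × 100` (percent of gene slots
rearranged, `NE` = species in the taxon), and per-gene rates
`PRg = NRg/NE × 100`. Percentages are rounded half-up (2 decimals for
proportions, 1 for breakdowns) — half-even rounding would silently shift
several tabulated values. The summary selector defaults to `differing`
(confirmed + refuted), which reproduces the conventional presentation of
per-class tables where the percentage column reflects everything deposited
as rearranged; a `confirmed` selector gives post-curation rates. The
order × gene matrix defaults to confirmed events, since per-gene rates are
most useful after curation. `PRg` can exceed 100 when a gene has several
events per species; it is reported raw with a warning rather than capped.
Hotspots are maximal circular runs (minimum length 2 by default) of genes
whose event totals reach a threshold; the threshold has no natural
default on real data and is exposed as a parameter (the pipeline uses 1,
i.e. "any recurrent involvement", which is only sensible at small scale).

## Convergence and distances

Two genomes share a convergent arrangement when they carry the same
derived architecture (identical canonical serialization — the
zero-rearrangement-distance criterion) or the same local signature
element, and belong to different taxa at the grouping rank (order by
default). Signature elements are maximal runs of moved genes in their
observed signed order, plus named duplications and deletions; they allow
genomes that differ elsewhere to share one local convergence, and they
cover shared gene losses and gains that whole-architecture identity would
miss. Genomes with duplications or deletions are excluded from permutation
distances (their content differs) and handled only through signatures.
Note that published figures often display a rearranged *window* wider than
the minimal moved run; our elements are the minimal runs, which are
sharper but can label the same biological event differently than a
hand-drawn figure would.

The rank gate is purely taxonomic. A shared derived arrangement in two
orders may still be a synapomorphy if the orders are sister groups;
distinguishing convergence from shared ancestry requires a phylogeny and
is deliberately left to the user.

Breakpoint distance counts signed circular adjacencies of one permutation
absent from the other (a reading-direction mirror `(−y, −x)` counts as
present). The inversion distance uses the Hannenhalli–Pevzner breakpoint
graph on the anchored linearization: `n + 1 − c + h`, with `c` the cycle
count and `h` the hurdle count. We do not implement the fortress
correction, so the value is a lower bound that is exact on all
fortress-free instances; the test suite confirms equality with
breadth-first-search exact distances exhaustively at small sizes and on
1,000 random instances up to eight genes. Since convergence detection only
uses distance zero — where cycle count alone decides — the missing
fortress term cannot affect any reported convergence.

## The synthetic-data generator

The generator is the package's study bed: it emulates the statistical
structure the analysis assumes, with known truth.

* **Rearranged fraction** 0.36 of genomes by default, matching the
  observed share of vertebrate mitogenomes with at least one
  rearrangement. A genome drawn as rearranged is guaranteed to differ from
  the ancestral architecture (draws that cancel back to the identity are
  rejected and redrawn).
* **Events per genome**: geometric with success probability 0.6, truncated
  at 5 — most rearranged genomes carry one small event, a few carry
  several, which mirrors the predominance of modest rearrangements.
* **Event kinds**: transposition 0.35, inversion 0.20, reverse
  transposition 0.15, TDRL 0.17, duplication 0.11, deletion 0.02. The
  duplication and deletion weights reproduce the observed dominance of
  inversions/translocations over duplications over (rare) deletions; the
  split among the order-changing kinds is our choice, since detection
  collapses them into the same reported categories.
* **Block lengths** 1–3 with probabilities 0.5/0.3/0.2 (rearranged tracts
  in mitogenomes are short); TDRL kept-patterns are sampled uniformly over
  the non-identity patterns.
* **Annotation errors** at rate 0.004 per locus (a few errors per thousand
  gene annotations), split 0.6/0.3/0.1 among strand flips, name swaps and
  omissions — tRNA-dominated strand errors being the most common real
  failure mode.

Error injection is deliberately conservative: errors are placed only at
loci far from any truly rearranged region (circular ancestral-index
distance ≥ 4 from every touched locus and from other errors), and name
swaps pair loci on the same ancestral strand at index distance ≥ 3. Under
these placement rules the set of refuted events after screening provably
equals the injected set, which is what the recovery tests assert. The cost
is a simplification of real data, where errors and true rearrangements can
collide in one region; the screening rules themselves do not depend on the
separation, but exact-recovery guarantees would not survive such
collisions (a wrong-strand error on a genuinely translocated gene is
fundamentally ambiguous at the gene-order level).

Other simplifications: events are drawn per genome with no phylogenetic
correlation (real rearrangements are inherited, so real datasets show
clade-level blocks rather than independent draws — taxonomic structure in
the simulated taxonomy is cosmetic); gene coordinates are synthesized from
typical gene lengths; and no sequence-level signal exists at all, so the
evidence table is exact rather than noisy. Passing the recovery tests
therefore demonstrates correctness of the gene-order algebra, the
screening logic and the bookkeeping — not robustness to noisy alignments
or to phylogenetically structured error percolation.

Randomness uses one top-level seed with per-genome substreams salted by
genome index, so individual genomes are stable under dataset resizing, and
dataset emission is byte-identical across runs.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive; origin-wrapping features
  (`end < start`) are allowed on circular genomes and positioned by start.
  Identical starts are ordered by (start, end, symbol).
* Labels that cannot be normalized are excluded and reported, never
  guessed. Bare leucine/serine tRNA labels are resolved from sorted
  neighbour context (nad1-adjacent trnL1, nad5-adjacent trnL2,
  trnH-adjacent trnS1, trnD-adjacent trnS2) and flagged ambiguous when no
  context matches.
* An architecture lacking trnF anchors at the smallest present ancestral
  index; with several heavy-strand trnF copies, the rotation with the
  lexicographically smallest serialization wins, keeping canonicalization
  rotation-invariant.
* Empty event sets yield empty (not failing) breakdowns; taxa with no
  rearrangement are reported with `PRo = 0` rather than omitted; an empty
  architecture or a genome with zero mappable genes is a hard error.

## Problem sizes

The bundled checks run at sizes chosen to make the oracles exact:
exhaustive moved-set verification over all signed circular permutations of
up to 6 genes (8,544 rotation classes), BFS-verified inversion distances
up to 8 genes, and a 500-genome simulated dataset (5 classes × 5 orders ×
20 species) for parameter recovery — large enough for a two-sided binomial
check on the 36% rearranged fraction while keeping a full run in well
under a minute.

## Known limitations

* Event classification is per gene occurrence, not per mechanistic event:
  a three-gene transposition is three translocations in the tables. This
  matches how per-gene rates are defined, but event-scenario
  reconstruction (which operation sequence produced an order) is out of
  scope.
* Table counts at the per-genome level depend on the tie-break convention
  for equally minimal explanations; other conventions can differ by a gene
  on genomes with symmetric exchanges.
* The inversion distance omits the fortress correction (see above).
* Strain-level deduplication is a flag (`dedupe_species`), keeping the
  first genome per species; no attempt is made to pick the best-annotated
  representative.
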