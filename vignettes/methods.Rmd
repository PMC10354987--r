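---
title: "Methods: reference-guided mitogenome assembly with hifimito"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-guided mitogenome assembly with hifimito}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hifimito` reconstructs a circular, rotated, annotated mitochondrial
genome from long high-accuracy reads (or pre-assembled contigs), using
a closely related reference mitogenome as a guide. This vignette
documents the algorithms, the parameter defaults and their rationale,
and the scope of the bundled simulator.

## Alignment core

All stages share one seed-chain-and-extend aligner (C++ via `Rcpp`):

* **Seeding.** Exact $k$-mer matches ($k \le 31$, default 15) found
  with a 2-bit rolling hash; runs containing `N` are skipped.
* **Chaining.** Hits are grouped by diagonal (query minus subject
  offset) within a corridor of `band` (default 150 bp) and split where
  consecutive hits are separated by more than `max_q_gap` in the
  query; chains shorter than `min_chain_seeds` are discarded.
* **Banded extension.** Needleman–Wunsch inside the diagonal corridor
  implied by the chain (match $+2$, mismatch $-4$, gap $-3$ per base,
  linear). Subject ends can be "free" so overhangs clip without
  penalty — this yields glocal alignments for mapping and overlap
  detection. The traceback is returned run-length encoded.

Because the gap model is linear, a long novel insertion can be
fragmented by the dynamic program into several shorter gaps separated
by chance matches. Wherever gap *structure* matters (see heteroplasmy
below), decisions therefore use the **net indel imbalance** of a block
($|\sum \text{ins} - \sum \text{del}|$) alongside the longest single
gap, not the longest gap alone.

## Read recruitment

Reads are mapped to the reference doubled head-to-tail so
origin-spanning reads map in one block. Mapping is block-local: a read
is mapped if its best chained block reaches identity $\ge 0.7$ over at
least $\min(1000, \lceil L/2 \rceil)$ columns. This deliberately maps
reads that only *partially* match the reference — such as reads that
carry a NUMT (a mitochondrial fragment inserted in the nuclear genome)
inside nuclear flanks. Recruitment then applies the length cutoff: a
mapped read longer than `max_read_len` (default: the exact reference
length) is excluded. Since genuine mitochondrial reads cannot exceed
one genome length while NUMT-spanning reads typically do, this single
cutoff removes NUMT contamination; the recruitment report records how
many reads were excluded this way.

## Assembly (overlap–layout–consensus)

* **Overlaps.** For every read pair the aligner searches both
  orientations for dovetail overlaps of at least `min_overlap`
  (default 1000 bp) at $\ge 0.99$ identity, or containment (one read
  covered by another up to 50 bp slack at each end). The best overlap
  per directed read pair is kept.
* **Layout.** Greedy best-overlap-first: the longest unused overlap
  seeds a path, which is extended right and left by the longest
  compatible overlap to an unused read. If an extension returns to the
  start of the path the layout is closed as a cycle ("eager cycle
  closure"). Contained reads never start or extend layouts. When local
  coverage leaves one junction without an overlap of `min_overlap`,
  the layout legitimately stays linear but spans more than one full
  turn; the circularization stage then detects the terminal redundancy
  and closes the circle.
* **Consensus.** The layout backbone is spliced from the oriented
  reads; every read is then realigned to the backbone and votes
  per-column (majority; insertions require a strict majority of the
  covering depth). Ties go to the earliest voter, which keeps the
  procedure deterministic.
* **Two rounds / heteroplasmy.** Reads whose best alignment to the
  round-1 consensus shows a structural disagreement — net indel
  imbalance or single gap of at least `structural_gap` (50 bp) — are
  deferred and assembled separately in round 2. A 50:50 heteroplasmic
  mixture with a 100 bp insertion therefore yields two candidate
  contigs, one per haplotype. Round-2 leftovers can also form
  redundant chimeric contigs; these are reported in the candidate
  table but lose the final selection to the circular,
  reference-length haplotype contigs.

## Reference filtering

Each assembled contig is aligned to the reference; the fraction of the
contig covered by reference-homologous blocks must exceed
`p_coverage`% (default 50, strict). Contigs at least 5x the reference
length are dropped as runaway/repetitive assemblies — except in
`taxon_mode = "plant"`, where bona fide plant mitogenomes are much
larger than their conserved gene complement suggests. Contigs at or
below 0.8x the reference length are dropped as fragments. Both length
comparisons are strict inequalities on the stated bounds.

## Circularization

A contig is circular when its start is repeated at its end: candidate
offsets come from seed diagonals between a prefix probe and the
contig's suffix window, and a candidate is accepted when the glocal
alignment reaches $\ge 0.99$ identity over **more than**
`circular_size` columns (default 220 — so a 221 bp terminal redundancy
is circular and a 220 bp one is not). Trimming removes the redundant
copy and repeats the check (up to 3 rounds, accumulating the removed
length), with the invariant `trimmed_length + overlap = original
length` at every round. Contigs no longer than `2 * circular_size` are
reported "too short to evaluate".

## Annotation and frameshift calls

Every reference feature is transferred individually: the feature's
reference sequence is aligned to the (doubled, if circular) target,
and the best placement above 0.6 identity and 0.7 reference coverage
is kept, reduced modulo the genome length, and marked origin-spanning
when it wraps. Short features (< 200 bp, i.e. tRNAs) use a smaller
seed ($k = 11$). A transferred CDS is flagged *frameshifted* when its
span is not congruent to the reference span modulo 3, or when its
translation (NCBI genetic code tables from `Biostrings`; default
table 5) contains a stop before 90% of the expected protein length. A
1 bp deletion in a CDS is thus flagged while an in-frame 3 bp deletion
is not, on either strand.

## Finalization

* **Rotation.** The anchor is `trnF` (tRNA-Phe, the conventional
  start of vertebrate/invertebrate mitogenomes) when any contig
  annotates it; otherwise the tRNA annotated on the most contigs (ties
  broken lexicographically); with no tRNA at all, rotation is skipped
  with a warning. A minus-strand anchor first reverse-complements the
  contig; circular contigs are then cyclically shifted so the anchor
  starts at base 1 on the plus strand.
* **Selection.** Candidates are ranked by annotated gene count
  (descending), then closeness of length to the reference, then
  identifier. The final genome is the first candidate that is (A)
  circular, (B) within 0.8–1.2x of the reference length and (C) free
  of frameshifted genes; failing that A∧B, then A∧C, then A; with no
  circular candidate at all the top-ranked contig is selected with a
  prominent warning.
* **Coverage.** Recruited reads are assigned to their best candidate
  (minimum mapping quality `covMap`, default 0) and per-base depth is
  accumulated modulo the genome length.

## Simulator: scope and defaults

The generator produces fully labelled instances and is the basis of
the test suite:

* `simulate_mitogenome()` — default 16,500 bp circle with 13 CDS
  (valid ORFs under genetic code 5: start codon, no internal stop,
  terminal stop), 2 rRNAs and 22 tRNAs including `trnF`, separated by
  at least 10 bp of intergenic spacer; strands are mixed.
* `simulate_reads()` — truncated-normal lengths (default mean 10 kb,
  sd 2 kb, min 5 kb), uniform start positions with circular wrap,
  per-base substitutions (0.2%) and 1 bp indels (0.05%); provenance
  records the true origin, strand and span of every read.
* `plant_numt()` — plants a (default 8 kb) mitochondrial fragment at a
  random position of a random nuclear background, at a controllable
  divergence (default 10%).
* `simulate_heteroplasmy()` — a second haplotype carrying a structural
  edit (default: 100 bp insertion at an intergenic site), and a read
  mixture drawn at the stated frequencies.

All simulator functions take explicit seeds, save and restore the
caller's RNG state, and are byte-deterministic.

**Limitations.** The error model is i.i.d. per base (no homopolymer
bias), the simulated genome has no control-region repeats, and the
overlap stage targets HiFi-class accuracy — identity thresholds
(0.99) are not appropriate for noisy long reads. The aligner's linear
gap penalty fragments very long indels, which is why structural
decisions use net gap imbalance; alignments themselves are not
guaranteed to represent a long indel as one gap. The assembler is
designed for small circular genomes at moderate coverage, not for
nuclear-scale assembly.

## Determinism

Given identical inputs, configuration and seeds, every stage —
simulation, recruitment, assembly (including consensus tie-breaking),
filtering, circularization, annotation, rotation and selection — is
deterministic, and all emitted files are byte-identical across reruns
(the run manifest's wall-clock timings excepted).
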