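---
title: "Positional analysis of plant miRNA precursor foldbacks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positional analysis of plant miRNA precursor foldbacks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirduplex)
```

## The biological model

Plant miRNA precursors are imperfect RNA hairpins. DCL1, the plant
Dicer-like ribonuclease, excises the miRNA/miRNA* duplex with two
staggered double-strand cuts, each leaving a 2-nt 3′ overhang. Some
precursors are processed base-to-loop (the first cut is below the duplex,
typically guided by a 15–17 bp lower stem), others loop-to-base (the
first cut releases the terminal loop). Beyond the secondary structure,
the *identity* of the nucleotides at unpaired positions matters for
processing efficiency — most prominently, C-C mismatches are strongly
deleterious and essentially absent from cleavage sites in natural
precursors, which motivates positional surveys of pair identities and
identity-aware design rules for artificial miRNAs (amiRNAs).

`mirduplex` turns those observations into a reusable pipeline with four
analytical stages, each exposed as ordinary functions:

1. **Structure** (`parse_dotbracket()`, `fold_sequence()`): a precursor's
   secondary structure is either supplied as Vienna dot-bracket or
   predicted by an external minimum-free-energy (MFE) engine. We wrap
   ViennaRNA's `RNAfold` at default parameters and use only its single
   MFE structure — no suboptimal ensemble, no post-processing of lonely
   pairs or dangling ends; the engine name and version are stamped into
   every report so that engine substitutions are auditable.
2. **Duplex registration** (`infer_star()`, `register_arms()`,
   `assign_cleavage_coords()`): the analytical core, described below.
3. **Pair statistics** (`site_composition()`, `overall_composition()`,
   `expected_pair_frequencies()`, …): positional frequency matrices and
   a mononucleotide independence null.
4. **Design screening** (`amirna_check()`): rule-based scoring of
   candidate amiRNA precursors.

## Cleavage-site coordinates and duplex registration

All positional statements use a coordinate system anchored on the
miRNA/miRNA* duplex. Coordinate 1 is the basal-most registered column of
the duplex (anchored on the strand whose 5′ end is basal: the miRNA for
a 5p miRNA, the star for a 3p miRNA — which makes the coordinate system
a property of the duplex, invariant under exchanging the miRNA and star
roles). Coordinates decrease below the duplex (−1, −2, …; coordinate 0
does not exist) and increase above it. The basal DCL1 cut spans
coordinates −1, 1, 2, 3; the apical cut spans L … L+3 for an L-nt miRNA
(21–24 for the canonical 21-mer). For base-to-loop precursors the basal
cut is the *first* cleavage site; for loop-to-base precursors the labels
swap while the coordinates stay put. Records with unknown processing
direction are treated as base-to-loop — the majority mechanism — and
flagged (`direction_assumed`), keeping the choice auditable.

**Star inference.** The 2-nt 3′ overhang geometry fixes the star strand
on the pairing table: its 5′ end is `partner(miRNA_end − 2)` and its 3′
end `partner(miRNA_start) + 2`. When an anchor position is unpaired in
the fold, the nearest paired position within 3 nt substitutes and the
offset is compensated assuming locally helical geometry; the result is
flagged `interpolated`. If no paired anchor exists within 3 nt on either
end the record is quarantined (`star_uninferrable`) rather than guessed.

**Registration.** A two-pointer walk starts at the basal duplex anchor
and moves outward in both directions, reading the 5′ arm 5′→3′ and the
3′ arm 3′→5′. Positions paired with each other emit paired columns;
opposed unpaired positions emit mismatch columns; an unpaired position
whose counterpart is committed to a partner further along emits a bulge
(gap on the far side). Bulged nucleotides are classified as their own
`BULGE` class, never as mismatches: the mismatch identity tables must
contain only true two-nucleotide oppositions. The walk stops at the
terminal loop, the precursor ends, or the survey window.

Within an internal loop whose two sides differ in length, more than one
minimal registration exists (the mismatch columns and the surplus bulges
can interleave in any order). The package adopts one convention:
*mismatch columns sit nearest the anchor, bulges distal*. The tests
check this against an independent oracle that exhaustively enumerates
every monotone registration of small hairpins, keeps the minimum-gap
ones and applies the same tie-break; the two implementations share
nothing but the convention.

**Window.** Surveys cover up to 56 coordinates, split 15 below / 41
at-or-above the anchor by default (configurable via `run_config()`).
The 15 coordinates below cover the documented 15–17 bp lower stem; the
rest covers the duplex and the region above it. Short precursors simply
yield shorter alignments, flagged `truncated`.

## Frequency matrices and the null model

Overall compositions pool *positions* across precursors (a pooled count,
not an average of per-precursor shares); per-coordinate matrices use as
denominator only the precursors whose alignment reaches that coordinate,
so every column sums to 100. Identity tables come in two modes —
`ordered` (16 nucleotide pairs, 5′ arm first) and `symmetric` (10
orientation-collapsed classes: A-U, G-C, G-U, and the seven mismatch
identities A-A, C-C, G-G, U-U, A-C, A-G, C-U) — because published
figures typically collapse orientation ("G-C/C-G") while the underlying
counts are ordered. Bulges are reported as their own class in identity
tables; for the paired/unpaired dichotomy in `kind` mode they fold into
the unpaired share by default.

The mononucleotide null asks whether pair-identity biases are explained
by base composition alone: under independence the expected share of the
ordered pair (x, y) is p(x)·p(y), with symmetric classes summing their
ordered members. `expected_pair_frequencies()` reports per-class
log2(observed/expected) enrichments and a per-position chi-square
goodness-of-fit statistic; a zero-expected class observed at non-zero
frequency yields an infinite enrichment sentinel and is excluded from
the chi-square with a warning. Group contrasts (`compare_groups()`) use
two-proportion z-tests without continuity correction,
Benjamini–Hochberg-adjusted across all cells at the conventional 0.05 —
the survey literature reports no formal test, so a default had to be
stated.

Percentages are kept at full precision internally and rounded (two
decimals) only at serialization.

## The synthetic-precursor generator

Every stage is testable without downloads because
`generate_precursor()` builds hairpins with known ground truth: basal
flank, lower stem (16 bp default, echoing the 15–17 bp dsRNA segment),
the miRNA/miRNA* duplex (21 nt default) plus a short region above it,
terminal loop (8 nt), and the mirror arm. Each registered coordinate
carries a probability vector over pair identities. Defaults: the lower
stem is fully paired (G-C 0.5, A-U 0.4, G-U 0.1 — the identity split of
paired positions in natural precursors); duplex coordinates are 80%
paired with the same split and 20% mismatches spread uniformly over the
seven identities, matching the few-mismatches-per-duplex character of
natural miRNA/miRNA* duplexes. Per-coordinate overrides (`planted`)
replace the default at chosen coordinates and are the basis of all
recovery tests. A single integer seed drives generation; per-record
seeds are derived by counter, so records are independent and the whole
survey is reproducible byte-for-byte.

Three structural design choices make the planted fold the dominant MFE
structure, so that refolding generated sequences with a real engine
reproduces the planted pairing (the refolding invariant, checked in the
tests at ≥ 95% of duplex positions pooled over a set):

* basal flanks are A-rich and unstructured;
* sampled unpaired columns are laid out as internal loops of at most two
  columns separated by near-equal contiguous helices. This is a
  deterministic placement of exchangeable draws from identical
  per-coordinate distributions, so per-coordinate marginals are exactly
  preserved — only the spatial clustering pattern is fixed. Planted
  coordinates are never moved;
* mismatch nucleotides are oriented (which nucleotide goes on which arm)
  to minimize spurious pairability with neighboring columns.

Similarly, the planted truth is emitted in the registration convention
(mismatches anchor-proximal within unpaired runs), so the pipeline
reproduces planted class maps *exactly* when run on ground-truth
structures. What the generator does **not** emulate: real species
composition and phylogenetic correlation between records, multi-branch
folds, length heterogeneity of natural precursors, and sequencing or
annotation noise. Passing recovery tests therefore demonstrates
correctness of the accounting machinery, not robustness to messy
real-world annotation.

## amiRNA design rules

`amirna_check()` maps the survey's empirical outcomes to severities:
identities with a greater-than-tenfold loss of mature miRNA in
mutagenesis fail (C-C anywhere; G-G at a cleavage site), roughly twofold
or context-dependent effects warn (G-G elsewhere; mismatch identities
outside A-C/U-C/U-U at cleavage sites; unpaired at the mostly-paired
coordinates 1, 3 and L+2). A C-C inside the duplex also gets an `info`
note for possible isomiR generation — a qualitative, possibly functional
effect, deliberately not a failure. Coordinate −1 being unpaired is
never penalized: roughly 40% of natural precursors are unpaired there.
All rules are individually toggleable; the verdict is the worst finding
severity, which makes it monotone under added defects.

## Numerical and degenerate-input choices

* Dot-bracket parsing is stack-based with positional error messages;
  pair tables are involutions by construction and asserted in tests.
* Folding is cached in memory per (sequence, engine, arguments) and
  deterministic for a fixed engine build.
* Invalid records (non-ACGU alphabet, out-of-range coordinates, miRNA
  length outside 19–25 nt, loop-spanning or unstructured miRNAs,
  uninferrable stars) are quarantined with a reason and reported —
  never silently dropped; `records_in = valid + quarantined` is logged.
* Empty surveys are an error; single-record matrices are degenerate but
  valid (one 100% cell per column).
* Problem sizes in the test-suite and acceptance runs: 500 synthetic
  precursors for recovery statistics, ~300 enumerated hairpins for the
  registration oracle, 60 (stem, interval) combinations for the overhang
  sweep — sizes at which every check is exact or has narrow binomial
  error while the whole suite stays fast.

## Known limitations

* Processing direction is an input, not a prediction; the 15–17 bp stem
  heuristic is deliberately not implemented as a classifier.
* The human comparison applies the plant cleavage-site coordinate
  convention to animal precursors — a like-for-like descriptive
  comparison, not a model of Drosha/Dicer cut placement; bundles carry
  an explicit caveat.
* No phylogenetic correction for shared ancestry among species in a
  group.
* MFE refolding of generated sequences occasionally slips a register
  around mismatch-adjacent wobbles; agreement is guaranteed only at the
  pooled ≥ 95% level, not per record.
* No pseudoknots, no partition-function analysis, and only the engine's
  first MFE structure is used.
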