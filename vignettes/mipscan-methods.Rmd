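---
title: "mipscan: methods and design notes"
author: "mipscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mipscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mipscan)
```

## The problem

MicroProteins are small proteins built around a single
protein-protein-interaction domain.  They are truncated relatives of
larger, multi-domain regulators — often transcription factors — and act
post-translationally: by heterodimerizing with the full-length relative
through the shared interaction domain, they sequester it into complexes
that lack the relative's other functional domains (DNA binding,
activation), or re-route it into repressive complexes.  The archetypal
plant example is the pair of miP1-type B-Box microProteins that bind the
flowering regulator CONSTANS and recruit TOPLESS co-repressors to it
through a short C-terminal motif.

`mipscan` packages the computational side of this biology: an ab initio
candidate screen over a proteome, the motif analytics used to characterise
B-Box microProteins and their TOPLESS-recruitment motifs, pairwise
identity for candidate/paralog comparisons, and the hypergeometric
statistics used to compare the downstream transcriptome signatures of a
microProtein and its target.

## The candidate screen

A protein is reported as a microProtein candidate when all three
computable criteria hold:

1. **Size.** Strictly fewer than `maxLength` residues (default 140).  The
   bound is strict: a 140-residue protein is rejected.  All characterised
   microProteins fall below this size, which is also small enough to
   exclude most "interfering proteins" — larger truncated regulators that
   are mechanistically different.
2. **Single interaction domain.**  The resolved domain architecture
   contains exactly one *distinct* domain accession, and that accession is
   on a whitelist of protein-interaction-capable domains.  Distinctness is
   counted per accession, not per occurrence, so a small protein carrying
   two copies of the same B-Box still counts as single-domain; this is a
   deliberate reading (the alternative — counting occurrences — would
   reject genuine microProteins with domain remnants) and is the one
   place where the screen's behaviour on repeated domains had to be
   decided rather than derived.
3. **Larger multi-domain relative.**  At least one other protein shares
   the accession, is strictly longer, and carries at least
   `minRelativeExtraDomains` (default 1) additional distinct domains.
   This operationalises "related to larger proteins" in the direction the
   microProtein mechanism requires: a target must have domains left to
   lose.  Relatedness by shared Pfam accession is deliberately coarse —
   it needs no alignment step and is robust to annotation versions — but
   it cannot separate paralogous subfamilies; see *Limitations*.

The fourth property of a genuine microProtein, a dominant-negative mode
of action, is an experimental observation and is intentionally not
encoded.

Targets are ranked by descending distinct-domain count, then descending
length, then id: the better-annotated, larger relative first.  Families
are labelled by the shared accession, which matches how candidate counts
per Pfam domain are usually summarised.

The whitelist ships as data
(`system.file("extdata", "ppi_domains.tsv", package = "mipscan")`), a
seed list covering zinc-finger (including the B-Box accession PF00643),
helix-loop-helix, and common plant transcription-factor domain classes.
It is a starting point, not an assertion: the historically used list for
any particular screen is not public, so the file is meant to be edited
per study.

## Domain-architecture resolution

Raw domain scans call overlapping models.  `resolveArchitecture()` ranks
hits best-first by E-value (ties: smaller start, then accession) and
greedily keeps a hit when its shared-residue count with every kept hit is
at most `overlapFraction` (default 0.5) of the shorter hit's length.  The
0.5 fraction tolerates ragged boundaries of adjacent repeats while
collapsing duplicate calls of the same region.  On up to six hits the
greedy result provably coincides with the rank-lexicographically best
pairwise-compatible subset (the test suite enumerates all subsets), so
the greedy step is an optimisation, not an approximation, at realistic
per-protein hit counts.  Pfam clans are *not* collapsed: distinctness is
by accession only, and clan-aware collapsing is left as an explicit
future hook.

## The consensus grammar

B-Box structures are written in the field as residue/spacer strings such
as `Cx2Cx8Cx7Cx2Cx4Hx8H` (CONSTANS/COL-type) and `Cx2Cx7Cx7Cx2Cx4Hx8H`
(miP1-type, one residue shorter).  `parseConsensus()` implements exactly
this notation: uppercase residue letters, `(A/B)` alternatives, `xN`
spacers (underscores and whitespace ignored), and every pattern has a
fixed match width — 38 and 37 for the two B-Box variants, 5 for
`PF(V/L)FL`, 5 for the EAR motif `LxLxL`.  Scanning reports *all* match
offsets, overlaps included, so downstream code chooses its own match
rather than inheriting a hidden leftmost-only rule.

Two C-terminal motif conventions differ on purpose:

* `PFVL-type` is **anchored**: the motif is defined as the last five
  residues, so it matches at the terminus or not at all.
* `EAR-type` (`LxLxL`) is only known to be carboxy-terminal, so it is
  searched within a window of the final 25 residues (rightmost match
  wins).  The window size is a flag, not a constant; 25 residues is wide
  enough for every EAR-motif position we are aware of in characterised
  TOPLESS clients and narrow enough to retain the "C-terminal" meaning.

The variant builders mirror the two classic perturbations: the
zinc-finger knockout (`makeBBoxDead()`: every C and H in the matched span
becomes A — all of them, including stray cysteines in spacer positions —
length preserved, idempotent) and the tail deletion (`truncateCTerm()`:
remove the last *n* residues, default 5).

## Pairwise identity

`globalAlign()` is a Gotoh affine-gap global aligner (a gap of length
*L* costs `gapOpening + gapExtension * L`; defaults BLOSUM62, 10, 0.5 —
the de facto standard for global protein alignment when no tool is
specified).  The traceback tie-break is fixed — diagonal, then vertical,
then horizontal — so results are reproducible to the byte.  Correctness
is tested three ways: exhaustive enumeration of all alignments for short
sequences, re-scoring of the emitted alignment strings, and score
agreement with the independent `Biostrings::pairwiseAlignment()`
implementation.

Percent identity is a *reporting convention*, not a property of the
alignment, and published identity figures rarely state their denominator.
`percentIdentity()` therefore offers all three common conventions
(alignment length — the default, shorter sequence, ungapped columns) so a
published figure can be located among them rather than assumed.

## Gene-set overlap statistics

`hypergeomSF()` computes the exact upper tail \(P(X \ge k)\) by log-space
term summation; this is the `phyper(k - 1, nA, N - nA, nB,
lower.tail = FALSE)` convention.  The tail convention had to be chosen
(the enrichment question is "at least this much overlap"), and it is
stated in the documentation and output rather than left implicit.  The
log-space form stays accurate where individual binomial coefficients
overflow, and a `log = TRUE` mode reports tails far below double
underflow.  Tests compare it to exact integer arithmetic (binomials are
integer-exact in doubles for universes up to 30) and to full enumeration
of draws.

`overlapReport()` requires an explicit universe (size or set).  Published
overlap analyses often leave the universe unstated — all annotated genes?
all expressed genes? — and the p-value moves by orders of magnitude
between those choices, so the package refuses to guess.  Both directional
percentages (`pct_of_a`, `pct_of_b`) are always reported, again so that a
published "X% overlap" can be matched to its actual denominator.

## What the synthetic generators emulate

The generators are first-class, tested code; every other module is
validated against them.

* `generateProteome()` plants candidate/target families and
  criterion-specific decoys: for each decoy class exactly one criterion is
  violated and the others hold (oversized; two-domain; single domain but
  off-whitelist, with its own larger relative so only the whitelist test
  fails; whitelisted but with no relative).  This one-violation-at-a-time
  construction makes a screen failure localise to a single criterion.
  Candidate lengths are drawn in 60–139 residues, targets in 200–400 with
  1–2 extra distinct domains anchored near the N terminus so a target
  always genuinely is multi-domain.
* `generateBBoxSequence()` plants a consensus-conforming span on a
  background drawn uniformly from the 18 non-C/H residues, which makes the
  planted span the *unique* match of its pattern — unrealistic
  composition, chosen so tests can assert exact offsets.
* `generateGeneSets()` plants an exact intersection size.
* `generateMiP1Exemplars()` builds a synthetic stand-in pair for the two
  characterised miP1-type proteins, reproducing their described structure
  — 121 and 117 residues, one intact miP1-type B-Box, a degenerate second
  B-Box remnant (its C/C/C/H skeleton only), the terminal `PFVFL`, the
  four-residue difference placed after the second B-Box — and their
  described ~65.5% mutual identity, implemented as 38 substitutions at
  non-conserved positions (on a clean 121-column alignment,
  \((117-38)/121 = 65.3\%\)).  These are labelled synthetic everywhere:
  they let the identity machinery demonstrate the described relationship
  without bundling third-party sequence data, and any analysis of the
  real proteins should substitute the real sequences.

All generators are driven by one integer seed through an internal
save/restore wrapper, so they are byte-deterministic and never disturb
the caller's RNG stream.

What the generators do **not** emulate: realistic residue composition,
homology between family members at the sequence level (family membership
is planted via the domain table, not via alignable sequence), correlated
domain-boundary noise, or annotation errors.  A perfect screen score on
these proteomes therefore demonstrates that the logic implements the
criteria exactly — not that the criteria themselves would achieve perfect
precision on a real proteome, where annotation quality and the whitelist
dominate the outcome.

## Problem sizes and numerical choices

The test-suite and acceptance-script problem sizes are chosen to exercise
every code path while keeping a full run in seconds: five planted
proteomes of ~200 proteins (144 candidates in 12 families, 16 decoys
across all four classes, background) for the screen; sequences up to 6
residues for exhaustive alignment enumeration (8,989 monotone paths at
6x6); universes up to 30 for exact hypergeometric arithmetic; 200-mers
for scanner/naive-matcher equivalence.  Screen precision and recall are
exact set comparisons against the truth table, not thresholds.

Numerical details worth knowing:

* Alignment DP uses a −10^18 sentinel rather than `-Inf` to keep
  arithmetic finite; traceback re-derives each step from the recurrence
  within 10^-9, with a defensive fall-back to the best predecessor.
* `hypergeomSF()` clamps at 1 (log at 0) against round-off.
* Coordinates are 1-based inclusive throughout, matching Pfam/HMMER
  reporting; accession versions are stripped on ingest so architecture
  counting is Pfam-release-independent.
* Report writers sort deterministically (family then id; descending
  carrier counts then accession) and write through a binary connection so
  repeated runs are byte-identical across platforms.

## Limitations

* The screen is annotation-driven: proteins missing from the domain table
  are invisible, and the whitelist is the single most influential input.
* Shared-accession relatedness cannot distinguish subfamilies; a
  candidate may list targets from a paralogous clade it never meets
  in vivo.
* Consensus patterns are strict: degenerate family members whose final
  histidine (for example) deviates from the consensus will not match, by
  design — relaxations belong in the pattern text, which is user-facing.
* The hypergeometric test assumes exchangeable genes within the universe;
  expression-level or length biases in differential-expression calls
  violate this silently, as for any such overlap test.
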