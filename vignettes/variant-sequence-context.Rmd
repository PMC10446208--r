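---
title: "Annotating the sequence context of genomic variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating the sequence context of genomic variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varcontext)
```

## Motivation

A VCF record pins a variant to a single position, but the position of an
indel inside repetitive sequence is a representational choice, not a
biological fact: deleting any one `GC` unit from a `(GC)x7` tract produces
the same mutated chromosome. `varcontext` makes that equivalence class
explicit and annotates each variant with the coordinates, flanks, HGVS
description, inter-variant distances and tandem-repeat structure of its
local sequence context.

## Normalization

Every record is first split into biallelic records (the retained ALT
becomes allele 1 in the genotype; all other ALT indices become missing,
with phasing separators preserved — the most conservative remapping that
invents no genotype information) and then normalized:

1. SNVs pass through unchanged.
2. While the rightmost bases of REF and ALT agree, they are trimmed; if an
   allele would become empty, both alleles are extended one reference base
   to the left and the position is decremented.
3. While both alleles are longer than one base and share their leftmost
   base, that base is trimmed and the position incremented.

The result is parsimonious (no shorter representation exists with
non-empty alleles) and left-aligned (the position cannot move further 5'
at constant allele lengths). Right-trimming runs to completion before
left-trimming; interleaving the two phases differently can leave output
that is not left-aligned. A variant whose left extension would run past
the contig start is returned unchanged with a warning and flagged
`normalized = FALSE`; this is the only input the normalizer declines.
Bases are compared case-insensitively and output uppercased.

The package carries an independent check: `oracle_normalize()` enumerates
*all* representations producing the same mutated sequence (using common
prefix/suffix lengths between wildtype and mutated sequence, so each
candidate is O(1) to validate) and returns the minimal-length, leftmost
one. The test suite and the acceptance script compare the trim-and-extend
normalizer against this oracle on 10^4 random references (≤ 300 bp) and
variants (indels ≤ 10 bp), generated with embedded repeat tracts in 60% of
cases so that ambiguity is common rather than exceptional.

## Breakpoint ambiguity

For a pure indel the *indel pattern* is the anchor-trimmed REF (deletion)
or ALT (insertion). Starting from the left-aligned record, the pattern
(a₁…aₙ) is compared with the reference bases immediately 3' of the indel;
while the pattern's first base matches the next reference base the pattern
rotates left by one and the 3'-edge advances. The annotation is:

* deletion: 5'-aligned = first deleted base of the left-aligned record
  (`pos + 1`); 3'-edge = last base reached by the walk; 3'-aligned =
  `edge − n + 1`, the first base of the 3'-most deleted run. With these
  conventions `three − five` equals the total shift range, so
  `ambiguous ⇔ five ≠ three` exactly. A definition of the 3'-aligned
  position as "the edge minus the pattern length" admits an off-by-one
  reading (first versus last base of the 3'-most run); we fix the
  convention by requiring agreement with the enumeration oracle's min/max
  statistics, under which the 3'-aligned position is the first base of the
  3'-most deleted run.
* insertion: 5'-aligned = the record position (the leftmost possible
  5'-adjacent base); 3'-aligned = 3'-edge = the rightmost possible anchor.
* SNV/MNV/complex records (e.g. REF `CATTC`, ALT `G`) contain a point
  change at a fixed position and are never ambiguous; their edge is the
  last REF base.

An indel is *in duplicate* when the shift range spans at least one full
copy of the pattern: the deletion removes one copy of a duplicated
sequence, or the insertion creates or extends one.

`oracle_equivalent_placements()` provides the second dual route: it
enumerates every same-length placement reproducing the mutated sequence,
and the 5'-aligned/3'-edge positions must equal its min/max statistics.
One boundary case is excluded by construction: an insertion whose
equivalence class reaches the contig start (placement 0) cannot be
expressed as an anchored VCF record, and such records are already flagged
unnormalized upstream.

Inter-variant distance is the count of reference bases strictly between
one variant's 3'-edge and the next variant's 5'-aligned position — both
ends of the interval come from the equivalence classes, not from raw POS —
which reproduces the 4 bp of the worked dinucleotide scenario. Distances
require position-sorted input; the pipeline verifies sortedness per contig
and errors otherwise rather than silently reporting negative gaps.
Overlapping spans report distance 0 with a note. BED annotation likewise
matches intervals against the closed span `[five, edge]`, so variants
partially overlapping or shifted into an interval are still labelled.

For sequence extraction, all normalized variants inside the requested
region are applied right-to-left to the wildtype substring. Overlapping
variants are a hard error: no precedence rule is defined, and silently
choosing one would fabricate a haplotype.

## Tandem-repeat discovery

The engine explores repeats that overlap *or touch* the variant's
ambiguity span. The *variant site* is the coordinate pair flanking
`[five − 1, edge + 1]`; every reference window of size `min_unit` to
`max_unit` (default 1–6 bp, the conventional STR motif range) intersecting
that closed interval seeds a candidate motif.

From each anchor the search proceeds 5' first, then 3'. In each round the
candidate set holds the same-size windows at gap 0…max_gap (default: one
motif length; a fixed bound may be supplied). Candidates are scored by
positionwise base identity with the current motif; the highest score wins,
ties go to the smallest gap, and the winner is accepted as a repeat unit
if its score reaches `similarity_threshold × w`. The search continues from
the accepted unit and stops at the first failing round. One consequence of
the highest-score rule worth noting: with the default gap bound a single
impure unit inside an otherwise perfect tract is *skipped via a gap*
(the perfect unit one motif-length away outscores it) rather than accepted
as a mismatch; mismatched units are accepted when no better candidate
exists within the gap bound.

Because fewer than five units cannot establish a consensus over a 4-letter
alphabet, the anchor subsequence itself is the comparison motif for the
first four rounds; from the fifth unit onwards the motif becomes the
per-position majority consensus of all collected units (ties resolve
toward the anchor's base) and keeps updating. At assembly, all units —
including those accepted in the first four rounds — are re-scored against
the final motif; we read "replacing" the early rounds' results as this
recomputation rather than overwriting the unit sequences, which would
discard observed bases.

A region's statistics follow the alignment view against an ideal perfect
repeat of the same motif and copy number:

\[
\mathrm{AlignmentScore} = MS\cdot match + MIS\cdot mismatch + GS\cdot gap,
\qquad
\mathrm{RepeatScore} = \frac{\mathrm{AlignmentScore}}{\mathrm{length}}
\times \mathrm{copy}
\]

with defaults MS = 2, MIS = −5, GS = −7 — magnitudes conventional in
tandem-repeat alignment scoring; the identities hold for any consistent
triple, and all three are user-visible parameters. Gap bases are the
summed inter-unit distances and are excluded from match/mismatch counts,
so `match + mismatch + gap = region length` exactly; percentages use the
region length as denominator. For a perfect tract `(m)^k` with `|m| = w`
this gives the closed forms `AlignmentScore = MS·w·k` and
`RepeatScore = MS·k`, which the acceptance checks verify for every motif
size.

Quality control keeps regions with copy number, match percentage and
alignment score above their floors. When no candidate passes, the
best-alignment candidate is trimmed: outermost units are removed one at a
time from whichever end leaves the higher alignment score (ties prefer
trimming the 3' tail), statistics are recomputed each step, and the
process stops at the first passing region or abandons the candidate when
the copy number would fall below its floor. Redundant nested motifs (such
as `ATAT` over an `AT` tract) are then removed: regions are ranked by
repeat score (ties by copy number), and for any pair whose
overlap-to-union span ratio strictly exceeds 0.5 the member whose motif
base-frequency vector is closer (L1) to its whole-span base frequency is
kept, ties favouring the higher rank. We read the redundancy denominator —
the "maximum covered region" of the pair — as the union span; the strict
inequality at 0.5 is covered by a dedicated test. Finally GC% is computed
over the reference span and the copy-number change of a length-changing
variant is `(len(ALT) − len(REF)) / w`, deliberately fractional when the
indel is not a whole number of units, and 0 for substitutions.

Two parameter profiles are provided. `tr_profile("perfect")` restricts
reporting to perfect STRs: similarity and match percentage 100%, minimum
region length 10 bp (expressed as minimum alignment score `MS × 10`), and
minimum copy numbers 10/5/4 for mono-/di-/tri- to hexanucleotide motifs —
floors in line with studies of slippage-prone microsatellites.
`tr_profile("imperfect90")` relaxes unit similarity and purity to 90%.
Variants with `N` in an allele are skipped by the repeat module (an `N`
never matches any base, so every similarity involving it is spurious);
other modules process such records literally and the ambiguity walk
treats `N` as matching nothing.

## What the synthetic fixtures do and do not show

`make_reference()` embeds perfect tracts into random backgrounds and
guards both tract boundaries with bases that break motif continuation, so
truth copy numbers are exact; `make_vcf()` writes anchored VCF records,
optionally re-encoded at their 3'-most placement (`shift_3prime()`) to
exercise the normalizer. Hostile-flank constructions (flank alphabet
disjoint from the motif) are used where a test needs *only* the embedded
tract to be discoverable at threshold 1.

These fixtures emulate coordinates, repeat structure and encoding
degeneracy — the inputs the algorithms actually consume. They do not
emulate sequencing error, alignment artefacts, real genomic repeat-length
and GC distributions, or structural variation; passing tests therefore
demonstrate algorithmic correctness on well-formed VCF + FASTA input, not
calling accuracy on real data. Problem sizes were chosen to keep the full
suite around a minute: 10^4 oracle-comparison cases on references ≤ 300 bp
for each of the two equivalence checks, and repeat fixtures up to 72 bp of
tract.

## Numerical and design choices

* Genotype remapping after multiallelic splitting (kept ALT → `1`, other
  ALTs → `.`) is a documented choice; the input conventions do not
  prescribe one.
* Contig names must match the FASTA exactly; no `chr`-prefix fuzzing.
  A REF/FASTA mismatch is fatal, as it almost always signals a wrong
  reference build.
* Symbolic (`<DEL>`, breakends) and non-ACGTN alleles are skipped with a
  warning; records with `N` alleles are read and processed literally
  except by the repeat module.
* HGVS `dup` detection compares the inserted sequence (in its 3'-most
  rotation) with the immediately preceding reference run of equal length;
  higher-order repeats still report a single-unit `dup`, the minimal
  HGVS-compliant description. Descriptions are DNA-level (`g.`) only.
* Output tables use `.` for not-applicable cells; when several repeat
  regions survive for one variant, the variant row is repeated once per
  region.
* The similarity threshold is applied as `score ≥ threshold × w − 1e-9`
  to keep fractional thresholds such as 2/3 exact at small `w`.

## Limitations

* No right-alignment mode and no haplotype-aware normalization across
  records.
* No transcript-level (c./p.) HGVS.
* Repeat discovery is variant-anchored; the package is not a genome-wide
  repeat scanner and does not genotype STRs from reads.
* The trimming step is greedy (one outermost unit per step); pathological
  tails that would require non-greedy removal to rescue a region are
  abandoned instead.
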