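# varcontext

Sequence-context annotation of genomic variants in R.

Variant callers report a variant as a single (POS, REF, ALT) triple, but an
indel inside repetitive sequence does not have one well-defined breakpoint:
the same change can be placed anywhere inside a microhomologous region and
produce an identical mutated sequence. That ambiguity affects variant
comparison, HGVS reporting, distance calculations between variants, and any
annotation that treats POS as the only affected coordinate. `varcontext`
takes a VCF and a reference FASTA and annotates each variant with its full
local sequence context:

* **Normalization** — multiallelic records are split into biallelic ones and
  every variant is made *parsimonious* (as few nucleotides as possible with
  no zero-length allele) and *left-aligned* (its position cannot shift
  further 5' at constant allele lengths), by right-trimming shared bases
  (extending from the reference when an allele would empty) and then
  left-trimming.
* **Breakpoint ambiguity** — for each indel the 5'-aligned position
  (leftmost equivalent placement), 3'-aligned position (rightmost equivalent
  placement) and 3'-edge position (rightmost affected reference base) are
  computed by rotating the anchor-trimmed indel pattern (a₁a₂…aₙ) along the
  3' reference sequence. A variant is *ambiguous* when its 5'- and
  3'-aligned positions differ, and *in duplicate* when the shift range
  covers at least one full copy of the pattern.
* **Adjacent-sequence annotations** — flanking bases including the full
  REF/ALT ambiguity segments, HGVS DNA-level nomenclature under the 3' rule
  (`g.103del`, `g.135_136dup`, `delins`, …), 3' distances between
  consecutive variants, wildtype/mutated/reverse-complement sequences of a
  user-chosen region, and custom BED-interval annotation against the whole
  affected span rather than POS alone.
* **Tandem-repeat discovery** — a local sequence-context comparison
  algorithm seeds candidate motifs of size 1–6 bp at the variant site and
  extends them unit by unit in both directions with a similarity threshold
  and bounded gaps. Each reported region carries

  ```
  AlignmentScore = MS·match_bases + MIS·mismatch_bases + GS·gap_bases
  RepeatScore    = AlignmentScore / region_length × copy_number
  ```

  plus match/mismatch/gap percentages, GC% and the signed copy-number
  change caused by the variant. Post-processing trims ragged tails that drag
  a region below the quality floors and removes redundant nested motifs
  (redundancy ratio = overlap/union of spans, strictly > 0.5).

The package also ships a first-class fixture module (`make_reference`,
`make_vcf`) that embeds guarded repeat tracts in synthetic references, and
brute-force oracles (`oracle_normalize`, `oracle_equivalent_placements`)
that exhaustively enumerate equivalent representations, so every annotation
path is verifiable without external data.

## Worked example

Build a 300 bp synthetic contig with a (GC)×7 tract at 123–136, spike a GC
deletion (anchored at 122) and an SNV at 141, and annotate:

```r
library(varcontext)

fx  <- make_reference(300, repeats = list(list(motif = "GC", copies = 7,
                                               start = 123)),
                      name = "chr_example", seed = 42)
seq <- fx$sequences[[1]]
write_sequences(fx$sequences, "demo_ref.fa")
make_vcf(list(
  variant_record("chr_example", 122, substr(seq, 122, 124),
                 substr(seq, 122, 122), id = "del_gc", gt = "0/1"),
  variant_record("chr_example", 141, substr(seq, 141, 141), "A",
                 id = "snv_3p", gt = "1/1")
), fx$sequences, "demo.vcf")

res <- run_annotation("demo.vcf", "demo_ref.fa", "demo_out",
                      ambiguity = TRUE, flank = 3, hgvs = TRUE,
                      distance = TRUE, tandem_repeat = TRUE,
                      params = tr_profile("perfect"))
```

The same run is available from the shell:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "varcontext.R",
                                      package = "varcontext"))') \
  --vcf demo.vcf --ref demo_ref.fa --out demo_out \
  --ambiguity --flank 3 --hgvs --distance --tandem_repeat --profile perfect
```

`demo_out.tsv` then contains (columns abridged):

```
id      five three edge ambiguous in_duplicate hgvs                     dist tr_motif tr_copy tr_gc tr_copy_change
del_gc  123  135   136  TRUE      TRUE         chr_example:g.135_136del 4    GC       7       100   -1
snv_3p  141  141   141  FALSE     FALSE        chr_example:g.141C>A     .    .        .       .     .
```

Reading the first row: the GC deletion can sit anywhere in the tract
(5'-aligned 123, 3'-aligned 135, edge 136, hence ambiguous and inside a
duplication), HGVS places it at the 3'-most copy, the next variant is 4 bp
downstream of the edge, and the variant removes one copy (copy change −1)
of a 7-copy, 100% GC dinucleotide repeat whose alignment score is
2×14 = 28 and repeat score 28/14×7 = 14.

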