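# liftkit

Lift SAM/BAM alignments from a variant-aware reference back to the
standard reference it was built from, using the VCF that defines their
differences — no chain file required.

## Why

Aligning reads to one linear reference genome biases results toward
reference alleles. A standard mitigation is to align against a
*variant-aware* reference (for example a major-allele reference), which is
defined as the standard reference plus a VCF of SNVs and indels. The
resulting alignments are in the wrong coordinate system for every
downstream tool, and each indel in the VCF shifts positions, reshapes
CIGAR strings and invalidates MD/NM tags. `liftkit` translates the
alignments back, streaming, in input order, with identical output for any
worker count.

## The core structure

For each contig the implied pairwise alignment between the source
(variant-aware) and target (standard) sequence is a sequence of columns;
each column carries a source base, a target base, or both. Two bit
vectors over the columns — `src_bv` (column has a source base) and
`tgt_bv` (column has a target base) — encode the whole map. With the
classic succinct-bitvector queries `rank1` (set bits before a position)
and `select1` (position of the k-th set bit), a 0-based source position
`s` lifts to

```
t = rank1(tgt_bv, select1(src_bv, s + 1))
```

A source base with no target counterpart (inserted base) maps to the next
target base, clamped at the contig end. CIGAR strings are lifted by
composing the read→source alignment with the source→target column map:
matches over inserted bases become insertions, deleted target bases
crossed by the alignment inject deletions (widening `N` gaps when they
fall inside a splice), and the query-consuming length is conserved
exactly. MAPQ and FLAG pass through unchanged.

## Worked example

A 16 bp target contig with one 2 bp insertion (`T>TGG` at position 4) and
one 2 bp deletion (`ACG>A` at position 9):

```r
library(liftkit)

calls <- data.frame(chrom = "chr22",
                    pos   = c(4L, 9L),
                    ref   = c("T", "ACG"),
                    alt   = c("TGG", "A"))
idx <- build_index(calls, contig_lengths = c(chr22 = 16L))
idx
#> <lift_index> v1, 1 contig(s)
#>   chr22 -> chr22: source 16 bp, target 16 bp, 18 columns
```

18 columns: 16 target bases plus 2 inserted ones (2 of the 18 are
deletion columns with no source base, so the source is also 16 bp).
Positions lift through rank/select; the two inserted bases (source
positions 4–5) map to the next target base, and everything after the
deletion shifts back:

```r
lift_pos(idx, "chr22", c(0, 5, 6, 9))
#> [1] 0 4 4 7
```

A 6 bp alignment starting at source position 2 spans the insertion, so
two of its matched bases become an insertion in target coordinates:

```r
res <- lift_cigar(idx$contigs$chr22, 2L, "6M")
res$t_pos
#> [1] 2
res$cigar
#> [1] "2M2I2M"
```

At the stream level: `run_index()` builds and serializes the index from a
VCF (`.lft` file), `run_lift()` rewrites a SAM/BAM stream (header `@SQ`
lines included), and `export_chain()` writes the same map as a UCSC chain
file. The same operations are available from the shell via the bundled
script:

```sh
exec/liftkit index -v calls.vcf.gz -F ref.fa.fai -o calls.lft
aligner ... | exec/liftkit lift -l calls.lft -a - -o out.bam -t 4 --md -f ref.fa
```

A fixture module (`gen_genome`, `gen_variants`, `apply_variants`,
`simulate_reads`) generates random genomes, call sets and reads with
known lifted truth, plus brute-force oracles (`oracle_lift`,
`oracle_lift_cigar`, `chain_interpreter`) that re-derive every result by
linear scans — the test suite checks the succinct implementation against
them everywhere.

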