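---
title: "Lifting alignments between a variant-aware and a standard reference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lifting alignments between a variant-aware and a standard reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liftkit)
```

## The problem

Aligning reads to a single linear reference biases alignments toward
reference alleles: reads carrying alternate alleles accumulate spurious
mismatches, lose score, and are sometimes misplaced or dropped. A common
mitigation is to align against a *variant-aware* reference — for example a
major-allele reference, in which each known variant site carries the
population's most common allele. Such references are not distributed as
sequence: they are defined by the standard reference plus a VCF of SNVs and
indels. After alignment, coordinates refer to the variant-aware ("source")
sequence and must be translated back to the standard ("target") reference
before any downstream tool can use them.

SNVs leave coordinates untouched, but every indel shifts all downstream
positions, changes alignment CIGAR strings that span it, and invalidates
MD/NM tags. `liftkit` performs this translation as a streaming transform
over SAM/BAM: position, CIGAR (including spliced `N` alignments), mate
fields and template length are rewritten; MAPQ, FLAG, SEQ, QUAL and all
other tags pass through unchanged; MD and NM can optionally be recomputed
against the target FASTA.

## The coordinate map

For each contig, picture the pairwise alignment between the source and
target version of the sequence as a sequence of columns. Every column
contributes a base to the source, to the target, or to both:

* both — an unaffected base or a SNV site (coordinates unchanged);
* source-only — a base inserted by an ALT longer than its REF;
* target-only — a base deleted by an ALT shorter than its REF.

Two bit vectors over the columns encode this completely: `src_bv[c] = 1`
iff column `c` has a source base, `tgt_bv[c] = 1` iff it has a target
base (no column is 0 in both). With rank/select support —
`rank1(bv, i)` counts set bits in `[0, i)` and `select1(bv, k)` finds the
k-th set bit — a source position `s` lifts to

```
t = rank1(tgt_bv, select1(src_bv, s + 1))
```

`select1` locates the column holding source base `s`; `rank1` counts the
target bases before it, which for a both-column is exactly the target
coordinate. The conventions (exclusive-prefix rank, 1-based select
ordinal) follow the succinct-data-structure literature. In this
implementation both queries are O(1) after an O(n) build: the rank
directory is a full cumulative-sum table and the select directory an array
of set-bit positions. This spends O(n) words in memory rather than o(n)
extra bits — a deliberate simplicity/space trade-off at the contig sizes R
users handle; the on-disk form (below) is bit-packed.

### Building the map from a VCF

`build_index()` walks the sorted site list left-to-right, emitting
both-columns for the gaps between variants, then the variant's own
columns. Standard anchored indels share a leading base between REF and
ALT; the shared prefix emits both-columns and only the surplus bases emit
one-sided columns. Records that are not left-anchored are normalized by
trimming the longest shared REF/ALT suffix (keeping at least one base each
side) before the shared-prefix/surplus split, so equivalent descriptions
of the same indel produce the same map.

Imperfect population VCFs are screened rather than fatal: multi-allelic
records contribute their first ALT only (the major-allele use case has one
chosen allele per site), records overlapping an earlier REF span are
skipped, and symbolic (`<DEL>`, `<INS>`), breakend or non-ACGTN alleles
are skipped — each with a warning. An unsorted VCF is an error, since the
builder is a single left-to-right pass. Genotype columns are ignored: the
map depends only on CHROM/POS/REF/ALT.

### Positions inside insertions

A source base with no target counterpart (an inserted base) has no exact
image. `lift_pos()` maps it to the **next** target base —
`rank1(tgt_bv, c)` evaluated at its column — clamped to
`target_length - 1` for an insertion at the very end of a contig. The
alternative (previous target base) was equally defensible; "next" was
chosen because it yields a valid, sort-stable POS for reads that start
inside an insertion, and it makes `lift_pos` agree with the target start
that CIGAR composition produces for such reads. The choice is fixed
everywhere: index queries, the brute-force oracles and the chain
interpreter all implement it, so tests compare implementations, not
conventions.

## Lifting a CIGAR

A read's CIGAR describes read→source; the map describes source→target;
the lifted CIGAR is their composition, computed one source base at a time:

* query-only ops (I, S, H, P) pass through untouched;
* a reference-consuming base in a both-column keeps its op;
* a base in a source-only column is an inserted reference base: M/=/X
  become I (the read base has nothing to align to in the target — the
  match/mismatch distinction is unrecoverable by construction), while D
  and N spans simply shrink;
* target-only columns crossed between two consumed source bases are
  deleted target bases and inject D.

Adjacent identical ops merge and zero-length ops are never emitted, so
the output is canonical. The query-consuming length is conserved exactly
— SEQ and QUAL are never touched.

Two boundary rules need care:

* **Splices.** An injected deletion that falls against a spliced run is
  absorbed into the N instead: the intron simply widens. `2M1N2M` lifted
  across a 2-base deletion inside the skip becomes `2M3N2M`, not a D/N
  sandwich. D and N are never merged with each other; deleted columns
  between two M bases stay D.
* **Reads inside insertions.** If no both-column is covered at all, the
  read has no target interval. It is returned unmapped (FLAG 0x4, CIGAR
  `*`) with POS at the lifted anchor so that coordinate-sorted output
  remains stable, and counted in the run summary. Dropping such records
  silently would break pairing downstream.

Terminal I runs produced by the conversion are SAM-legal but rejected by
some downstream tools; `clip_leading_insertions` converts them to soft
clips at both ends, merging with existing clips.

## Mate fields and TLEN

Mate lookup is stateless — the streaming contract is bounded memory, so
mates are never paired up in RAM. PNEXT is lifted through the index like
any position (the `=` RNEXT convention is preserved). TLEN is recomputed
whenever both mates are mapped to the same contig: the leftmost mate
(positive TLEN) lifts its template end coordinate `POS + TLEN` through
the map and reports the difference from its own lifted start; the
rightmost mate reports the negated distance from its lifted PNEXT to its
own lifted alignment end. For the outermost-coordinate TLEN convention
this reproduces `|TLEN| = rightmost end − leftmost start` on both mates,
with opposite signs, without ever seeing the mate record. Whether the
original tool recomputes or copies TLEN is not observable from its
description; recomputation was chosen because positions move under
lifting and a stale TLEN is inconsistent with the rewritten coordinates.

## MD and NM

With a target FASTA supplied, MD/NM are rebuilt by walking the lifted
CIGAR against the reference: NM is mismatched M/=/X positions plus all I
and D bases; MD alternates match-run counts, mismatched reference bases
and `^`-prefixed deleted runs, beginning and ending with a (possibly
zero) count. N ops contribute to neither tag. Existing MD/NM are
replaced; every other tag is preserved byte-for-byte.

## Serialization and chain export

Indexes are saved as a small binary container (suffix `.lft`): magic
bytes, a format version, then per contig the length-prefixed source and
target names, the column count, and the two bitvectors packed into
little-endian 64-bit words. Loading reproduces bitwise-identical
bitvectors, so a population call set is parsed once and reused.

The same column map can be exported as a UCSC chain file for
interoperability with classic lift-over tools: one chain block per contig
with `size dt dq` lines from a run-length scan of the columns (`dt` =
source-only run, `dq` = target-only run), score reported as the source
size since no alignment scoring is performed. A brute-force chain
interpreter ships with the fixture module and is tested to lift every
position identically to `lift_pos()`.

## Streaming and determinism

`run_lift()` rewrites the header once (`@SQ` renamed/resized through the
index, one `@PG` appended), then processes body records in fixed-size
batches of 8192. With `threads > 1`, batches are lifted by forked workers
but reassembled by sequence number before writing, so output is
byte-identical for any worker count — determinism is a contract, not an
accident of scheduling. Per-record failures (malformed lines, contigs
missing from the index) never abort the stream: the record passes through
unchanged and is counted in the summary printed to standard error. BAM
input/output is converted at the edges via Rsamtools; `-` denotes
standard input/output for use in aligner pipes.

## The fixture generator and what passing tests mean

All tests run on synthetic fixtures built in code: a uniform-ACGT target
contig, a sorted anchored call set (`gen_variants`), the source sequence
obtained by splicing ALTs in (`apply_variants`) — which also records the
explicit per-column map used as the brute-force oracle — and error-free
reads sampled from the source with truth coordinates from the oracle
composer. Default rates are 0.01 SNV/bp and 0.002 insertions and
deletions/bp with indel lengths uniform in 1–10 bp: denser than a human
population call set so that kilobase-scale contigs carry enough indels to
exercise every code path, while keeping the SNV majority real call sets
show. Generated variants keep at least one untouched base between
consecutive REF spans, so deletion and insertion columns from different
records are never adjacent and the column order within an inter-variant
gap is unambiguous (real VCFs may place indels back-to-back; the builder
accepts them, emitting the earlier record's columns first).

The generator emulates none of the messiness of real data — no sequencing
errors beyond optional uniform substitutions, no quality modeling, no
repeats or low-complexity structure, no structural variation. Passing
tests therefore demonstrate the coordinate arithmetic is exact under the
stated conventions, not that any aligner's output on real reads is
biologically correct after lifting.

Test problem sizes: contigs of 5–10 kb, 200 random fixtures with 1 000
reads each for the oracle-equivalence suite, 100 000 records for the
worker-determinism suite, 50 serialization round trips.

## Limitations

* Only SNVs and indels: symbolic, breakend, copy-number and inversion
  records are skipped with warnings, matching the stated scope of
  VCF-derived variant-aware references.
* One ALT per site; haplotype-resolved lifting means building one index
  per haplotype VCF.
* MAPQ is passed through, never recalibrated, and no re-alignment is
  performed; reads lifted onto an insertion boundary keep their original
  quality even though their target alignment is shorter.
* Aligner-specific tags (SA, XA, AS) pass through verbatim and may be
  stale in target coordinates.
* CRAM is not supported; BED/GFF interval lifting is exposed only via the
  position API, not the CLI.
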