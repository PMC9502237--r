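# Fixed toy maps: target chr1=ACGTACGT with either an insertion
# (pos 3 G>GAA, source ACGAATACGT) or a deletion (pos 2 CGT>C, source ACACGT).
ins_fx <- function() {
  v <- data.frame(chrom = "chr1", pos = 3L, ref = "G", alt = "GAA",
                  stringsAsFactors = FALSE)
  build_index(v, contig_lengths = c(chr1 = 8L))
}
del_fx <- function() {
  v <- data.frame(chrom = "chr1", pos = 2L, ref = "CGT", alt = "C",
                  stringsAsFactors = FALSE)
  build_index(v, contig_lengths = c(chr1 = 8L))
}

test_that("lift_cigar reproduces the hand-worked compositions", {
  idx <- build_index(data.frame(chrom = character(0), pos = integer(0),
                                ref = character(0), alt = character(0)),
                     contig_lengths = c(chr1 = 8L))
  r <- lift_cigar(idx$contigs$chr1, 1L, "3M2I1M")
  expect_identical(r$t_pos, 1L)
  expect_identical(r$cigar, "3M2I1M")

  r <- lift_cigar(ins_fx()$contigs$chr1, 2L, "5M")
  expect_true(r$mapped)
  expect_identical(r$t_pos, 2L)
  expect_identical(r$cigar, "1M2I2M")

  cl <- del_fx()$contigs$chr1
  r <- lift_cigar(cl, 0L, "4M")
  expect_identical(r$t_pos, 0L)
  expect_identical(r$cigar, "2M2D2M")

  # spliced: the two deleted target bases are absorbed into the N gap
  r <- lift_cigar(cl, 0L, "2M1N2M")
  expect_identical(r$t_pos, 0L)
  expect_identical(r$cigar, "2M3N2M")
})

test_that("malformed CIGARs and out-of-bounds alignments are errors", {
  cl <- ins_fx()$contigs$chr1
  expect_error(lift_cigar(cl, 0L, "5Q"), "malformed")
  expect_error(lift_cigar(cl, 0L, "M5"), "malformed")
  expect_error(lift_cigar(cl, 8L, "5M"), "outside source contig")
})

test_that("terminal insertions can be converted to soft clips", {
  cl <- ins_fx()$contigs$chr1
  # alignment starting on the inserted bases: leading M becomes I
  r <- lift_cigar(cl, 3L, "4M")
  expect_identical(r$cigar, "2I2M")
  r <- lift_cigar(cl, 3L, "4M", clip_leading_insertions = TRUE)
  expect_identical(r$cigar, "2S2M")
  # existing clip merges with the converted run
  r <- lift_cigar(cl, 3L, "1S4M", clip_leading_insertions = TRUE)
  expect_identical(r$cigar, "3S2M")
  # trailing side
  r <- lift_cigar(cl, 0L, "5M")
  expect_identical(r$cigar, "3M2I")
  r <- lift_cigar(cl, 0L, "5M", clip_leading_insertions = TRUE)
  expect_identical(r$cigar, "3M2S")
})

test_that("alignments entirely inside an insertion come back unmapped", {
  cl <- ins_fx()$contigs$chr1
  r <- lift_cigar(cl, 3L, "2M")
  expect_false(r$mapped)
  expect_identical(r$t_pos, 3L)   # anchor: next target base

  rec <- list(qname = "r1", flag = 0L, rname = "chr1", pos = 3L, mapq = 37L,
              cigar = "2M", rnext = "*", pnext = -1L, tlen = 0L,
              seq = "AA", qual = "II", tags = character(0))
  out <- lift_record(rec, ins_fx())
  expect_identical(attr(out, "lift_status"), "unmapped_by_lift")
  expect_identical(bitwAnd(out$flag, 4L), 4L)
  expect_identical(out$pos, 3L)
  expect_identical(out$cigar, "*")
})

test_that("lift_record preserves the untouched fields", {
  fx <- make_fixture(21L)
  sim <- simulate_reads(fx$source["chr1"], fx$map, 60L, read_len = 80L,
                        seed = 4L, feature_frac = 0.3)
  for (k in seq_along(sim$records)) {
    rec <- sim$records[[k]]
    out <- lift_record(rec, fx$index)
    expect_identical(out$qname, rec$qname)
    expect_identical(out$mapq, rec$mapq)
    expect_identical(out$seq, rec$seq)
    expect_identical(out$qual, rec$qual)
    if (attr(out, "lift_status") == "lifted") {
      expect_identical(out$flag, rec$flag)
      pin <- parse_cigar(rec$cigar)
      pout <- parse_cigar(out$cigar)
      qin <- sum(pin$lens[pin$ops %in% c(0L, 1L, 4L, 7L, 8L)])
      qout <- sum(pout$lens[pout$ops %in% c(0L, 1L, 4L, 7L, 8L)])
      expect_identical(qout, qin)
      # reference span consistency with the lifted end of the alignment
      span_in <- sum(pin$lens[pin$ops %in% c(0L, 2L, 3L, 7L, 8L)])
      span_out <- sum(pout$lens[pout$ops %in% c(0L, 2L, 3L, 7L, 8L)])
      expect_lte(out$pos + span_out, target_length(fx$index, "chr1"))
      expect_identical(out$pos + span_out,
                       liftkit:::lift_end(fx$index$contigs$chr1,
                                          rec$pos + span_in))
    }
  }
})

test_that("unmapped input records pass through untouched", {
  fx <- make_fixture(22L)
  rec <- list(qname = "u1", flag = 4L, rname = "*", pos = -1L, mapq = 0L,
              cigar = "*", rnext = "*", pnext = -1L, tlen = 0L,
              seq = "ACGT", qual = "IIII", tags = c("RG:Z:rg1"))
  out <- lift_record(rec, fx$index)
  expect_identical(attr(out, "lift_status"), "passed_through")
  attr(out, "lift_status") <- NULL
  expect_identical(out, rec)
})

test_that("records on contigs absent from the index pass through", {
  fx <- make_fixture(23L)
  rec <- list(qname = "x1", flag = 0L, rname = "chrUn", pos = 10L, mapq = 9L,
              cigar = "4M", rnext = "*", pnext = -1L, tlen = 0L,
              seq = "ACGT", qual = "IIII", tags = character(0))
  out <- lift_record(rec, fx$index)
  expect_identical(attr(out, "lift_status"), "passed_through")
  expect_identical(out$pos, 10L)
  expect_identical(out$cigar, "4M")
})

test_that("lifted mates stay mutually consistent across a deletion", {
  idx <- del_fx()
  # pair straddling the deleted GT: R1 at source 0 (2M), R2 at source 4 (2M)
  r1 <- list(qname = "p1", flag = 99L, rname = "chr1", pos = 0L, mapq = 60L,
             cigar = "2M", rnext = "=", pnext = 4L, tlen = 6L,
             seq = "AC", qual = "II", tags = character(0))
  r2 <- list(qname = "p1", flag = 147L, rname = "chr1", pos = 4L, mapq = 60L,
             cigar = "2M", rnext = "=", pnext = 0L, tlen = -6L,
             seq = "GT", qual = "II", tags = character(0))
  o1 <- lift_record(r1, idx)
  o2 <- lift_record(r2, idx)
  expect_identical(o1$pnext, o2$pos)
  expect_identical(o2$pnext, o1$pos)
  expect_identical(o1$tlen, -o2$tlen)
  # source span 0..6 maps onto target 0..8: TLEN widens by the deletion
  expect_identical(o1$tlen, 8L)
})

test_that("rewrite_header renames and resizes @SQ and appends one @PG", {
  idx <- ins_fx()
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           "@SQ\tSN:chr1\tLN:10",
           "@SQ\tSN:chrUn\tLN:999",
           "@RG\tID:rg1\tPL:ILLUMINA\tSM:sampleA")
  out <- rewrite_header(hdr, idx, cmdline = "liftkit lift -l x.lft")
  expect_identical(out[2L], "@SQ\tSN:chr1\tLN:8")
  expect_identical(out[3L], hdr[3L])     # absent from index: untouched
  expect_identical(out[4L], hdr[4L])     # @RG byte-identical
  expect_identical(sum(startsWith(out, "@PG")), 1L)
  expect_match(out[length(out)], "CL:liftkit lift -l x.lft", fixed = TRUE)

  empty_idx <- lift_index(list())
  out2 <- rewrite_header(hdr, empty_idx, "cmd")
  expect_identical(out2[seq_along(hdr)], hdr)
})
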