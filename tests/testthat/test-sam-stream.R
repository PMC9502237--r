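make_sam <- function(fx, n = 200L, seed = 50L, read_len = 80L, ...) {
  sim <- simulate_reads(fx$source["chr1"], fx$map, n, read_len = read_len,
                        seed = seed, ...)
  sam <- tempfile(fileext = ".sam")
  write_sam(source_header(fx$index), sim$records, sam)
  list(sam = sam, sim = sim)
}

test_that("run_index writes a loadable .lft with identity behavior", {
  lens <- c(chr1 = 120L)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(data.frame(chrom = character(0), pos = integer(0),
                       ref = character(0), alt = character(0)), lens, vcf)
  lft <- withr::local_tempfile(fileext = ".lft")
  expect_message(run_index(vcf, lft), "1 contig")
  idx <- load_index(lft)
  expect_identical(lift_pos(idx, "chr1", 0:119), 0:119)
})

test_that("run_index handles multi-contig VCFs and missing lengths", {
  g <- c(gen_genome(300L, seed = 51L, name = "chrA"),
         gen_genome(200L, seed = 52L, name = "chrB"))
  v <- gen_variants(g, seed = 53L)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(v, stats::setNames(nchar(g), names(g)), vcf)
  lft <- withr::local_tempfile(fileext = ".lft")
  suppressMessages(run_index(vcf, lft))
  idx <- load_index(lft)
  expect_identical(length(idx$contigs), 2L)
  # no ##contig header and no .fai: error names both remedies
  lines <- readLines(vcf)
  vcf2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(lines[!startsWith(lines, "##contig")], vcf2)
  err <- tryCatch(run_index(vcf2, lft), error = conditionMessage)
  expect_match(err, "##contig")
  expect_match(err, "\\.fai")
})

test_that("output is byte-identical for any thread count", {
  fx <- make_fixture(54L)
  ms <- make_sam(fx, n = 3000L, feature_frac = 0.2)
  outs <- lapply(c(1L, 4L), function(t) {
    out <- tempfile(fileext = ".sam")
    run_lift(ms$sam, out, index = fx$index, threads = t, quiet = TRUE,
             cmdline = "fixed")
    readLines(out)
  })
  expect_identical(outs[[1L]], outs[[2L]])
})

test_that("streaming preserves record count and order", {
  fx <- make_fixture(55L)
  ms <- make_sam(fx, n = 500L, feature_frac = 0.3)
  out <- withr::local_tempfile(fileext = ".sam")
  s <- run_lift(ms$sam, out, index = fx$index, quiet = TRUE,
                batch_size = 64L)
  body <- sam_body(out)
  expect_identical(length(body), 500L)
  expect_identical(s$records_in, 500L)
  expect_identical(sam_field(body, 1L),
                   vapply(ms$sim$records, `[[`, "", "qname"))
  # lifted fields match the oracle truth
  expect_identical(as.integer(sam_field(body, 4L)),
                   ms$sim$truth$expected_pos_1based)
})

test_that("BAM input and output round-trip through the lifter", {
  fx <- make_fixture(56L)
  ms <- make_sam(fx, n = 150L)
  bam_in <- withr::local_tempfile(fileext = ".bam")
  Rsamtools::asBam(ms$sam, sub("\\.bam$", "", bam_in), overwrite = TRUE,
                   indexDestination = FALSE)
  bam_out <- withr::local_tempfile(fileext = ".bam")
  s <- run_lift(bam_in, bam_out, index = fx$index, quiet = TRUE)
  expect_identical(s$records_in, 150L)
  expect_identical(Rsamtools::countBam(bam_out)$records, 150L)
})

test_that("records on unknown contigs pass through with one warning", {
  fx <- make_fixture(57L)
  ms <- make_sam(fx, n = 20L)
  lines <- readLines(ms$sam)
  stray <- paste("s1", 0L, "chrUn", 11L, 60L, "4M", "*", 0L, 0L,
                 "ACGT", "IIII", sep = "\t")
  writeLines(c(lines, stray, sub("^s1", "s2", stray)), ms$sam)
  out <- withr::local_tempfile(fileext = ".sam")
  expect_warning(
    s <- run_lift(ms$sam, out, index = fx$index, quiet = TRUE),
    "chrUn")
  expect_identical(s$records_in, 22L)
  expect_identical(s$records_passed_through, 2L)
  body <- sam_body(out)
  expect_identical(length(body), 22L)
  expect_identical(sam_field(body, 3L)[21L], "chrUn")
})

test_that("a malformed body line passes through and is counted", {
  fx <- make_fixture(58L)
  ms <- make_sam(fx, n = 5L)
  writeLines(c(readLines(ms$sam), "not\ta\tsam\tline"), ms$sam)
  out <- withr::local_tempfile(fileext = ".sam")
  s <- run_lift(ms$sam, out, index = fx$index, quiet = TRUE)
  expect_identical(s$records_in, 6L)
  expect_identical(s$records_passed_through, 1L)
  expect_identical(s$warnings, 1L)
  expect_identical(sam_body(out)[6L], "not\ta\tsam\tline")
})

test_that("chain export matches the documented block grammar", {
  idx0 <- build_index(data.frame(chrom = character(0), pos = integer(0),
                                 ref = character(0), alt = character(0)),
                      contig_lengths = c(chr1 = 8L))
  f <- withr::local_tempfile(fileext = ".chain")
  export_chain(idx0, f)
  expect_identical(readLines(f),
                   c("chain 8 chr1 8 + 0 8 chr1 8 + 0 8 1", "8", ""))

  ins <- build_index(data.frame(chrom = "chr1", pos = 3L, ref = "G",
                                alt = "GAA"), contig_lengths = c(chr1 = 8L))
  export_chain(ins, f)
  expect_identical(readLines(f),
                   c("chain 10 chr1 10 + 0 10 chr1 8 + 0 8 1", "3 2 0", "5",
                     ""))

  del <- build_index(data.frame(chrom = "chr1", pos = 2L, ref = "CGT",
                                alt = "C"), contig_lengths = c(chr1 = 8L))
  export_chain(del, f)
  expect_identical(readLines(f),
                   c("chain 6 chr1 6 + 0 6 chr1 8 + 0 8 1", "2 0 2", "4", ""))
})

test_that("a brute-force chain interpreter agrees with lift_pos", {
  for (seed in c(61L, 62L, 63L)) {
    fx <- make_fixture(seed, len = 4000L)
    f <- tempfile(fileext = ".chain")
    export_chain(fx$index, f)
    lift <- chain_interpreter(f)
    sl <- source_length(fx$index, "chr1")
    expect_identical(lift("chr1", 0:(sl - 1L)),
                     lift_pos(fx$index, "chr1", 0:(sl - 1L)))
    unlink(f)
  }
})

test_that("the CLI dispatches, reports usage errors and writes outputs", {
  fx <- make_fixture(64L)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(fx$variants, fx$lens, vcf)
  lft <- withr::local_tempfile(fileext = ".lft")
  expect_identical(suppressMessages(
    liftkit_main(c("index", "-v", vcf, "-o", lft))), 0L)
  expect_true(file.exists(lft))

  ms <- make_sam(fx, n = 50L)
  out <- withr::local_tempfile(fileext = ".sam")
  chain <- withr::local_tempfile(fileext = ".chain")
  code <- suppressMessages(
    liftkit_main(c("lift", "-l", lft, "-a", ms$sam, "-o", out,
                   "-t", "2", "--chain", chain)))
  expect_identical(code, 0L)
  expect_identical(length(sam_body(out)), 50L)
  expect_true(file.exists(chain))

  expect_identical(suppressMessages(liftkit_main(c("lift", "-a", "x"))), 2L)
  expect_identical(suppressMessages(liftkit_main(c("nope"))), 2L)
  expect_identical(suppressMessages(
    liftkit_main(c("index", "-v", "/nonexistent.vcf", "-o", lft))), 1L)
})
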