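#' Build and serialize a lift index from a VCF
#'
#' Command-level wrapper: builds the per-contig coordinate maps from `vcf`
#' (contig lengths from its `##contig` headers, or from a FASTA `.fai`) and
#' writes them to `out` in `.lft` form.
#'
#' @param vcf path to the VCF describing source-vs-target differences
#'   (coordinates relative to the target reference).
#' @param out output `.lft` path.
#' @param fai optional FASTA `.fai` path supplying contig lengths.
#' @return The built [lift_index()], invisibly.
#' @export
run_index <- function(vcf, out, fai = NULL) {
  index <- build_index(vcf, fai = fai)
  save_index(index, out)
  message(sprintf("liftkit index: %d contig(s) -> %s", length(index$contigs),
                  out))
  invisible(index)
}

new_run_summary <- function() {
  structure(list(records_in = 0L, records_lifted = 0L,
                 records_passed_through = 0L, records_unmapped_by_lift = 0L,
                 warnings = 0L),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf(paste0("liftkit lift summary: %d record(s) in, %d lifted, ",
                     "%d passed through, %d unmapped by lift, %d warning(s)\n"),
              x$records_in, x$records_lifted, x$records_passed_through,
              x$records_unmapped_by_lift, x$warnings))
  invisible(x)
}

# Lift a batch of SAM body lines. Pure function of (lines, index, opts) so
# batches can be processed by any worker in any order; returns the output
# lines plus counters, reassembled by sequence number in run_lift.
lift_batch <- function(lines, index, opts) {
  n <- length(lines)
  out <- character(n)
  counts <- c(lifted = 0L, passed_through = 0L, unmapped_by_lift = 0L,
              errors = 0L)
  unknown <- character(0)
  for (i in seq_len(n)) {
    rec <- tryCatch(parse_sam_record(lines[i]), error = function(e) NULL)
    if (is.null(rec)) {
      out[i] <- lines[i]
      counts["errors"] <- counts["errors"] + 1L
      next
    }
    lifted <- tryCatch(lift_record(rec, index, opts), error = function(e) NULL)
    if (is.null(lifted)) {
      out[i] <- lines[i]
      counts["errors"] <- counts["errors"] + 1L
      next
    }
    st <- attr(lifted, "lift_status")
    counts[st] <- counts[st] + 1L
    if (st == "passed_through" && lifted$rname != "*" &&
        is.null(index$contigs[[rec$rname]]) && bitwAnd(rec$flag, 4L) == 0L) {
      unknown <- c(unknown, rec$rname)
    }
    out[i] <- format_sam_record(lifted)
  }
  list(lines = out, counts = counts, unknown = unique(unknown))
}

#' Lift a SAM/BAM alignment stream from source to target coordinates
#'
#' Streams records from `input`, rewrites the header once, lifts records in
#' fixed-size batches and writes them in input order. With `threads > 1`
#' batches are processed concurrently by forked workers, but batches are
#' reassembled by sequence number before writing, so output is
#' byte-identical for any thread count. Per-record failures never abort the
#' stream: the offending record passes through unchanged and is counted. A
#' summary is printed to standard error.
#'
#' @param input SAM path, BAM path, or `"-"` for standard input (SAM text).
#' @param output SAM path, BAM path (`.bam` suffix), or `"-"` for standard
#'   output.
#' @param index a [lift_index()], a `.lft` path, or `NULL` if `vcf` given.
#' @param vcf VCF path to build the index from when no `.lft` is supplied.
#' @param fai optional `.fai` for contig lengths when building from VCF.
#' @param threads number of worker processes (forked; 1 = serial).
#' @param batch_size records per batch.
#' @param md recompute MD/NM tags (requires `fasta`).
#' @param fasta target-reference FASTA for `md`.
#' @param clip_leading_ins convert terminal insertion runs to soft clips.
#' @param chain_out optional path: also export the index as a UCSC chain.
#' @param cmdline command-line string recorded in the appended `@PG` line.
#' @param quiet suppress the summary message.
#' @return A `run_summary` object, invisibly.
#' @export
run_lift <- function(input, output, index = NULL, vcf = NULL, fai = NULL,
                     threads = 1L, batch_size = 8192L, md = FALSE,
                     fasta = NULL, clip_leading_ins = FALSE,
                     chain_out = NULL, cmdline = "liftkit lift",
                     quiet = FALSE) {
  if (is.null(index) && is.null(vcf)) {
    stop("run_lift: supply exactly one of `index` (.lft) or `vcf`")
  }
  if (is.character(index)) index <- load_index(index)
  if (is.null(index)) index <- build_index(vcf, fai = fai)
  stopifnot(inherits(index, "lift_index"))
  if (!is.null(chain_out)) export_chain(index, chain_out)
  opts <- lift_options(recompute_tags = md,
                       clip_leading_insertions = clip_leading_ins,
                       target_fasta = fasta)
  threads <- max(1L, as.integer(threads))
  use_fork <- threads > 1L && .Platform$OS.type == "unix"

  in_path <- input
  if (!identical(input, "-") && grepl("\\.bam$", input, ignore.case = TRUE)) {
    in_path <- bam_to_sam(input)
  }
  bam_out <- !identical(output, "-") &&
    grepl("\\.bam$", output, ignore.case = TRUE)
  out_path <- if (bam_out) tempfile(fileext = ".sam") else output

  con <- if (identical(in_path, "-")) {
    file("stdin", open = "r")
  } else {
    if (!file.exists(in_path)) stop(sprintf("cannot read input: %s", in_path))
    file(in_path, open = "r")
  }
  on.exit(close(con), add = TRUE)
  out_con <- if (identical(out_path, "-")) {
    stdout()
  } else {
    oc <- file(out_path, open = "w")
    on.exit(close(oc), add = TRUE)
    oc
  }

  # header: read line by line until the first body line, which is buffered
  header <- character(0)
  pending <- character(0)
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) break
    if (startsWith(line, "@")) header <- c(header, line) else {
      pending <- line
      break
    }
  }
  writeLines(rewrite_header(header, index, cmdline), out_con)

  summary <- new_run_summary()
  warned <- character(0)
  repeat {
    lines <- c(pending, readLines(con, n = batch_size * threads -
                                    length(pending)))
    pending <- character(0)
    if (!length(lines)) break
    batches <- split(lines, (seq_along(lines) - 1L) %/% batch_size)
    results <- if (use_fork && length(batches) > 1L) {
      parallel::mclapply(batches, lift_batch, index = index, opts = opts,
                         mc.cores = threads)
    } else {
      lapply(batches, lift_batch, index = index, opts = opts)
    }
    for (res in results) {
      writeLines(res$lines, out_con)
      summary$records_in <- summary$records_in + length(res$lines)
      summary$records_lifted <- summary$records_lifted +
        res$counts[["lifted"]] + res$counts[["unmapped_by_lift"]]
      summary$records_passed_through <- summary$records_passed_through +
        res$counts[["passed_through"]] + res$counts[["errors"]]
      summary$records_unmapped_by_lift <- summary$records_unmapped_by_lift +
        res$counts[["unmapped_by_lift"]]
      summary$warnings <- summary$warnings + res$counts[["errors"]]
      new_unknown <- setdiff(res$unknown, warned)
      for (ctg in new_unknown) {
        warning(sprintf("contig not in index, records passed through: %s",
                        ctg), call. = FALSE)
        summary$warnings <- summary$warnings + 1L
      }
      warned <- c(warned, new_unknown)
    }
  }

  if (bam_out) {
    flush(out_con)
    close(out_con)
    on.exit(close(con), add = FALSE)  # out_con already closed
    sam_to_bam(out_path, output)
  }
  if (!quiet) message(format_summary(summary))
  invisible(summary)
}

format_summary <- function(x) {
  sprintf(paste0("liftkit lift summary: %d record(s) in, %d lifted, ",
                 "%d passed through, %d unmapped by lift, %d warning(s)"),
          x$records_in, x$records_lifted, x$records_passed_through,
          x$records_unmapped_by_lift, x$warnings)
}
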