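#' Parse one SAM record line
#'
#' Splits a tab-separated SAM body line into a record list. POS and PNEXT
#' are converted to 0-based coordinates here, at the I/O boundary; all
#' internal computation is 0-based, half-open.
#'
#' @param line a SAM body line (no trailing newline).
#' @return A record list with fields `qname`, `flag`, `rname`, `pos`
#'   (0-based), `mapq`, `cigar`, `rnext`, `pnext` (0-based), `tlen`, `seq`,
#'   `qual` and `tags` (character vector of raw `TAG:TYPE:VALUE` strings).
#' @export
parse_sam_record <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(f) < 11L) stop("malformed SAM record: fewer than 11 fields")
  list(
    qname = f[1L],
    flag  = as.integer(f[2L]),
    rname = f[3L],
    pos   = as.integer(f[4L]) - 1L,
    mapq  = as.integer(f[5L]),
    cigar = f[6L],
    rnext = f[7L],
    pnext = as.integer(f[8L]) - 1L,
    tlen  = as.integer(f[9L]),
    seq   = f[10L],
    qual  = f[11L],
    tags  = if (length(f) > 11L) f[12:length(f)] else character(0)
  )
}

#' Format a record list back into a SAM line
#'
#' @param record a record list as from [parse_sam_record()].
#' @return A single tab-separated SAM line.
#' @export
format_sam_record <- function(record) {
  paste(c(record$qname, record$flag, record$rname, record$pos + 1L,
          record$mapq, record$cigar, record$rnext, record$pnext + 1L,
          record$tlen, record$seq, record$qual, record$tags),
        collapse = "\t")
}

#' Write SAM text
#'
#' @param header character vector of header lines.
#' @param records list of record lists, or a character vector of
#'   pre-formatted body lines.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(header, records, path) {
  body <- if (is.character(records)) records else {
    vapply(records, format_sam_record, character(1))
  }
  writeLines(c(header, body), path)
  invisible(path)
}

# BAM <-> SAM conversion via Rsamtools. Returns the path of the converted
# file (a tempfile for BAM input).
bam_to_sam <- function(bam_path) {
  out <- tempfile(fileext = ".sam")
  Rsamtools::asSam(bam_path, sub("\\.sam$", "", out), overwrite = TRUE)
  out
}

sam_to_bam <- function(sam_path, bam_path) {
  Rsamtools::asBam(sam_path, sub("\\.bam$", "", bam_path), overwrite = TRUE,
                   indexDestination = FALSE)
  invisible(bam_path)
}
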