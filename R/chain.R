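#' Export a lift index as a UCSC chain file
#'
#' Writes one chain block per contig, direction source to target. The
#' header line is
#' `chain <score> <srcName> <srcSize> + 0 <srcSize> <tgtName> <tgtSize> + 0 <tgtSize> <id>`
#' followed by `size dt dq` alignment-data lines obtained by run-length
#' scanning the column map (`dt` = source-only bases skipped, `dq` =
#' target-only). No alignment scoring is performed; the score field is
#' emitted as the source size. Blocks are terminated by a blank line.
#'
#' @param index a [lift_index()].
#' @param path output path or text connection.
#' @return `path`, invisibly.
#' @export
export_chain <- function(index, path) {
  con <- if (inherits(path, "connection")) path else {
    f <- file(path, "w"); on.exit(close(f)); f
  }
  id <- 0L
  for (cl in index$contigs) {
    id <- id + 1L
    ssize <- src_len(cl)
    tsize <- tgt_len(cl)
    writeLines(sprintf("chain %d %s %d + 0 %d %s %d + 0 %d %d",
                       ssize, cl$name, ssize, ssize,
                       cl$tgt_name, tsize, tsize, id), con)
    # column classes: 3 = both, 1 = src-only, 2 = tgt-only
    cls <- cl$src_bv$bits + 2L * cl$tgt_bv$bits
    r <- rle(cls)
    size <- 0L; dt <- 0L; dq <- 0L; in_gap <- FALSE
    lines <- character(0)
    for (k in seq_along(r$values)) {
      v <- r$values[k]; len <- r$lengths[k]
      if (v == 3L) {
        if (in_gap) {
          lines <- c(lines, sprintf("%d %d %d", size, dt, dq))
          size <- len; dt <- 0L; dq <- 0L; in_gap <- FALSE
        } else {
          size <- size + len
        }
      } else {
        in_gap <- TRUE
        if (v == 1L) dt <- dt + len else dq <- dq + len
      }
    }
    if (in_gap) {
      lines <- c(lines, sprintf("%d %d %d", size, dt, dq), "0")
    } else {
      lines <- c(lines, sprintf("%d", size))
    }
    writeLines(c(lines, ""), con)
  }
  invisible(path)
}
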