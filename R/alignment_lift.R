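QUERY_OPS <- c(0L, 1L, 4L, 7L, 8L)  # M I S = X
REF_OPS   <- c(0L, 2L, 3L, 7L, 8L)  # M D N = X

#' Parse / format CIGAR strings
#'
#' `parse_cigar()` splits a CIGAR into parallel op-code and length vectors
#' (BAM op order `MIDNSHP=X`, codes 0-8); `format_cigar()` is its inverse.
#'
#' @param cigar a CIGAR string (not `"*"`).
#' @return For `parse_cigar()`, a list with integer vectors `ops` and
#'   `lens`; for `format_cigar()`, a CIGAR string.
#' @export
parse_cigar <- function(cigar) cpp_parse_cigar(cigar)

#' @rdname parse_cigar
#' @param ops,lens integer vectors of op codes and lengths.
#' @export
format_cigar <- function(ops, lens) cpp_format_cigar(ops, lens)

cigar_ref_span <- function(ops, lens) sum(lens[ops %in% REF_OPS])
cigar_query_len <- function(ops, lens) sum(lens[ops %in% QUERY_OPS])

#' Options controlling record lifting
#'
#' @param recompute_tags replace the MD and NM tags of lifted records with
#'   values recomputed against the target reference; requires `target_fasta`.
#' @param clip_leading_insertions convert terminal I runs produced by the
#'   coordinate conversion into soft clips (S). I-first CIGARs are legal
#'   SAM but rejected by some downstream tools.
#' @param target_fasta a reference accessor from [fasta_accessor()], or a
#'   FASTA path / named character vector accepted by it.
#' @return An object of class `lift_options`.
#' @export
lift_options <- function(recompute_tags = FALSE,
                         clip_leading_insertions = FALSE,
                         target_fasta = NULL) {
  if (recompute_tags && is.null(target_fasta)) {
    stop("recompute_tags requires target_fasta")
  }
  if (!is.null(target_fasta) && !is.function(target_fasta)) {
    target_fasta <- fasta_accessor(target_fasta)
  }
  structure(list(recompute_tags = recompute_tags,
                 clip_leading_insertions = clip_leading_insertions,
                 target_fasta = target_fasta),
            class = "lift_options")
}

# Convert terminal insertion runs (outside any existing clips) to soft
# clips, then re-merge adjacent identical ops.
clip_terminal_ins <- function(ops, lens) {
  n <- length(ops)
  i <- 1L
  while (i <= n && ops[i] %in% c(4L, 5L)) i <- i + 1L
  if (i <= n && ops[i] == 1L) ops[i] <- 4L
  j <- n
  while (j >= 1L && ops[j] %in% c(4L, 5L)) j <- j - 1L
  if (j >= 1L && ops[j] == 1L) ops[j] <- 4L
  keep <- c(TRUE, ops[-1L] != ops[-n])
  grp <- cumsum(keep)
  list(ops = ops[keep], lens = as.integer(tapply(lens, grp, sum)))
}

#' Lift an alignment's position and CIGAR to target coordinates
#'
#' Composes the read-to-source alignment described by `cigar` with the
#' source-to-target column map of one contig. Query-only ops (I/S/H/P)
#' pass through; reference-consuming ops are re-expressed column by column:
#' both-1 columns keep the op, inserted (src-only) reference bases turn
#' M/=/X into I and shrink D/N spans, and deleted (tgt-only) columns
#' between consecutive source bases inject D — widened into N when they
#' fall against a spliced (N) run. The query-consuming length is conserved
#' exactly.
#'
#' @param cl a [contig_lift()].
#' @param s_pos 0-based source alignment start.
#' @param cigar CIGAR string, or a list with `ops`/`lens` from
#'   [parse_cigar()].
#' @param clip_leading_insertions convert terminal I runs to S.
#' @return A list: `mapped` (FALSE when the alignment lies entirely inside
#'   an insertion), `t_pos` (0-based target start; for unmapped results the
#'   clamped anchor position), `ops`, `lens`, and `cigar` (the formatted
#'   target CIGAR).
#' @export
lift_cigar <- function(cl, s_pos, cigar, clip_leading_insertions = FALSE) {
  stopifnot(inherits(cl, "contig_lift"))
  pc <- if (is.character(cigar)) cpp_parse_cigar(cigar) else cigar
  s_pos <- as.integer(s_pos)
  span <- cigar_ref_span(pc$ops, pc$lens)
  sl <- src_len(cl)
  if (is.na(s_pos) || s_pos < 0L || span < 1L || s_pos + span > sl) {
    stop(sprintf(
      "lift_cigar: alignment [%d, %d) outside source contig %s of length %d",
      s_pos, s_pos + span, cl$name, sl))
  }
  res <- cpp_lift_cigar(cl$src_bv$bits, cl$tgt_bv$bits, cl$tgt_bv$rank,
                        cl$src_bv$sel, s_pos, pc$ops, pc$lens, tgt_len(cl))
  if (res$mapped && clip_leading_insertions) {
    cc <- clip_terminal_ins(res$ops, res$lens)
    res$ops <- cc$ops
    res$lens <- cc$lens
  }
  res$cigar <- cpp_format_cigar(res$ops, res$lens)
  res
}

#' Lift a single alignment record
#'
#' Translates one SAM record (as parsed by [parse_sam_record()], 0-based
#' `pos`/`pnext`) from source to target coordinates. Mapped records get
#' RNAME/POS/CIGAR from the column map; MAPQ, FLAG, QNAME, SEQ and QUAL are
#' untouched. Mate fields are lifted statelessly through the index (the
#' `"="` convention is preserved), and TLEN is recomputed from the lifted
#' template ends when both mates are mapped to the same contig. An
#' alignment falling entirely inside an insertion has no target interval:
#' it is returned with FLAG 0x4 set, CIGAR `"*"`, and POS at the lifted
#' anchor for sort stability. Records whose contig is not in the index, and
#' unmapped input records, pass through untouched apart from contig
#' renaming.
#'
#' @param record a record list from [parse_sam_record()].
#' @param index a [lift_index()].
#' @param opts a [lift_options()].
#' @return The lifted record, with attribute `"lift_status"` one of
#'   `"lifted"`, `"passed_through"`, `"unmapped_by_lift"`.
#' @export
lift_record <- function(record, index, opts = lift_options()) {
  nm <- index$name_map
  rename <- function(x) {
    if (!is.null(x) && x %in% names(nm)) nm[[x]] else x
  }
  finish <- function(rec, status) {
    attr(rec, "lift_status") <- status
    rec
  }

  unmapped_in <- bitwAnd(record$flag, 4L) != 0L ||
    record$rname == "*" || record$cigar == "*"
  if (unmapped_in) {
    record$rname <- rename(record$rname)
    if (record$rnext != "=" && record$rnext != "*") {
      record$rnext <- rename(record$rnext)
    }
    return(finish(record, "passed_through"))
  }
  cl <- index$contigs[[record$rname]]
  if (is.null(cl)) {
    return(finish(record, "passed_through"))
  }

  res <- lift_cigar(cl, record$pos, record$cigar,
                    clip_leading_insertions = opts$clip_leading_insertions)

  # mate fields (stateless: lifted through the index, not by mate pairing)
  mate_src <- if (record$rnext == "=") record$rname else record$rnext
  mcl <- if (mate_src == "*") NULL else index$contigs[[mate_src]]
  mate_lifted <- FALSE
  if (!is.null(mcl) && record$pnext >= 0L && record$pnext < src_len(mcl)) {
    record$pnext <- lift_pos(index, mate_src, record$pnext)
    mate_lifted <- TRUE
  }
  if (record$rnext != "=" && record$rnext != "*") {
    record$rnext <- rename(record$rnext)
  }

  old_pos <- record$pos
  old_tlen <- record$tlen
  record$rname <- cl$tgt_name
  record$pos <- res$t_pos

  if (!res$mapped) {
    record$flag <- bitwOr(record$flag, 4L)
    record$cigar <- "*"
    return(finish(record, "unmapped_by_lift"))
  }
  record$cigar <- res$cigar

  same_ctg <- mate_src == cl$name
  if (old_tlen != 0L && mate_lifted && same_ctg) {
    if (old_tlen > 0L) {
      e_old <- old_pos + old_tlen   # exclusive end of the rightmost mate
      if (e_old >= 1L && e_old <= src_len(cl)) {
        record$tlen <- lift_end(cl, e_old) - res$t_pos
      }
    } else {
      end_new <- res$t_pos + cigar_ref_span(res$ops, res$lens)
      record$tlen <- -(end_new - record$pnext)
    }
  }

  if (opts$recompute_tags && record$seq != "*") {
    record <- recompute_tags(record, opts$target_fasta)
  }
  finish(record, "lifted")
}

#' Rewrite a SAM header for target coordinates
#'
#' Renames `@SQ` SN fields through the index name map and replaces LN with
#' the target contig length; `@SQ` lines for contigs absent from the index
#' are kept as-is, as are all other lines (in order). One `@PG` line is
#' appended recording the tool and command line.
#'
#' @param header character vector of header lines (each starting with `@`).
#' @param index a [lift_index()].
#' @param cmdline command-line string recorded in the `@PG` line.
#' @return Character vector of rewritten header lines.
#' @export
rewrite_header <- function(header, index, cmdline = "") {
  out <- vapply(header, function(line) {
    if (!startsWith(line, "@SQ")) return(line)
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    sn_i <- grep("^SN:", fields)
    if (!length(sn_i)) return(line)
    sn <- sub("^SN:", "", fields[sn_i[1L]])
    cl <- index$contigs[[sn]]
    if (is.null(cl)) return(line)
    fields[sn_i[1L]] <- paste0("SN:", cl$tgt_name)
    ln_i <- grep("^LN:", fields)
    if (length(ln_i)) fields[ln_i[1L]] <- paste0("LN:", tgt_len(cl))
    paste(fields, collapse = "\t")
  }, character(1), USE.NAMES = FALSE)
  ver <- as.character(utils::packageVersion("liftkit"))
  pg <- sprintf("@PG\tID:liftkit\tPN:liftkit\tVN:%s\tCL:%s", ver, cmdline)
  c(out, pg)
}
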