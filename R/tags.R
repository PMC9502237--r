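#' Random-access accessor for a reference FASTA
#'
#' Loads a FASTA into memory (contigs at the scale this tool targets are
#' read once and sliced many times) and returns a closure
#' `function(contig, start0, len)` yielding the uppercase reference slice
#' at 0-based `start0`. Names are truncated at the first whitespace, as in
#' SAM headers.
#'
#' @param x FASTA file path, a `Biostrings::DNAStringSet`, or a named
#'   character vector of sequences.
#' @return A function `(contig, start0, len) -> character`.
#' @export
fasta_accessor <- function(x) {
  seqs <- if (is.character(x) && length(x) == 1L && file.exists(x)) {
    Biostrings::readDNAStringSet(x)
  } else if (methods::is(x, "DNAStringSet")) {
    x
  } else if (is.character(x) && !is.null(names(x))) {
    Biostrings::DNAStringSet(x)
  } else {
    stop("fasta_accessor: need a FASTA path, DNAStringSet or named character vector")
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  function(contig, start0, len) {
    i <- match(contig, names(seqs))
    if (is.na(i)) {
      stop(sprintf("reference contig not found: %s", contig))
    }
    if (start0 < 0L || start0 + len > length(seqs[[i]])) {
      stop(sprintf("reference %s too short: need [%d, %d), have %d bp",
                   contig, start0, start0 + len, length(seqs[[i]])))
    }
    toupper(as.character(Biostrings::subseq(seqs[[i]], start0 + 1L,
                                            start0 + len)))
  }
}

#' Compute MD and NM for an alignment in target coordinates
#'
#' Walks the CIGAR against the target reference. NM is the edit distance:
#' mismatched M/=/X positions plus all inserted (I) and deleted (D) bases.
#' MD alternates match-run counts, mismatched reference bases and
#' `^`-prefixed deleted reference runs, always beginning and ending with a
#' (possibly zero) count. N (splice) ops contribute to neither tag.
#'
#' @param seq read bases (SEQ field, not `"*"`).
#' @param ops,lens parsed CIGAR in target coordinates.
#' @param t_pos 0-based target alignment start.
#' @param rname target contig name.
#' @param ref_get accessor from [fasta_accessor()].
#' @return A list with integer `nm` and character `md`.
#' @export
calc_md_nm <- function(seq, ops, lens, t_pos, rname, ref_get) {
  qbases <- strsplit(toupper(seq), "")[[1L]]
  qi <- 0L
  ri <- t_pos
  nm <- 0L
  run <- 0L
  md <- character(0)
  for (k in seq_along(ops)) {
    op <- ops[k]
    len <- lens[k]
    if (op %in% c(0L, 7L, 8L)) {          # M / = / X
      refs <- strsplit(ref_get(rname, ri, len), "")[[1L]]
      reads <- qbases[(qi + 1L):(qi + len)]
      mism <- which(reads != refs)
      prev <- 0L
      for (m in mism) {
        run <- run + (m - 1L - prev)
        md <- c(md, as.character(run), refs[m])
        run <- 0L
        prev <- m
      }
      run <- run + (len - prev)
      nm <- nm + length(mism)
      qi <- qi + len
      ri <- ri + len
    } else if (op == 1L) {                # I
      nm <- nm + len
      qi <- qi + len
    } else if (op == 4L) {                # S
      qi <- qi + len
    } else if (op == 2L) {                # D
      md <- c(md, as.character(run),
              paste0("^", ref_get(rname, ri, len)))
      run <- 0L
      nm <- nm + len
      ri <- ri + len
    } else if (op == 3L) {                # N: silent in both tags
      ri <- ri + len
    }                                     # H, P: nothing
  }
  md <- c(md, as.character(run))
  list(nm = nm, md = paste(md, collapse = ""))
}

#' Replace the MD/NM tags of a target-coordinate record
#'
#' Existing MD and NM tags are dropped and recomputed values appended; all
#' other optional fields are preserved verbatim.
#'
#' @param record a mapped record (target coordinates, `seq != "*"`).
#' @param ref_get accessor from [fasta_accessor()].
#' @return The record with updated tags.
#' @export
recompute_tags <- function(record, ref_get) {
  pc <- cpp_parse_cigar(record$cigar)
  r <- calc_md_nm(record$seq, pc$ops, pc$lens, record$pos, record$rname,
                  ref_get)
  tags <- record$tags[!grepl("^(MD|NM):", record$tags)]
  record$tags <- c(tags, sprintf("NM:i:%d", r$nm), sprintf("MD:Z:%s", r$md))
  record
}
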