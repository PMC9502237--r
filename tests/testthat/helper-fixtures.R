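# Shared fixture builders: everything is generated in code at test time.

# One random (genome, call set) fixture with both construction paths:
# the explicit column map from apply_variants and the bitvector index
# from build_index.
make_fixture <- function(seed, len = 6000L, snv_rate = 0.01,
                         ins_rate = 0.002, del_rate = 0.002,
                         max_indel = 10L, via_file = FALSE) {
  g <- gen_genome(len, seed = seed)
  v <- gen_variants(g, snv_rate = snv_rate, ins_rate = ins_rate,
                    del_rate = del_rate, max_indel = max_indel,
                    seed = seed + 10000L)
  av <- apply_variants(g, v)
  lens <- stats::setNames(nchar(g), names(g))
  idx <- if (via_file) {
    vcf <- tempfile(fileext = ".vcf")
    on.exit(unlink(vcf))
    write_vcf(v, lens, vcf)
    build_index(vcf)
  } else {
    build_index(v, contig_lengths = lens)
  }
  list(genome = g, variants = v, source = av$source, map = av$maps[[1L]],
       index = idx, lens = lens)
}

# SAM header in source coordinates for a fixture index
source_header <- function(idx) {
  c("@HD\tVN:1.6\tSO:unsorted",
    vapply(names(idx$contigs), function(nm) {
      sprintf("@SQ\tSN:%s\tLN:%d", nm, source_length(idx, nm))
    }, character(1), USE.NAMES = FALSE))
}

sam_body <- function(path) {
  lines <- readLines(path)
  lines[!startsWith(lines, "@")]
}

sam_header <- function(path) {
  lines <- readLines(path)
  lines[startsWith(lines, "@")]
}

sam_field <- function(body, k) {
  vapply(strsplit(body, "\t", fixed = TRUE), `[[`, character(1), k)
}

# Rebuild, from SEQ + target CIGAR + MD, the reference bases consumed by
# M and D ops — an independent check that MD round-trips to the actual
# target slice.
md_reconstruct <- function(seq, cigar, md) {
  pc <- parse_cigar(cigar)
  qb <- strsplit(seq, "")[[1L]]
  # aligned (M) read bases in order
  mb <- character(0)
  qi <- 0L
  for (k in seq_along(pc$ops)) {
    op <- pc$ops[k]; len <- pc$lens[k]
    if (op %in% c(0L, 7L, 8L)) mb <- c(mb, qb[(qi + 1L):(qi + len)])
    if (op %in% c(0L, 1L, 4L, 7L, 8L)) qi <- qi + len
  }
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Z]+|[A-Z]", md))[[1L]]
  out <- character(0)
  mi <- 0L
  for (tok in toks) {
    if (grepl("^[0-9]+$", tok)) {
      n <- as.integer(tok)
      if (n > 0L) {
        out <- c(out, mb[(mi + 1L):(mi + n)])
        mi <- mi + n
      }
    } else if (startsWith(tok, "^")) {
      out <- c(out, strsplit(sub("^\\^", "", tok), "")[[1L]])
    } else {
      out <- c(out, tok)   # mismatched reference base
      mi <- mi + 1L
    }
  }
  paste(out, collapse = "")
}

# reference bases actually consumed by M and D ops of a target alignment
ref_md_bases <- function(ref_get, rname, pos0, cigar) {
  pc <- parse_cigar(cigar)
  out <- character(0)
  ri <- pos0
  for (k in seq_along(pc$ops)) {
    op <- pc$ops[k]; len <- pc$lens[k]
    if (op %in% c(0L, 2L, 7L, 8L)) out <- c(out, ref_get(rname, ri, len))
    if (op %in% c(0L, 2L, 3L, 7L, 8L)) ri <- ri + len
  }
  paste(out, collapse = "")
}
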