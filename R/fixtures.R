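# Column tags of the explicit alignment-column map (the brute-force oracle
# the succinct index must agree with).
COL_BOTH <- 1L
COL_SRC_ONLY <- 2L
COL_TGT_ONLY <- 3L

#' Generate a random genome contig
#'
#' Uniform ACGT sequence, reproducible by seed. The RNG state of the caller
#' is left untouched.
#'
#' @param length contig length in bp (>= 1).
#' @param seed integer seed.
#' @param name contig name.
#' @return Named character vector of length 1 (name = contig name).
#' @export
gen_genome <- function(length, seed, name = "chr1") {
  if (length < 1L) stop("gen_genome: length must be >= 1")
  withr::with_seed(seed, {
    stats::setNames(paste(sample(c("A", "C", "G", "T"), length,
                                 replace = TRUE), collapse = ""), name)
  })
}

#' Generate a random non-overlapping SNV/indel call set
#'
#' Draws per-base variant events against the target genome: SNVs at
#' `snv_rate`, anchored insertions at `ins_rate`, anchored deletions at
#' `del_rate`, indel lengths uniform in `[1, max_indel]`. Events that would
#' collide with (or sit directly adjacent to) the span of an earlier
#' variant are skipped, guaranteeing a sorted, non-overlapping, bi-allelic
#' call set with at least one untouched base between consecutive variants.
#'
#' @param genome named character vector of contig sequences (the target).
#' @param snv_rate,ins_rate,del_rate per-bp event probabilities in `[0, 1]`.
#' @param max_indel maximum inserted/deleted length in bp.
#' @param seed integer seed.
#' @return data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`.
#' @export
gen_variants <- function(genome, snv_rate = 0.01, ins_rate = 0.002,
                         del_rate = 0.002, max_indel = 10L, seed = 1L) {
  stopifnot(all(c(snv_rate, ins_rate, del_rate) >= 0),
            snv_rate + ins_rate + del_rate <= 1)
  withr::with_seed(seed, {
    rows <- list()
    for (ctg in names(genome)) {
      bases <- strsplit(genome[[ctg]], "")[[1L]]
      n <- length(bases)
      u <- stats::runif(n)
      ev <- ifelse(u < snv_rate, 1L,
                   ifelse(u < snv_rate + ins_rate, 2L,
                          ifelse(u < snv_rate + ins_rate + del_rate, 3L, 0L)))
      lens <- sample.int(max_indel, n, replace = TRUE)
      next_free <- 1L  # first position not blocked by an earlier variant
      for (p in which(ev > 0L)) {
        if (p < next_free) next
        if (ev[p] == 1L) {
          alt <- sample(setdiff(c("A", "C", "G", "T"), bases[p]), 1L)
          rows[[length(rows) + 1L]] <-
            list(chrom = ctg, pos = p, ref = bases[p], alt = alt)
          ref_end <- p
        } else if (ev[p] == 2L) {
          ins <- paste(sample(c("A", "C", "G", "T"), lens[p],
                              replace = TRUE), collapse = "")
          rows[[length(rows) + 1L]] <-
            list(chrom = ctg, pos = p, ref = bases[p],
                 alt = paste0(bases[p], ins))
          ref_end <- p
        } else {
          if (p + lens[p] > n) next
          rows[[length(rows) + 1L]] <-
            list(chrom = ctg, pos = p,
                 ref = paste(bases[p:(p + lens[p])], collapse = ""),
                 alt = bases[p])
          ref_end <- p + lens[p]
        }
        next_free <- ref_end + 2L  # keep one untouched base in between
      }
    }
    if (!length(rows)) {
      return(data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        stringsAsFactors = FALSE))
    }
    data.frame(chrom = vapply(rows, `[[`, "", "chrom"),
               pos = vapply(rows, `[[`, 0L, "pos"),
               ref = vapply(rows, `[[`, "", "ref"),
               alt = vapply(rows, `[[`, "", "alt"),
               stringsAsFactors = FALSE)
  })
}

#' Apply variants to a genome, recording every alignment column
#'
#' Splices the ALT alleles into the target genome left-to-right, producing
#' the source (variant-aware) sequence together with an explicit
#' [column_map]: one entry per alignment column tagged BOTH, SRC_ONLY or
#' TGT_ONLY with the contributed base(s). This is the brute-force
#' construction path against which [build_index()] is verified.
#'
#' @param genome named character vector of target contig sequences.
#' @param variants data.frame with `chrom`, `pos` (1-based), `ref`, `alt`;
#'   REF must match the genome (checked).
#' @return A list with `source` (named character vector) and `maps` (named
#'   list of `column_map` objects).
#' @export
apply_variants <- function(genome, variants) {
  source_seqs <- character(0)
  maps <- list()
  for (ctg in names(genome)) {
    bases <- strsplit(genome[[ctg]], "")[[1L]]
    n <- length(bases)
    rows <- which(variants$chrom == ctg)
    tags <- integer(0)
    src_b <- character(0)
    tgt_b <- character(0)
    emit <- function(tag, s, t) {
      k <- max(length(s), length(t))
      tags <<- c(tags, rep(tag, k))
      src_b <<- c(src_b, if (tag == COL_TGT_ONLY) rep(NA_character_, k) else s)
      tgt_b <<- c(tgt_b, if (tag == COL_SRC_ONLY) rep(NA_character_, k) else t)
    }
    cursor <- 1L
    for (i in rows) {
      pos <- variants$pos[i]
      ref <- variants$ref[i]
      alt <- variants$alt[i]
      nr <- nchar(ref)
      have <- paste(bases[pos:(pos + nr - 1L)], collapse = "")
      if (pos + nr - 1L > n || have != ref) {
        stop(sprintf("apply_variants: REF mismatch at %s:%d (VCF %s, genome %s)",
                     ctg, pos, ref, have))
      }
      if (pos > cursor) {
        emit(COL_BOTH, bases[cursor:(pos - 1L)], bases[cursor:(pos - 1L)])
      }
      rs <- strsplit(ref, "")[[1L]]
      as <- strsplit(alt, "")[[1L]]
      na <- length(as)
      ts <- 0L
      while (nr - ts > 1L && na - ts > 1L && rs[nr - ts] == as[na - ts]) {
        ts <- ts + 1L
      }
      nr2 <- nr - ts; na2 <- na - ts
      sh <- min(nr2, na2)
      emit(COL_BOTH, as[1:sh], rs[1:sh])
      if (na2 > nr2) emit(COL_SRC_ONLY, as[(sh + 1L):na2], character(0))
      if (nr2 > na2) emit(COL_TGT_ONLY, character(0), rs[(sh + 1L):nr2])
      cursor <- pos + nr - ts  # trailing shared suffix rejoins the gap
    }
    if (cursor <= n) emit(COL_BOTH, bases[cursor:n], bases[cursor:n])
    map <- structure(list(tags = tags, src_base = src_b, tgt_base = tgt_b,
                          cache = new.env(parent = emptyenv())),
                     class = "column_map")
    maps[[ctg]] <- map
    source_seqs[[ctg]] <- paste(src_b[!is.na(src_b)], collapse = "")
  }
  list(source = source_seqs, maps = maps)
}

#' @export
print.column_map <- function(x, ...) {
  cat(sprintf("<column_map> %d columns: %d both, %d src-only, %d tgt-only\n",
              length(x$tags), sum(x$tags == COL_BOTH),
              sum(x$tags == COL_SRC_ONLY), sum(x$tags == COL_TGT_ONLY)))
  invisible(x)
}

#' Convert a column map to a contig_lift
#'
#' The lossless translation from the explicit oracle representation to the
#' bitvector pair used by the index.
#'
#' @param map a `column_map`.
#' @param name contig name.
#' @return A [contig_lift()].
#' @export
map_to_contig_lift <- function(map, name = "chr1") {
  contig_lift(name,
              bitvec(as.integer(map$tags != COL_TGT_ONLY)),
              bitvec(as.integer(map$tags != COL_SRC_ONLY)))
}

#' Brute-force position lift through a column map
#'
#' Walks the columns one by one, counting source and target bases — no
#' rank/select involved. Implements the same conventions as [lift_pos()]
#' (an inserted base maps to the next target base, clamped at the contig
#' end) so any disagreement exposes a bug, not convention drift.
#'
#' @param map a `column_map`.
#' @param s 0-based source position(s); vectorized.
#' @return 0-based target position(s).
#' @export
oracle_lift <- function(map, s) {
  lut <- oracle_lift_table(map)
  if (any(s < 0L | s >= length(lut))) stop("oracle_lift: position out of range")
  lut[s + 1L]
}

# one pass over the columns: target position for every source base.
# The table is cached on the map (reference-semantics environment) so
# repeated oracle queries pay the linear scan once.
oracle_lift_table <- function(map) {
  if (!is.null(map$cache) && !is.null(map$cache$lut)) return(map$cache$lut)
  tags <- map$tags
  n_src <- sum(tags != COL_TGT_ONLY)
  n_tgt <- sum(tags != COL_SRC_ONLY)
  out <- integer(n_src)
  tcount <- 0L
  si <- 0L
  for (c in seq_along(tags)) {
    tag <- tags[c]
    if (tag != COL_TGT_ONLY) {          # a source base lives here
      si <- si + 1L
      out[si] <- tcount                 # both: own position; src-only: next
    }
    if (tag != COL_SRC_ONLY) tcount <- tcount + 1L
  }
  lut <- pmin(out, n_tgt - 1L)
  if (!is.null(map$cache)) map$cache$lut <- lut
  lut
}

# columns holding source bases, cached like the lift table
map_src_cols <- function(map) {
  if (!is.null(map$cache) && !is.null(map$cache$src_cols)) {
    return(map$cache$src_cols)
  }
  src_cols <- which(map$tags != COL_TGT_ONLY)
  if (!is.null(map$cache)) map$cache$src_cols <- src_cols
  src_cols
}

#' Brute-force CIGAR lift through a column map
#'
#' Linear-scan re-implementation of the alignment composition, kept
#' independent of the bitvector machinery: used as the oracle for
#' [lift_cigar()]. Follows the same conventions (M/=/X over inserted bases
#' become I; D/N shrink over inserted bases; deleted columns between
#' consumed source bases inject D, widened to N against a spliced run;
#' leading gap columns before the first both column are dropped).
#'
#' @param map a `column_map`.
#' @param s_pos 0-based source alignment start.
#' @param cigar CIGAR string.
#' @return A list with `mapped`, `t_pos` (0-based) and `cigar`.
#' @export
oracle_lift_cigar <- function(map, s_pos, cigar) {
  tags <- map$tags
  # parse the CIGAR with plain regmatches, independent of the C++ parser
  m <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  if (!length(m) || nchar(paste(m, collapse = "")) != nchar(cigar)) {
    stop(sprintf("oracle_lift_cigar: malformed CIGAR %s", cigar))
  }
  lens <- as.integer(sub("[MIDNSHP=X]$", "", m))
  opch <- sub("^[0-9]+", "", m)

  src_cols <- map_src_cols(map)
  lut <- oracle_lift_table(map)
  out_op <- character(0)
  out_len <- integer(0)
  emit <- function(op, len) {
    if (len <= 0L) return()
    k <- length(out_op)
    if (k && out_op[k] == op) {
      out_len[k] <<- out_len[k] + len
    } else {
      out_op <<- c(out_op, op)
      out_len[k + 1L] <<- len
    }
  }
  cur <- s_pos + 1L          # 1-based index of next source base to consume
  first_both_tpos <- NA_integer_
  prev_op <- ""
  first <- TRUE
  cur_col <- src_cols[cur]
  for (k in seq_along(opch)) {
    op <- opch[k]
    len <- lens[k]
    if (op %in% c("I", "S", "H", "P")) {
      emit(op, len)
      next
    }
    for (j in seq_len(len)) {
      if (!first) {
        nxt <- src_cols[cur]
        gap <- sum(tags[(cur_col + 1L):nxt] == COL_TGT_ONLY)
        if (gap > 0L && !is.na(first_both_tpos)) {
          emit(if (prev_op == "N" || op == "N") "N" else "D", gap)
        }
        cur_col <- nxt
      }
      first <- FALSE
      if (tags[cur_col] == COL_BOTH) {
        emit(op, 1L)
        if (is.na(first_both_tpos)) first_both_tpos <- lut[cur]
      } else if (op %in% c("M", "=", "X")) {
        emit("I", 1L)
      }
      prev_op <- op
      cur <- cur + 1L
    }
  }
  mapped <- !is.na(first_both_tpos)
  t_pos <- if (mapped) first_both_tpos else lut[s_pos + 1L]
  list(mapped = mapped, t_pos = t_pos,
       cigar = paste0(out_len, out_op, collapse = ""))
}

#' Simulate reads from the source genome with known lifted truth
#'
#' Samples error-free reads at uniform positions on the source (variant
#' aware) contig. By default reads are all-M; a fraction carry injected
#' I/D/N/S CIGAR features exercising the composition logic, and an optional
#' substitution rate plants mismatches (counted per read in the truth
#' table). Paired mode emits proper FR pairs (all-M) with consistent
#' FLAG/PNEXT/TLEN. The truth table holds the expected target-coordinate
#' alignment from [oracle_lift_cigar()].
#'
#' @param source named character vector with one source contig.
#' @param map the `column_map` for that contig.
#' @param n number of reads (or read pairs).
#' @param read_len read length in bp.
#' @param paired emit FR pairs instead of single-end reads.
#' @param seed integer seed.
#' @param feature_frac fraction of single-end reads given injected
#'   I/D/N/S CIGAR features.
#' @param sub_rate per-base substitution probability in M segments.
#'   Substitutions are planted only on bases aligned to shared (both-1)
#'   columns, so the truth column `n_subs` counts mismatches relative to
#'   the target reference; read bases over inserted reference bases are
#'   left alone (they have no target counterpart).
#' @param with_truth compute the oracle truth table; disable for large
#'   throughput fixtures where only the records are needed.
#' @return A list with `records` (list of record lists, source coordinates)
#'   and `truth` (data.frame: `qname`, `expected_rname`,
#'   `expected_pos_1based`, `expected_cigar`, `expected_mapped`, `n_subs`).
#' @export
simulate_reads <- function(source, map, n, read_len = 100L, paired = FALSE,
                           seed = 1L, feature_frac = 0.1, sub_rate = 0,
                           with_truth = TRUE) {
  ctg <- names(source)[1L]
  slen <- nchar(source[[1L]])
  if (read_len > slen) stop("simulate_reads: read_len exceeds source length")
  sbases <- strsplit(source[[1L]], "")[[1L]]
  alpha <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    records <- list()
    truth <- list()
    add <- function(rec, n_subs) {
      records[[length(records) + 1L]] <<- rec
      if (!with_truth) return(invisible())
      exp <- oracle_lift_cigar(map, rec$pos, rec$cigar)
      truth[[length(truth) + 1L]] <<- list(
        qname = rec$qname, expected_rname = ctg,
        expected_pos_1based = exp$t_pos + 1L,
        expected_cigar = if (exp$mapped) exp$cigar else "*",
        expected_mapped = exp$mapped, n_subs = n_subs)
    }
    if (n == 0L) {
      return(list(records = list(),
                  truth = data.frame(qname = character(0),
                                     expected_rname = character(0),
                                     expected_pos_1based = integer(0),
                                     expected_cigar = character(0),
                                     expected_mapped = logical(0),
                                     n_subs = integer(0))))
    }
    if (paired) {
      frag_max <- min(slen, 2L * read_len + 200L)
      frag_min <- 2L * read_len
      for (i in seq_len(n)) {
        frag <- frag_min + sample.int(frag_max - frag_min + 1L, 1L) - 1L
        p1 <- sample.int(slen - frag + 1L, 1L) - 1L
        p2 <- p1 + frag - read_len
        qn <- sprintf("pair%06d", i)
        seq1 <- paste(sbases[(p1 + 1L):(p1 + read_len)], collapse = "")
        seq2 <- paste(sbases[(p2 + 1L):(p2 + read_len)], collapse = "")
        q <- strrep("I", read_len)
        cg <- sprintf("%dM", read_len)
        r1 <- list(qname = qn, flag = 99L, rname = ctg, pos = p1, mapq = 60L,
                   cigar = cg, rnext = "=", pnext = p2, tlen = frag,
                   seq = seq1, qual = q, tags = character(0))
        r2 <- list(qname = qn, flag = 147L, rname = ctg, pos = p2, mapq = 60L,
                   cigar = cg, rnext = "=", pnext = p1, tlen = -frag,
                   seq = seq2, qual = q, tags = character(0))
        add(r1, 0L)
        add(r2, 0L)
      }
    } else {
      for (i in seq_len(n)) {
        qn <- sprintf("read%06d", i)
        featured <- stats::runif(1) < feature_frac
        if (!featured) {
          p <- sample.int(slen - read_len + 1L, 1L) - 1L
          cg <- sprintf("%dM", read_len)
          qseq <- sbases[(p + 1L):(p + read_len)]
        } else {
          shape <- sample(c("ins", "del", "splice", "clip", "hard"), 1L)
          a <- max(1L, read_len %/% 3L)
          b <- sample.int(10L, 1L)
          if (shape == "splice") b <- sample(5:50, 1L)
          c_ <- read_len - a - if (shape == "ins") b else 0L
          if (c_ < 1L) c_ <- 1L
          span <- a + c_ + if (shape %in% c("del", "splice")) b else 0L
          if (span >= slen) {  # degenerate on tiny contigs: plain read
            p <- sample.int(slen - read_len + 1L, 1L) - 1L
            cg <- sprintf("%dM", read_len)
            qseq <- sbases[(p + 1L):(p + read_len)]
          } else {
            p <- sample.int(slen - span + 1L, 1L) - 1L
            if (shape == "ins") {
              cg <- sprintf("%dM%dI%dM", a, b, c_)
              qseq <- c(sbases[(p + 1L):(p + a)],
                        sample(alpha, b, replace = TRUE),
                        sbases[(p + a + 1L):(p + a + c_)])
            } else if (shape %in% c("del", "splice")) {
              cg <- sprintf("%dM%d%s%dM", a, b,
                            if (shape == "del") "D" else "N", c_)
              qseq <- c(sbases[(p + 1L):(p + a)],
                        sbases[(p + a + b + 1L):(p + a + b + c_)])
            } else if (shape == "clip") {
              cg <- sprintf("%dS%dM", b, a + c_)
              qseq <- c(sample(alpha, b, replace = TRUE),
                        sbases[(p + 1L):(p + a + c_)])
            } else {  # hard clip: consumes nothing
              cg <- sprintf("%dH%dM", b, a + c_)
              qseq <- sbases[(p + 1L):(p + a + c_)]
            }
          }
        }
        n_subs <- 0L
        if (sub_rate > 0) {
          pc <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1L]]
          # Substitute only within M stretches (CIGAR stays valid) and only
          # on bases aligned to shared columns: a read base over an
          # inserted reference base has no target counterpart, so changing
          # it would not be a substitution relative to the target. n_subs
          # therefore counts planted target-coordinate mismatches.
          src_cols <- map_src_cols(map)
          qoff <- 0L
          rpos <- p
          for (tok in pc) {
            op <- sub("^[0-9]+", "", tok)
            ln <- as.integer(sub("[A-Z=]$", "", tok))
            if (op %in% c("M", "=", "X")) {
              hit <- which(stats::runif(ln) < sub_rate)
              for (h in hit) {
                if (map$tags[src_cols[rpos + h]] != COL_BOTH) next
                old <- qseq[qoff + h]
                qseq[qoff + h] <- sample(setdiff(alpha, old), 1L)
                n_subs <- n_subs + 1L
              }
              rpos <- rpos + ln
            } else if (op %in% c("D", "N")) {
              rpos <- rpos + ln
            }
            if (op %in% c("M", "I", "S", "=", "X")) qoff <- qoff + ln
          }
        }
        rec <- list(qname = qn, flag = 0L, rname = ctg, pos = p, mapq = 60L,
                    cigar = cg, rnext = "*", pnext = -1L, tlen = 0L,
                    seq = paste(qseq, collapse = ""),
                    qual = strrep("I", length(qseq)), tags = character(0))
        add(rec, n_subs)
      }
    }
    list(records = records,
         truth = data.frame(
           qname = vapply(truth, `[[`, "", "qname"),
           expected_rname = vapply(truth, `[[`, "", "expected_rname"),
           expected_pos_1based = vapply(truth, `[[`, 0L,
                                        "expected_pos_1based"),
           expected_cigar = vapply(truth, `[[`, "", "expected_cigar"),
           expected_mapped = vapply(truth, `[[`, TRUE, "expected_mapped"),
           n_subs = vapply(truth, `[[`, 0L, "n_subs"),
           stringsAsFactors = FALSE))
  })
}

#' Brute-force lift through a UCSC chain file
#'
#' Independent interpreter for chain files written by [export_chain()]:
#' parses the block grammar and lifts a source position by scanning the
#' `size dt dq` runs. Positions inside a source gap map to the target start
#' of the next block (the next target base), clamped to the contig end —
#' the same convention as [lift_pos()].
#'
#' @param chain_path path to a chain file.
#' @return A function `(contig, s) -> t` lifting 0-based positions
#'   (vectorized over `s`).
#' @export
chain_interpreter <- function(chain_path) {
  lines <- readLines(chain_path)
  tables <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(lines[i])) {
      i <- i + 1L
      next
    }
    h <- strsplit(lines[i], " ", fixed = TRUE)[[1L]]
    if (h[1L] != "chain") stop("chain_interpreter: expected chain header")
    src_name <- h[3L]
    src_size <- as.integer(h[4L])
    tgt_size <- as.integer(h[9L])
    i <- i + 1L
    s <- 0L; t <- 0L
    lut <- integer(src_size)
    while (i <= length(lines) && nzchar(lines[i])) {
      d <- as.integer(strsplit(lines[i], "[ \t]+")[[1L]])
      size <- d[1L]
      dt <- if (length(d) >= 2L) d[2L] else 0L
      dq <- if (length(d) >= 3L) d[3L] else 0L
      if (size > 0L) lut[(s + 1L):(s + size)] <- t + 0:(size - 1L)
      # source bases inside the gap: next target base after the gap
      if (dt > 0L) lut[(s + size + 1L):(s + size + dt)] <- t + size + dq
      s <- s + size + dt
      t <- t + size + dq
      i <- i + 1L
    }
    tables[[src_name]] <- list(lut = pmin(lut, tgt_size - 1L),
                               src_size = src_size)
    i <- i + 1L
  }
  function(contig, s) {
    tab <- tables[[contig]]
    if (is.null(tab)) stop(sprintf("chain_interpreter: no chain for %s",
                                   contig))
    if (any(s < 0L | s >= tab$src_size)) {
      stop("chain_interpreter: position out of range")
    }
    tab$lut[s + 1L]
  }
}

#' Write contigs as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
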