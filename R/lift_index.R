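#' Per-contig coordinate map
#'
#' A pair of equal-length bit vectors over the columns of the implied
#' pairwise alignment between the source (variant-aware) and target
#' (standard) version of one contig. Column `c` contributes a source base
#' iff `src_bv[c] = 1` and a target base iff `tgt_bv[c] = 1`; a column with
#' `src = 1, tgt = 0` is an inserted base (ALT longer than REF), `src = 0,
#' tgt = 1` a deleted base. SNVs leave coordinates untouched and occupy
#' ordinary both-1 columns.
#'
#' @param name source contig name.
#' @param src_bv,tgt_bv [bitvec()] objects of equal length; no column may be
#'   0 in both.
#' @param tgt_name target contig name (defaults to `name`).
#' @return An object of class `contig_lift`.
#' @export
contig_lift <- function(name, src_bv, tgt_bv, tgt_name = name) {
  stopifnot(inherits(src_bv, "bitvec"), inherits(tgt_bv, "bitvec"))
  if (src_bv$length != tgt_bv$length) {
    stop("contig_lift: src and tgt bitvectors differ in length")
  }
  if (any(src_bv$bits == 0L & tgt_bv$bits == 0L)) {
    stop("contig_lift: column contributes neither a source nor a target base")
  }
  structure(
    list(name = name, tgt_name = tgt_name,
         src_bv = src_bv, tgt_bv = tgt_bv,
         n_columns = src_bv$length),
    class = "contig_lift"
  )
}

#' @export
print.contig_lift <- function(x, ...) {
  cat(sprintf("<contig_lift> %s -> %s: %d columns, source %d bp, target %d bp\n",
              x$name, x$tgt_name, x$n_columns,
              x$src_bv$rank[x$n_columns + 1L],
              x$tgt_bv$rank[x$n_columns + 1L]))
  invisible(x)
}

src_len <- function(cl) cl$src_bv$rank[cl$n_columns + 1L]
tgt_len <- function(cl) cl$tgt_bv$rank[cl$n_columns + 1L]

# Trim the longest common suffix of REF/ALT, keeping at least one base on
# each side, then split into shared columns and the one-sided surplus.
# Returns counts only; the index does not store bases.
variant_shape <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  rs <- strsplit(ref, "")[[1L]]; as <- strsplit(alt, "")[[1L]]
  ts <- 0L
  while (nr - ts > 1L && na - ts > 1L && rs[nr - ts] == as[na - ts]) {
    ts <- ts + 1L
  }
  nr2 <- nr - ts; na2 <- na - ts
  sh <- min(nr2, na2)
  list(n_both_lead = sh,
       n_src_extra = max(0L, na2 - nr2),   # insertion surplus
       n_tgt_extra = max(0L, nr2 - na2),   # deletion surplus
       n_both_tail = ts)
}

valid_allele <- function(x) grepl("^[ACGTNacgtn]+$", x)

#' Build a lift index from a VCF
#'
#' Constructs one [contig_lift()] per contig from a sorted VCF whose
#' coordinates are relative to the **target** reference; the source
#' reference is the target with the ALT alleles applied. Insertions emit
#' src-only columns immediately after the shared anchor base, deletions
#' emit tgt-only columns; every other base (including SNV sites) is a
#' both-1 column. Contigs with lengths but no variants get an identity map.
#'
#' Records are screened streaming-style: multi-allelic records contribute
#' their first ALT only, records overlapping the REF span of an earlier
#' record are skipped, and symbolic / breakend / non-ACGTN alleles are
#' skipped — each with a warning. An unsorted VCF is an error.
#'
#' @param vcf path to a VCF file, or a data.frame with columns `chrom`,
#'   `pos` (1-based), `ref`, `alt`.
#' @param contig_lengths named integer vector of target contig lengths.
#'   When `vcf` is a path this defaults to the `##contig` header lengths;
#'   `fai` may name a FASTA `.fai` sidecar to use instead.
#' @param fai optional path to a `.fai` file providing contig lengths.
#' @param name_map optional named character vector mapping source contig
#'   names to target names (identity by default).
#' @return An object of class `lift_index`.
#' @export
build_index <- function(vcf, contig_lengths = NULL, fai = NULL,
                        name_map = NULL) {
  if (is.character(vcf) && length(vcf) == 1L) {
    sites <- read_vcf_sites(vcf)
    variants <- sites$variants
    if (is.null(contig_lengths)) {
      if (!is.null(fai)) {
        contig_lengths <- read_fai(fai)
      } else if (length(sites$contig_lengths)) {
        contig_lengths <- sites$contig_lengths
      }
    }
  } else {
    variants <- as.data.frame(vcf)
  }
  if (is.null(contig_lengths) || !length(contig_lengths)) {
    stop(paste("build_index: no contig lengths available;",
               "add ##contig=<ID=...,length=...> header lines to the VCF",
               "or supply a FASTA .fai via `fai`"))
  }
  missing_ctg <- setdiff(unique(variants$chrom), names(contig_lengths))
  if (length(missing_ctg)) {
    stop(sprintf("build_index: no length known for contig(s): %s",
                 paste(missing_ctg, collapse = ", ")))
  }
  # sortedness: positions non-decreasing within a contig, contigs contiguous
  if (nrow(variants)) {
    r <- rle(variants$chrom)
    if (anyDuplicated(r$values)) {
      stop("build_index: VCF is unsorted (contig blocks are interleaved)")
    }
    ooo <- unlist(tapply(variants$pos, factor(variants$chrom, r$values),
                         function(p) diff(p) < 0L), use.names = FALSE)
    if (any(ooo)) {
      stop("build_index: VCF is unsorted (positions decrease within a contig)")
    }
  }

  contigs <- vector("list", length(contig_lengths))
  names(contigs) <- names(contig_lengths)
  for (ctg in names(contig_lengths)) {
    clen <- contig_lengths[[ctg]]
    rows <- which(variants$chrom == ctg)
    # run-length emission: (n_both, n_src_only, n_tgt_only) per event
    both_runs <- integer(0); src_runs <- integer(0); tgt_runs <- integer(0)
    cursor <- 1L   # next unconsumed 1-based target position
    for (i in rows) {
      pos <- variants$pos[i]; ref <- variants$ref[i]; alt <- variants$alt[i]
      if (grepl(",", alt, fixed = TRUE)) {
        alt <- strsplit(alt, ",", fixed = TRUE)[[1L]][1L]
        warning(sprintf("%s:%d multi-allelic record: applying first ALT only",
                        ctg, pos), call. = FALSE)
      }
      if (!valid_allele(ref) || !valid_allele(alt)) {
        warning(sprintf(
          "%s:%d symbolic or non-ACGTN allele (%s>%s): record skipped",
          ctg, pos, ref, alt), call. = FALSE)
        next
      }
      if (pos < cursor) {
        warning(sprintf("%s:%d overlaps a previous record: skipped", ctg, pos),
                call. = FALSE)
        next
      }
      if (pos + nchar(ref) - 1L > clen) {
        warning(sprintf("%s:%d REF extends past contig end: skipped", ctg, pos),
                call. = FALSE)
        next
      }
      sh <- variant_shape(ref, alt)
      both_runs <- c(both_runs, (pos - cursor) + sh$n_both_lead)
      src_runs  <- c(src_runs, sh$n_src_extra)
      tgt_runs  <- c(tgt_runs, sh$n_tgt_extra)
      # the trailing shared suffix is emitted with the next inter-variant gap
      cursor <- pos + nchar(ref) - sh$n_both_tail
    }
    both_runs <- c(both_runs, clen - cursor + 1L)
    src_runs  <- c(src_runs, 0L)
    tgt_runs  <- c(tgt_runs, 0L)
    n_cols <- sum(both_runs) + sum(src_runs) + sum(tgt_runs)
    src_bits <- integer(n_cols); tgt_bits <- integer(n_cols)
    at <- 1L
    for (j in seq_along(both_runs)) {
      nb <- both_runs[j]
      if (nb > 0L) {
        src_bits[at:(at + nb - 1L)] <- 1L
        tgt_bits[at:(at + nb - 1L)] <- 1L
        at <- at + nb
      }
      ns <- src_runs[j]
      if (ns > 0L) {
        src_bits[at:(at + ns - 1L)] <- 1L
        at <- at + ns
      }
      nt <- tgt_runs[j]
      if (nt > 0L) {
        tgt_bits[at:(at + nt - 1L)] <- 1L
        at <- at + nt
      }
    }
    tname <- if (!is.null(name_map) && ctg %in% names(name_map)) {
      name_map[[ctg]]
    } else ctg
    contigs[[ctg]] <- contig_lift(ctg, bitvec(src_bits), bitvec(tgt_bits),
                                  tgt_name = tname)
  }
  nm <- vapply(contigs, function(cl) cl$tgt_name, character(1))
  lift_index(contigs, name_map = nm)
}

#' Collection of per-contig coordinate maps
#'
#' @param contigs named list of [contig_lift()] objects (keyed by source
#'   contig name).
#' @param name_map named character vector mapping source to target contig
#'   names; identity by default.
#' @return An object of class `lift_index`.
#' @export
lift_index <- function(contigs, name_map = NULL) {
  stopifnot(is.list(contigs))
  if (is.null(name_map)) {
    name_map <- stats::setNames(names(contigs), names(contigs))
  }
  if (!all(names(name_map) %in% names(contigs))) {
    stop("lift_index: name_map entry without a contig_lift")
  }
  structure(list(contigs = contigs, name_map = name_map, version = 1L),
            class = "lift_index")
}

#' @export
print.lift_index <- function(x, ...) {
  cat(sprintf("<lift_index> v%d, %d contig(s)\n", x$version,
              length(x$contigs)))
  for (cl in x$contigs) {
    cat(sprintf("  %s -> %s: source %d bp, target %d bp, %d columns\n",
                cl$name, cl$tgt_name, src_len(cl), tgt_len(cl), cl$n_columns))
  }
  invisible(x)
}

get_contig <- function(index, contig) {
  cl <- index$contigs[[contig]]
  if (is.null(cl)) stop(sprintf("contig not in index: %s", contig))
  cl
}

#' Lift a source position to target coordinates
#'
#' Maps a 0-based source position through the contig's column map. A base
#' in a both-1 column maps to its own target coordinate; an inserted base
#' (src-only column) maps to the next target base, clamped to
#' `target_length - 1` for insertions at the very end of the contig. The
#' result is non-decreasing in `s`.
#'
#' @param index a [lift_index()].
#' @param contig source contig name.
#' @param s 0-based source position(s); vectorized.
#' @return 0-based target position(s).
#' @export
lift_pos <- function(index, contig, s) {
  cl <- get_contig(index, contig)
  s <- as.integer(s)
  sl <- src_len(cl)
  if (length(s) == 0L || anyNA(s) || any(s < 0L | s >= sl)) {
    stop(sprintf("lift_pos: position out of range [0, %d) on %s", sl, contig))
  }
  cols <- cl$src_bv$sel[s + 1L]
  t <- cl$tgt_bv$rank[cols + 1L]
  ins <- cl$tgt_bv$bits[cols + 1L] == 0L
  if (any(ins)) t[ins] <- pmin(t[ins], tgt_len(cl) - 1L)
  t
}

# Lift an exclusive source end coordinate: number of target bases in
# columns up to and including the column of source base (e - 1). For an
# alignment ending on a both-1 base this is (target pos of that base) + 1.
lift_end <- function(cl, e) {
  cols <- cl$src_bv$sel[e]          # column of source base e-1
  cl$tgt_bv$rank[cols + 1L] + cl$tgt_bv$bits[cols + 1L]
}

#' Target contig length
#'
#' @param index a [lift_index()].
#' @param contig source contig name.
#' @return Length of the target version of the contig (popcount of its
#'   target bitvector).
#' @export
target_length <- function(index, contig) {
  tgt_len(get_contig(index, contig))
}

#' Source contig length
#'
#' @param index a [lift_index()].
#' @param contig source contig name.
#' @return Length of the source (variant-aware) version of the contig.
#' @export
source_length <- function(index, contig) {
  src_len(get_contig(index, contig))
}
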