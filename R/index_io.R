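#' Serialize a lift index
#'
#' Writes the index as a compact binary container (conventional suffix
#' `.lft`) so the VCF differences need not be recomputed. Layout, all
#' integers little-endian int32:
#'
#' * magic bytes `"LFTK"`, then the format version;
#' * contig count, then per contig: length-prefixed source name,
#'   length-prefixed target name, the column count, and the two bitvectors
#'   (source, then target) bit-packed into little-endian 64-bit words,
#'   least-significant bit first.
#'
#' @param index a [lift_index()].
#' @param path output file path, or a writable binary connection.
#' @return `path`, invisibly.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "lift_index"))
  con <- if (inherits(path, "connection")) path else {
    f <- file(path, "wb"); on.exit(close(f)); f
  }
  writeBin(charToRaw("LFTK"), con)
  writeBin(as.integer(index$version), con, size = 4L, endian = "little")
  writeBin(length(index$contigs), con, size = 4L, endian = "little")
  for (cl in index$contigs) {
    for (nm in c(cl$name, cl$tgt_name)) {
      raw_nm <- charToRaw(nm)
      writeBin(length(raw_nm), con, size = 4L, endian = "little")
      writeBin(raw_nm, con)
    }
    writeBin(cl$n_columns, con, size = 4L, endian = "little")
    writeBin(pack_words(cl$src_bv$bits), con)
    writeBin(pack_words(cl$tgt_bv$bits), con)
  }
  invisible(path)
}

# bit-pack 0/1 ints into little-endian 64-bit words (LSB-first), as raw
pack_words <- function(bits) {
  n <- length(bits)
  pad <- (64L - n %% 64L) %% 64L
  packBits(as.logical(c(bits, integer(pad))), type = "raw")
}

unpack_words <- function(raw, n) {
  as.integer(rawToBits(raw))[seq_len(n)]
}

index_format_error <- function(msg) {
  stop(sprintf("not a lift index (format error): %s", msg), call. = FALSE)
}

#' Load a serialized lift index
#'
#' Reads a container written by [save_index()]. The result is behaviorally
#' identical to the saved index: every `lift_pos`/`target_length` query
#' returns the same value.
#'
#' @param path path to a `.lft` file, or a readable binary connection.
#' @return A [lift_index()].
#' @export
load_index <- function(path) {
  con <- if (inherits(path, "connection")) path else {
    f <- file(path, "rb"); on.exit(close(f)); f
  }
  magic <- readBin(con, "raw", 4L)
  if (!identical(magic, charToRaw("LFTK"))) {
    index_format_error("bad magic bytes")
  }
  read_i32 <- function(what) {
    x <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(x) != 1L) index_format_error(paste("truncated at", what))
    x
  }
  version <- read_i32("version")
  if (version != 1L) {
    index_format_error(sprintf("unsupported format version %d", version))
  }
  n_contigs <- read_i32("contig count")
  if (n_contigs < 0L) index_format_error("negative contig count")
  contigs <- vector("list", n_contigs)
  nms <- character(n_contigs)
  for (i in seq_len(n_contigs)) {
    read_name <- function() {
      len <- read_i32("name length")
      if (len < 0L) index_format_error("negative name length")
      raw_nm <- readBin(con, "raw", len)
      if (length(raw_nm) != len) index_format_error("truncated contig name")
      rawToChar(raw_nm)
    }
    nm <- read_name()
    tnm <- read_name()
    n_cols <- read_i32("column count")
    if (n_cols < 0L) index_format_error("negative column count")
    nbytes <- 8L * ((n_cols + 63L) %/% 64L)
    read_bv <- function() {
      raw_bv <- readBin(con, "raw", nbytes)
      if (length(raw_bv) != nbytes) index_format_error("truncated bitvector")
      bitvec(unpack_words(raw_bv, n_cols))
    }
    sb <- read_bv()
    tb <- read_bv()
    contigs[[i]] <- contig_lift(nm, sb, tb, tgt_name = tnm)
    nms[i] <- nm
  }
  names(contigs) <- nms
  nm <- stats::setNames(vapply(contigs, function(cl) cl$tgt_name,
                               character(1)), nms)
  lift_index(contigs, name_map = nm)
}
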