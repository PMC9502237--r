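#' Read the site list of a VCF
#'
#' Reads CHROM/POS/REF/ALT from a VCF (plain or gzip/bgzip compressed) along
#' with any contig lengths declared in `##contig=<ID=...,length=...>` header
#' lines. Genotype and sample columns are ignored: the coordinate map is
#' built from the site list alone.
#'
#' @param path path to a VCF file.
#' @return A list with `variants` (data.frame with columns `chrom`, `pos`
#'   (1-based), `ref`, `alt`) and `contig_lengths` (named integer vector,
#'   possibly empty when the header carries no lengths).
#' @export
read_vcf_sites <- function(path) {
  if (!file.exists(path)) stop(sprintf("VCF not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE)
  fix <- v@fix
  variants <- data.frame(
    chrom = as.character(fix[, "CHROM"]),
    pos   = as.integer(fix[, "POS"]),
    ref   = as.character(fix[, "REF"]),
    alt   = as.character(fix[, "ALT"]),
    stringsAsFactors = FALSE
  )
  meta <- v@meta
  contig_lengths <- integer(0)
  ctg <- grep("^##contig=<", meta, value = TRUE)
  if (length(ctg)) {
    ids <- sub('.*[<,]ID=([^,>]+).*', "\\1", ctg)
    has_len <- grepl("[<,]length=", ctg)
    lens <- rep(NA_integer_, length(ctg))
    lens[has_len] <- as.integer(sub(".*[<,]length=([0-9]+).*", "\\1",
                                    ctg[has_len]))
    keep <- !is.na(lens)
    contig_lengths <- stats::setNames(lens[keep], ids[keep])
  }
  list(variants = variants, contig_lengths = contig_lengths)
}

#' Read contig lengths from a FASTA index
#'
#' Parses a `samtools faidx`-style `.fai` sidecar (tab separated; at least
#' name and length columns).
#'
#' @param path path to a `.fai` file.
#' @return Named integer vector of contig lengths.
#' @export
read_fai <- function(path) {
  if (!file.exists(path)) stop(sprintf(".fai not found: %s", path))
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop(".fai must have at least two columns (name, length)")
  stats::setNames(as.integer(tab[[2L]]), tab[[1L]])
}

#' Write a minimal sites-only VCF
#'
#' Writes a sorted, anchored, bi-allelic site list in VCF v4.2 form with
#' `##contig` length headers, the format consumed by [build_index()] and
#' emitted by the fixture generator.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`.
#' @param contig_lengths named integer vector of target contig lengths.
#' @param path output path (plain text; use a `.vcf` suffix).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, contig_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines(sprintf("##contig=<ID=%s,length=%d>",
                     names(contig_lengths), contig_lengths), con)
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(variants)) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                       variants$chrom, variants$pos,
                       variants$ref, variants$alt), con)
  }
  invisible(path)
}
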