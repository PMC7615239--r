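#' Construct a genome assembly
#'
#' A genome assembly is the coordinate universe for every interval the
#' package handles: an ordered set of chromosome names with lengths.
#' It is represented as a [GenomeInfoDb::Seqinfo] object; the declared
#' order defines the sort order of all genomic output.
#'
#' @param chroms Character vector of unique, non-empty chromosome names.
#' @param lengths Integer vector of chromosome lengths in base pairs,
#'   strictly positive, parallel to `chroms`.
#' @return A `Seqinfo` object.
#' @examples
#' genome_assembly(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_assembly <- function(chroms, lengths) {
  if (!is.character(chroms) || length(chroms) == 0L)
    stop("'chroms' must be a non-empty character vector")
  if (length(chroms) != length(lengths))
    stop("'chroms' and 'lengths' must have equal length")
  if (any(!nzchar(chroms)) || anyNA(chroms))
    stop("chromosome names must be non-empty")
  if (anyDuplicated(chroms))
    stop("duplicate chromosome name: ", chroms[duplicated(chroms)][1L])
  lengths <- as.integer(lengths)
  if (anyNA(lengths) || any(lengths <= 0L))
    stop("chromosome lengths must be strictly positive integers")
  GenomeInfoDb::Seqinfo(seqnames = chroms, seqlengths = lengths)
}

#' Read / write chromosome sizes
#'
#' Two-column tab-separated files (`name<TAB>length`), the `chrom.sizes`
#' convention used across genome browsers.
#'
#' @param path File path.
#' @return `read_chrom_sizes()` returns a `Seqinfo`;
#'   `write_chrom_sizes()` returns `path` invisibly.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "length"),
                   colClasses = c("character", "integer"))
  genome_assembly(df$chrom, df$length)
}

#' @rdname read_chrom_sizes
#' @param assembly A `Seqinfo` object.
#' @export
write_chrom_sizes <- function(assembly, path) {
  writeLines(paste(GenomeInfoDb::seqnames(assembly),
                   GenomeInfoDb::seqlengths(assembly), sep = "\t"), path)
  invisible(path)
}

#' Total assembly length in base pairs
#' @param assembly A `Seqinfo` object.
#' @return Numeric scalar (may exceed integer range).
#' @export
assembly_length <- function(assembly) {
  sum(as.numeric(GenomeInfoDb::seqlengths(assembly)))
}

## Bind an assembly to a GRanges and fail loudly on out-of-bounds records.
bind_assembly <- function(gr, assembly, what = "interval") {
  sl <- GenomeInfoDb::seqlengths(assembly)
  chr <- as.character(GenomeInfoDb::seqnames(gr))
  bad <- !(chr %in% names(sl))
  if (any(bad))
    stop(sprintf("%s %d on unknown chromosome '%s'",
                 what, which(bad)[1L], chr[bad][1L]))
  oob <- start(gr) < 1L | end(gr) > sl[chr]
  if (any(oob)) {
    i <- which(oob)[1L]
    stop(sprintf("%s %d (%s:%d-%d) outside assembly bounds (length %d)",
                 what, i, chr[i], start(gr)[i] - 1L, end(gr)[i], sl[chr][i]))
  }
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(assembly)
  GenomeInfoDb::seqinfo(gr) <- assembly
  gr
}

## 0-based half-open (BED) -> GRanges, with basic coordinate validation.
bed_to_granges <- function(chrom, start0, end0, assembly = NULL,
                           what = "interval") {
  start0 <- as.numeric(start0); end0 <- as.numeric(end0)
  bad <- is.na(start0) | is.na(end0) | start0 < 0 | start0 >= end0
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("%s %d has invalid coordinates [%s, %s)",
                 what, i, start0[i], end0[i]))
  }
  gr <- GRanges(chrom, IRanges(start = start0 + 1, end = end0))
  if (!is.null(assembly)) gr <- bind_assembly(gr, assembly, what)
  gr
}
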