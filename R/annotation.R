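#' Read gene models from GFF3
#'
#' Imports records of one feature type (default `"gene"`) from a GFF3
#' file into a `GRanges` with a `gene_id` metadata column taken from
#' the `ID` attribute. GFF3 1-based inclusive coordinates map directly
#' onto the 1-based closed `GRanges` representation. Child features
#' (mRNA, exon, ...) are ignored: peak-to-gene assignment operates on
#' gene spans, not transcript structure.
#'
#' @param path Path to a GFF3 file (optionally `.gz`).
#' @param feature_type Feature type (column 3) to keep.
#' @param assembly Optional `Seqinfo` for bounds checking.
#' @return A position-sorted `GRanges` with `gene_id`; strand is `+` or
#'   `-` (unstranded gene records are an error), and `gene_id` values
#'   are unique.
#' @export
read_gff3_genes <- function(path, feature_type = "gene", assembly = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  if (length(gr) && (is.null(gr$ID) || anyNA(gr$ID)))
    stop("GFF3 parse error: '", feature_type,
         "' records without an ID attribute in ", path)
  ids <- as.character(gr$ID)
  if (anyDuplicated(ids))
    stop("duplicate gene ID in ", path, ": ", ids[duplicated(ids)][1L])
  if (any(!as.character(strand(gr)) %in% c("+", "-"))) {
    bad <- ids[!as.character(strand(gr)) %in% c("+", "-")][1L]
    stop("gene '", bad, "' has strand '.'; gene models must be stranded")
  }
  out <- GRanges(seqnames(gr), ranges(gr), strand = strand(gr),
                 gene_id = ids)
  if (!is.null(assembly)) out <- bind_assembly(out, assembly, "gene")
  sort(out, ignore.strand = TRUE)
}

#' Write gene models as GFF3
#'
#' Minimal deterministic GFF3 serialization (one `gene` line per model,
#' `ID` attribute only); round-trips through [read_gff3_genes()]
#' preserving spans, strands and identifiers.
#'
#' @param genes A gene `GRanges` with `gene_id`.
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(genes, path, source = "chipsummit") {
  lines <- c("##gff-version 3",
             if (length(genes)) paste(as.character(seqnames(genes)), source, "gene",
                   format_int(start(genes)), format_int(end(genes)), ".",
                   as.character(strand(genes)), ".",
                   paste0("ID=", genes$gene_id), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' TSS and TTS of gene models
#'
#' The transcription start site is the 5' end of the gene span and the
#' transcription termination site the 3' end, so on the minus strand
#' the TSS is the right (higher-coordinate) end. Both always lie
#' inside the gene region; for a single-base gene they coincide.
#'
#' @param genes A stranded gene `GRanges`.
#' @return A `data.frame` with `gene_id`, `chrom`, `tss`, `tts`
#'   (1-based positions) and `strand`.
#' @export
tss_tts <- function(genes) {
  minus <- as.character(strand(genes)) == "-"
  data.frame(gene_id = if (!is.null(genes$gene_id)) genes$gene_id
                       else as.character(seq_along(genes)),
             chrom = as.character(seqnames(genes)),
             tss = ifelse(minus, end(genes), start(genes)),
             tts = ifelse(minus, start(genes), end(genes)),
             strand = as.character(strand(genes)),
             stringsAsFactors = FALSE)
}

#' Peak-assignment window around a gene
#'
#' The window runs from `flank` bp upstream of the TSS to `flank` bp
#' downstream of the TTS; because the two flanks are equal this is the
#' gene span extended by `flank` on both sides regardless of strand,
#' clipped to chromosome bounds. A summit anywhere in this window
#' (boundaries inclusive) is assignable to the gene.
#'
#' @param genes A gene `GRanges`.
#' @param flank Flank size in bp (>= 0); default 1000 (the "within
#'   1 kb" rule).
#' @return An unstranded `GRanges` of windows, parallel to `genes`,
#'   carrying `gene_id`.
#' @export
assignment_window <- function(genes, flank = 1000) {
  if (length(flank) != 1L || is.na(flank) || flank < 0)
    stop("'flank' must be a single non-negative number")
  flank <- as.integer(flank)
  lo <- pmax(1L, start(genes) - flank)
  hi <- end(genes) + flank
  sl <- GenomeInfoDb::seqlengths(genes)
  if (!all(is.na(sl)))
    hi <- pmin(hi, sl[as.character(seqnames(genes))])
  out <- GRanges(seqnames(genes), IRanges(lo, hi), seqinfo = seqinfo(genes))
  out$gene_id <- genes$gene_id
  out
}
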