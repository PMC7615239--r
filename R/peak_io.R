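#' Read a narrowPeak file
#'
#' Parses an ENCODE narrowPeak (BED6+4) file into a `GRanges` with
#' metadata columns `name`, `score`, `signalValue`, `pValue` and
#' `qValue` (the latter two as -log10 values, `-1` meaning "not
#' available" per the format), and `peak`, the summit offset in bp from
#' the region start (`-1` = unknown). Lines with fewer than 10 columns,
#' or summit offsets outside the peak, are rejected with the offending
#' line number. Gzip-compressed files are read transparently.
#'
#' Sample identity (`factor`, `condition`, `replicate`) is attached as
#' `metadata()` on the returned object and is carried through
#' filtering.
#'
#' @param path Path to a narrowPeak file (optionally `.gz`).
#' @param assembly Optional `Seqinfo`; peaks outside it are an error.
#' @param factor,condition,replicate Sample labels for this peak set.
#' @return A position-sorted `GRanges` (the record count equals the
#'   number of data lines in the file).
#' @export
read_narrowpeak <- function(path, assembly = NULL, factor = NA_character_,
                            condition = NA_character_,
                            replicate = NA_character_) {
  lines <- read_text_lines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 10L)) {
    i <- which(nf < 10L)[1L]
    stop(sprintf("narrowPeak parse error at line %d of '%s': expected 10 tab-separated columns, found %d",
                 lineno[i], path, nf[i]))
  }
  if (length(fields) == 0L) {
    gr <- GRanges()
  } else {
    m <- matrix(unlist(lapply(fields, `[`, 1:10)), ncol = 10L, byrow = TRUE)
    start0 <- suppressWarnings(as.numeric(m[, 2L]))
    end0 <- suppressWarnings(as.numeric(m[, 3L]))
    bad <- is.na(start0) | is.na(end0) | start0 < 0 | start0 >= end0
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("narrowPeak parse error at line %d of '%s': invalid interval [%s, %s)",
                   lineno[i], path, m[i, 2L], m[i, 3L]))
    }
    offset <- suppressWarnings(as.integer(m[, 10L]))
    bad <- is.na(offset) | offset < -1L | offset >= (end0 - start0)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("narrowPeak validation error at line %d of '%s': summit offset %s outside peak of length %d",
                   lineno[i], path, m[i, 10L], as.integer(end0[i] - start0[i])))
    }
    str <- m[, 6L]
    str[!str %in% c("+", "-")] <- "*"
    gr <- GRanges(m[, 1L], IRanges(start0 + 1, end0), strand = str,
                  name = m[, 4L],
                  score = as.integer(m[, 5L]),
                  signalValue = as.numeric(m[, 7L]),
                  pValue = as.numeric(m[, 8L]),
                  qValue = as.numeric(m[, 9L]),
                  peak = offset)
  }
  if (length(gr) == 0L)
    mcols(gr) <- S4Vectors::DataFrame(name = character(), score = integer(),
                                      signalValue = numeric(),
                                      pValue = numeric(), qValue = numeric(),
                                      peak = integer())
  if (!is.null(assembly)) gr <- bind_assembly(gr, assembly, "peak")
  gr <- sort(gr, ignore.strand = TRUE)
  metadata(gr) <- list(factor = factor, condition = condition,
                       replicate = replicate)
  gr
}

#' Write peaks as narrowPeak
#'
#' Serializes a peak `GRanges` (as produced by [read_narrowpeak()] or
#' the simulator) back to the 10-column narrowPeak format, converting
#' to 0-based half-open coordinates. Writing then re-reading is
#' lossless on all 10 columns.
#'
#' @param peaks A peak `GRanges` with the narrowPeak metadata columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  if (length(peaks) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  str <- as.character(strand(peaks))
  str[str == "*"] <- "."
  lines <- paste(as.character(seqnames(peaks)),
                 format_int(start(peaks) - 1L), format_int(end(peaks)),
                 peaks$name, format_int(peaks$score), str,
                 format_num(peaks$signalValue), format_num(peaks$pValue),
                 format_num(peaks$qValue), format_int(peaks$peak),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Filter peaks on called significance
#'
#' Retains peaks whose -log10 Q-value is at least `min_neglog10_q`
#' (inclusive). The default of 10 keeps peaks with Q-value <= 1e-10,
#' the "highly significant" stratum used for all downstream analysis;
#' peak callers are typically run at a much more permissive threshold
#' (e.g. q 0.05) and this is a post-hoc filter on their output.
#'
#' @param peaks A peak `GRanges` with a `qValue` metadata column.
#' @param min_neglog10_q Inclusive threshold on -log10(Q); `0` keeps
#'   everything.
#' @return The filtered `GRanges`, original order and metadata
#'   preserved.
#' @export
filter_by_q <- function(peaks, min_neglog10_q = 10) {
  if (is.null(peaks$qValue))
    stop("peaks have no 'qValue' column")
  if (any(peaks$qValue < 0))
    stop("some peaks have missing Q-values (qValue = -1); ",
         "supply peaks with called Q-values before filtering")
  meta <- metadata(peaks)
  out <- peaks[peaks$qValue >= min_neglog10_q]
  metadata(out) <- meta
  out
}

#' Peak summit positions
#'
#' The summit is the base of maximal estimated signal within a peak —
#' the anchor used for gene assignment. When the summit offset is
#' recorded (`peak >= 0`) the summit is `start + offset`; otherwise the
#' integer midpoint `floor((start0 + end0) / 2)` (0-based convention)
#' is used as a fallback, so BED-like inputs without summit calls
#' remain usable.
#'
#' @param peaks A peak `GRanges`.
#' @return A width-1 `GRanges` of summit positions, parallel to
#'   `peaks`, carrying over the `name` column if present.
#' @export
summit_position <- function(peaks) {
  if (length(peaks) == 0L)
    return(granges(peaks))
  offset <- peaks$peak
  if (is.null(offset)) offset <- rep(-1L, length(peaks))
  ## midpoint of BED [s0, e0) is floor((s0 + e0) / 2); +1 back to 1-based
  mid <- floor(((start(peaks) - 1L) + end(peaks)) / 2) + 1L
  pos <- ifelse(offset >= 0L, start(peaks) + offset, mid)
  out <- GRanges(seqnames(peaks), IRanges(pos, pos),
                 seqinfo = seqinfo(peaks))
  if (!is.null(peaks$name)) out$name <- peaks$name
  out
}

## --- shared I/O helpers -------------------------------------------------

read_text_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con)
}

## Deterministic numeric formatting: as.character() emits up to 15
## significant digits, which round-trips exactly for values that were
## parsed from decimal text of that precision.
format_num <- function(x) {
  out <- as.character(x)
  out[is.na(x)] <- "-1"
  out
}

format_int <- function(x) sprintf("%d", as.integer(x))
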