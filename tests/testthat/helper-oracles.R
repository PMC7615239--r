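## Independent brute-force oracles and small fixture builders. The
## oracles deliberately avoid GenomicRanges machinery: they work on
## plain vectors of 1-based closed coordinates with explicit loops, so
## they can arbitrate the interval engine.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

toy_assembly <- function(len = 10000L, n = 2L)
  genome_assembly(paste0("chr", seq_len(n)), rep(len, n))

## random intervals as a plain data.frame (1-based closed)
rand_intervals <- function(n, chroms = c("chr1", "chr2"), chrom_len = 10000L,
                           max_width = 500L) {
  start <- sample.int(chrom_len - max_width, n, replace = TRUE)
  width <- sample.int(max_width, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width - 1L,
             stringsAsFactors = FALSE)
}

df_to_gr <- function(df) GRanges(df$chrom, IRanges(df$start, df$end))

gr_to_df <- function(gr)
  data.frame(chrom = as.character(seqnames(gr)), start = start(gr),
             end = end(gr), stringsAsFactors = FALSE)

## quadratic pairwise merge to fixpoint; min_gap in the BED sense
## (gap bp between half-open intervals; touching always merges)
oracle_merge <- function(df, min_gap = 0) {
  max_gap_bp <- max(min_gap, 1) - 1   # merge iff gap_bp <= this
  rows <- split(df, seq_len(nrow(df)))
  repeat {
    merged <- FALSE
    for (i in seq_along(rows)) {
      if (merged) break
      for (j in seq_along(rows)) {
        if (i >= j) next
        a <- rows[[i]]; b <- rows[[j]]
        if (a$chrom != b$chrom) next
        gap <- max(a$start, b$start) - min(a$end, b$end) - 1L
        if (gap <= max_gap_bp) {
          rows[[i]] <- data.frame(chrom = a$chrom,
                                  start = min(a$start, b$start),
                                  end = max(a$end, b$end),
                                  stringsAsFactors = FALSE)
          rows[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start), , drop = FALSE]
}

## all-pairs overlap flags (>= 1 shared base, 1-based closed)
oracle_overlaps <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    any(subject$chrom == query$chrom[i] &
          subject$start <= query$end[i] &
          subject$end >= query$start[i])
  }, logical(1))
}

## linear-scan closest feature: coordinate-difference distance,
## ties to lexicographically smallest id
oracle_closest <- function(chrom, pos, df, ids) {
  on_chrom <- which(df$chrom == chrom)
  if (length(on_chrom) == 0L) return(list(index = NA, distance = NA))
  d <- vapply(on_chrom, function(i) {
    if (pos >= df$start[i] && pos <= df$end[i]) 0
    else min(abs(pos - df$start[i]), abs(pos - df$end[i]))
  }, numeric(1))
  cand <- on_chrom[d == min(d)]
  cand <- cand[order(ids[cand], cand)]
  list(index = cand[1L], distance = min(d))
}

## per-base metagene binning on plain vectors (NA off chromosome)
oracle_metagene_row <- function(cov_vec, gstart, gend, strand, flank,
                                body_bins, flank_bins) {
  chrom_len <- length(cov_vec)
  base_at <- function(p) if (p >= 1 && p <= chrom_len) cov_vec[p] else NA_real_
  L <- gend - gstart + 1L
  fbw <- flank %/% flank_bins
  pos <- seq(gstart - flank, gend + flank)
  vals <- vapply(pos, base_at, numeric(1))
  if (strand == "-") vals <- rev(vals)
  out <- numeric(0)
  for (b in seq_len(flank_bins))
    out <- c(out, mean(vals[((b - 1) * fbw + 1):(b * fbw)]))
  body <- vals[(flank + 1):(flank + L)]
  for (b in seq_len(body_bins)) {
    sel <- which(floor((seq_len(L) - 1) * body_bins / L) + 1 == b)
    out <- c(out, mean(body[sel]))
  }
  down <- vals[(flank + L + 1):(flank + L + flank)]
  for (b in seq_len(flank_bins))
    out <- c(out, mean(down[((b - 1) * fbw + 1):(b * fbw)]))
  out
}

## peak GRanges builder (1-based closed inputs)
mk_peaks <- function(start, end, chrom = "chr1", q = 20, offset = -1L,
                     factor = "FAC", condition = "COND",
                     replicate = "rep1", assembly = NULL,
                     name = sprintf("p%d", seq_along(start))) {
  n <- length(start)
  gr <- GRanges(rep(chrom, length.out = n), IRanges(start, end),
                name = name,
                score = rep(0L, n),
                signalValue = rep(1, n),
                pValue = rep_len(q + 1, n),
                qValue = rep_len(q, n),
                peak = rep_len(as.integer(offset), n))
  if (!is.null(assembly)) gr <- chipsummit:::bind_assembly(gr, assembly)
  gr <- sort(gr, ignore.strand = TRUE)
  metadata(gr) <- list(factor = factor, condition = condition,
                       replicate = replicate)
  gr
}

mk_genes <- function(start, end, strand = "+", chrom = "chr1",
                     ids = sprintf("G%d", seq_along(start)),
                     assembly = NULL) {
  gr <- GRanges(rep(chrom, length.out = length(start)),
                IRanges(start, end),
                strand = rep(strand, length.out = length(start)),
                gene_id = ids)
  if (!is.null(assembly)) gr <- chipsummit:::bind_assembly(gr, assembly)
  sort(gr, ignore.strand = TRUE)
}

## small deterministic step track: RleList from (start1, end1, value)
mk_track <- function(steps, assembly) {
  gr <- GRanges(steps$chrom, IRanges(steps$start, steps$end))
  gr <- chipsummit:::bind_assembly(gr, assembly, "step")
  cov <- coverage(gr, weight = steps$value)
  metadata(cov) <- list(normalization = "raw")
  cov
}
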