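#' Read a bedGraph coverage track
#'
#' Loads a 4-column bedGraph into a per-chromosome run-length encoded
#' coverage vector (`RleList`), one run per chromosome base range;
#' bases not covered by any step have value 0. Steps must be
#' non-overlapping (they are sorted on load); overlaps are a format
#' error. `track` header lines are ignored.
#'
#' @param path Path to a bedGraph file (optionally `.gz`).
#' @param assembly A `Seqinfo`; steps outside it are an error.
#' @return An `RleList` over all assembly chromosomes, with
#'   `metadata()$normalization == "raw"`.
#' @export
read_bedgraph <- function(path, assembly) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  gr <- bind_assembly(gr, assembly, "coverage step")
  if (!isDisjoint(gr)) {
    self <- findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
    stop(sprintf("bedGraph format error in '%s': overlapping steps (records %d and %d)",
                 path, queryHits(self)[1L], subjectHits(self)[1L]))
  }
  if (length(gr) && (any(!is.finite(gr$score)) || any(gr$score < 0)))
    stop("bedGraph values must be finite and >= 0 in ", path)
  cov <- coverage(gr, weight = if (length(gr)) gr$score else 1)
  metadata(cov) <- list(normalization = "raw")
  cov
}

#' Write a coverage track as bedGraph
#'
#' One line per constant-value run; zero-valued runs are omitted
#' (bedGraph's implicit zero), so write/read round trips reproduce the
#' track exactly.
#'
#' @param track An `RleList` coverage track.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  chunks <- lapply(names(track), function(chrom) {
    r <- track[[chrom]]
    ends <- cumsum(runLength(r))
    starts0 <- ends - runLength(r)   # 0-based starts
    val <- runValue(r)
    keep <- val != 0
    if (!any(keep)) return(character(0))
    paste(chrom, format_int(starts0[keep]), format_int(ends[keep]),
          format_num(val[keep]), sep = "\t")
  })
  writeLines(unlist(chunks), path)
  invisible(path)
}

#' RPGC (1x genomic content) normalization
#'
#' Scales a raw coverage track so that mean coverage over the
#' effective genome equals exactly 1 ("reads per genomic content"):
#' every value is multiplied by `G / sum(value * step_length)`, with
#' `G` the effective genome size (default: the total assembly length).
#' Tracks from different libraries become directly comparable.
#'
#' @param track A raw `RleList` coverage track.
#' @param effective_genome_size Optional effective genome size in bp.
#' @return The scaled `RleList`, tagged `normalization = "RPGC"`.
#' @export
rpgc_normalize <- function(track, effective_genome_size = NULL) {
  total <- track_total(track)
  if (total == 0)
    stop("cannot RPGC-normalize an all-zero track (undefined scale factor)")
  G <- if (is.null(effective_genome_size))
    sum(as.numeric(lengths(track))) else as.numeric(effective_genome_size)
  out <- track * (G / total)
  metadata(out) <- list(normalization = "RPGC",
                        effective_genome_size = G)
  out
}

#' Sum coverage tracks (replicate merging)
#'
#' Step-wise sum of raw tracks on the same assembly — the replicate
#' merging applied before RPGC normalization for metagene profiles.
#'
#' @param tracks A list of `RleList` tracks with identical chromosome
#'   layouts.
#' @return The summed `RleList`, tagged `raw`.
#' @export
merge_tracks <- function(tracks) {
  stopifnot(is.list(tracks), length(tracks) >= 1L)
  out <- Reduce(`+`, tracks)
  metadata(out) <- list(normalization = "raw")
  out
}

track_total <- function(track) {
  sum(vapply(track,
             function(r) sum(as.numeric(runValue(r)) * runLength(r)),
             numeric(1)))
}

#' Per-gene metagene coverage matrix
#'
#' Extracts, for every gene, coverage over a fixed-width upstream
#' flank, the gene body rescaled to a common number of bins, and a
#' fixed-width downstream flank. Flank bins have width
#' `flank / flank_bins` bp; body bins partition the gene into
#' `body_bins` near-equal base spans (base `i` of a length-`L` body
#' goes to bin `floor(i * body_bins / L)`), each bin holding the mean
#' coverage of its span. Rows of minus-strand genes are reversed so
#' that bin 1 is always 5'-most. Flank bins that run off the
#' chromosome are `NA`; genes shorter than `min_gene_length` are
#' dropped (with a message).
#'
#' @param track An `RleList` coverage track (normally RPGC-scaled).
#' @param genes A stranded gene `GRanges` with `gene_id`.
#' @param flank Flank length in bp; must be a multiple of
#'   `flank_bins`.
#' @param body_bins,flank_bins Bin counts for body and each flank.
#' @param min_gene_length Minimum body length in bp (default:
#'   `body_bins`, so no body bin is empty).
#' @return A numeric matrix, one row per retained gene (rownames =
#'   `gene_id`), `flank_bins + body_bins + flank_bins` columns, with a
#'   `"role"` attribute marking each column `upstream`/`body`/
#'   `downstream`.
#' @export
metagene_matrix <- function(track, genes, flank = 1000, body_bins = 100,
                            flank_bins = 20, min_gene_length = body_bins) {
  stopifnot(flank > 0, body_bins > 0, flank_bins > 0)
  if (flank %% flank_bins != 0)
    stop("'flank' must be a multiple of 'flank_bins'")
  short <- width(genes) < min_gene_length
  if (any(short)) {
    message(sum(short), " gene(s) shorter than ", min_gene_length,
            " bp excluded from the metagene matrix")
    genes <- genes[!short]
  }
  if (length(genes) == 0L) stop("no genes left to profile")
  fb_width <- flank %/% flank_bins
  ncol_out <- flank_bins + body_bins + flank_bins
  chrom_len <- setNames(lengths(track), names(track))
  mat <- matrix(NA_real_, nrow = length(genes), ncol = ncol_out,
                dimnames = list(genes$gene_id, NULL))
  for (g in seq_along(genes)) {
    chrom <- as.character(seqnames(genes))[g]
    if (!chrom %in% names(track))
      stop("gene '", genes$gene_id[g], "' on chromosome '", chrom,
           "' absent from the coverage track")
    L <- width(genes)[g]
    s <- start(genes)[g] - flank
    e <- end(genes)[g] + flank
    len <- chrom_len[[chrom]]
    vals <- rep(NA_real_, e - s + 1L)
    lo <- max(1L, s); hi <- min(len, e)
    if (lo <= hi)
      vals[(lo - s + 1L):(hi - s + 1L)] <-
        as.numeric(window(track[[chrom]], lo, hi))
    if (as.character(strand(genes))[g] == "-") vals <- rev(vals)
    bin <- c(rep(seq_len(flank_bins), each = fb_width),
             flank_bins + floor((seq_len(L) - 1) * body_bins / L) + 1L,
             flank_bins + body_bins + rep(seq_len(flank_bins),
                                          each = fb_width))
    ## mean without na.rm: a flank bin is NA unless fully on-chromosome
    sums <- rowsum(vals, bin)
    cnts <- rowsum(rep(1, length(bin)), bin)
    mat[g, as.integer(rownames(sums))] <- sums / cnts
  }
  structure(mat,
            role = rep(c("upstream", "body", "downstream"),
                       c(flank_bins, body_bins, flank_bins)),
            flank = flank, body_bins = body_bins, flank_bins = flank_bins)
}

#' Mean metagene profile
#'
#' Column-wise mean of a per-gene metagene matrix, ignoring `NA` bins
#' (off-chromosome flanks); a bin that is `NA` for every gene stays
#' `NA`. Control tracks (e.g. input chromatin) are profiled
#' identically and plotted alongside, not subtracted.
#'
#' @param mat A matrix from [metagene_matrix()].
#' @return An object of class `metagene_profile`: a list with
#'   `values`, `n` (non-`NA` genes per bin), `n_genes`, `role`, and
#'   the bin geometry.
#' @export
mean_profile <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) >= 1L)
  n <- colSums(!is.na(mat))
  values <- suppressWarnings(colMeans(mat, na.rm = TRUE))
  values[n == 0L] <- NA_real_
  structure(list(values = unname(values), n = unname(n),
                 n_genes = nrow(mat),
                 role = attr(mat, "role"),
                 flank = attr(mat, "flank"),
                 body_bins = attr(mat, "body_bins"),
                 flank_bins = attr(mat, "flank_bins")),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("metagene profile: %d genes, %d bins (%d flank + %d body + %d flank)\n",
              x$n_genes, length(x$values), x$flank_bins, x$body_bins,
              x$flank_bins))
  cat(sprintf("  mean coverage: upstream %.3f, body %.3f, downstream %.3f\n",
              mean(x$values[x$role == "upstream"], na.rm = TRUE),
              mean(x$values[x$role == "body"], na.rm = TRUE),
              mean(x$values[x$role == "downstream"], na.rm = TRUE)))
  invisible(x)
}

#' @export
as.data.frame.metagene_profile <- function(x, ...) {
  data.frame(bin = seq_along(x$values), role = x$role,
             mean = x$values, n = x$n, stringsAsFactors = FALSE)
}

#' Write a metagene profile as TSV
#' @param profile A `metagene_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  write_tsv_file(as.data.frame(profile), path)
}
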