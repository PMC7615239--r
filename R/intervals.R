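#' Merge genomic intervals
#'
#' Collapses a set of intervals into maximal disjoint intervals. Two
#' intervals merge when they overlap, touch, or are separated by a gap
#' of fewer than `min_gap` base pairs; `min_gap = 0` therefore means
#' "touching or overlapping intervals merge" (BED `[a,b)` and `[b,c)`
#' become `[a,c)`). The operation is idempotent and independent of
#' input order; output is sorted by chromosome (assembly order) then
#' start.
#'
#' @param x A `GRanges`. Strand is ignored.
#' @param min_gap Non-negative gap threshold in bp: intervals separated
#'   by a gap strictly smaller than `min_gap` are merged (touching
#'   intervals always merge).
#' @param assembly Optional `Seqinfo`; when supplied, records outside
#'   the assembly raise a coordinate error naming the record.
#' @return A sorted, disjoint `GRanges`.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 151), c(200, 250)))
#' merge_intervals(gr)
#' @export
merge_intervals <- function(x, min_gap = 0, assembly = NULL) {
  if (!is(x, "GRanges")) stop("'x' must be a GRanges")
  if (length(min_gap) != 1L || is.na(min_gap) || min_gap < 0)
    stop("'min_gap' must be a single non-negative number")
  if (!is.null(assembly)) x <- bind_assembly(x, assembly)
  strand(x) <- "*"
  ## reduce() merges ranges separated by a gap < min.gapwidth;
  ## min.gapwidth = 1 merges touching ranges only, matching min_gap = 0.
  sort(reduce(x, min.gapwidth = max(as.integer(min_gap), 1L)),
       ignore.strand = TRUE)
}

#' Flag query intervals overlapped by a subject set
#'
#' One logical per query interval: `TRUE` iff at least one subject
#' interval shares at least one base with it. Half-open/closed
#' conventions are respected: BED `[0,100)` and `[100,200)` (adjacent
#' intervals) do not overlap.
#'
#' @param query,subject `GRanges` objects. Strand is ignored.
#' @return Logical vector parallel to `query`.
#' @export
overlaps_any <- function(query, subject) {
  as.logical(overlapsAny(query, subject, minoverlap = 1L,
                         ignore.strand = TRUE))
}

#' Closest feature to a genomic point
#'
#' Finds, among `features`, the interval closest to a single genomic
#' position. Distance is 0 when the point lies inside a feature,
#' otherwise the coordinate difference to the nearer end base of the
#' feature. Ties are broken by the lexicographically smallest feature
#' identifier (then by input index), so results are deterministic.
#'
#' @param chrom Chromosome name of the point.
#' @param pos 1-based position of the point.
#' @param features A `GRanges` of candidate features.
#' @param ids Optional character identifiers parallel to `features`
#'   used for tie-breaking (defaults to `names(features)`).
#' @return A list with `index` (into `features`; `NA` if no feature is
#'   on the point's chromosome) and `distance` (bp; `NA` if none).
#' @export
closest_feature <- function(chrom, pos, features, ids = names(features)) {
  stopifnot(length(chrom) == 1L, length(pos) == 1L)
  on_chrom <- which(as.character(seqnames(features)) == chrom)
  if (length(on_chrom) == 0L)
    return(list(index = NA_integer_, distance = NA_real_))
  d <- point_to_range_distance(pos, start(features)[on_chrom],
                               end(features)[on_chrom])
  cand <- on_chrom[d == min(d)]
  if (length(cand) > 1L) {
    key <- if (!is.null(ids)) ids[cand] else as.character(cand)
    cand <- cand[order(key, cand)]
  }
  list(index = cand[1L], distance = min(d))
}

## Coordinate-difference distance from point(s) to range end bases:
## 0 inside, else |pos - start| or |pos - end| in 1-based coordinates
## (equivalently, distance to the nearest end *base*, not the gap).
point_to_range_distance <- function(pos, start, end) {
  pmax(start - pos, pos - end, 0)
}
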