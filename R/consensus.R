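#' Build consensus peaks across replicates
#'
#' Pools the peaks of all replicates of one factor/condition, clusters
#' transitively overlapping peaks (merge semantics of
#' [merge_intervals()] at `min_gap = 0`), and emits one consensus peak
#' per cluster supported by at least `min_support` distinct replicates
#' — by default two, the reproducibility rule for calling a region a
#' genuine binding site. Several peaks from the same replicate in one
#' cluster count once toward support.
#'
#' The consensus region is the union span of the cluster; its summit is
#' the summit of the member peak with the highest -log10 Q-value
#' (ties resolved to the leftmost summit).
#'
#' @param replicates A list of replicate peak `GRanges` (as from
#'   [read_narrowpeak()], normally Q-filtered first). All must carry
#'   the same `factor` and `condition` metadata; mixing is an error.
#' @param min_support Minimum number of distinct supporting replicates
#'   (>= 1). Values below 2 drop the replication requirement — only
#'   sensible for single-replicate designs — and emit a warning.
#' @return A sorted `GRanges` with metadata columns `name`
#'   (`consensus_<factor>_<condition>_<k>`), `support`, `n_members`,
#'   `members` (comma-separated `replicate:peak_index`), `summit`
#'   (1-based bp) and `best_q`.
#' @export
build_consensus <- function(replicates, min_support = 2) {
  if (!is.list(replicates) || length(replicates) == 0L)
    stop("'replicates' must be a non-empty list of peak GRanges")
  if (min_support < 1L) stop("'min_support' must be >= 1")
  if (min_support < 2L)
    warning("min_support < 2 drops the replication requirement; ",
            "consensus peaks may reflect single-replicate noise")
  fac <- unique(unlist(lapply(replicates, function(x) metadata(x)$factor)))
  cond <- unique(unlist(lapply(replicates, function(x) metadata(x)$condition)))
  fac <- fac[!is.na(fac)]; cond <- cond[!is.na(cond)]
  if (length(fac) > 1L || length(cond) > 1L)
    stop("replicates mix factors/conditions: ",
         paste(fac, collapse = ","), " / ", paste(cond, collapse = ","))
  fac <- if (length(fac)) fac else "NA"
  cond <- if (length(cond)) cond else "NA"

  rep_ids <- vapply(seq_along(replicates), function(i) {
    rid <- metadata(replicates[[i]])$replicate
    if (is.null(rid) || is.na(rid)) {
      nm <- names(replicates)[i]
      if (!is.null(nm) && nzchar(nm)) nm else sprintf("rep%d", i)
    } else as.character(rid)
  }, character(1))

  pooled <- do.call(c, lapply(seq_along(replicates), function(i) {
    gr <- granges(replicates[[i]])
    mcols(gr) <- S4Vectors::DataFrame(
      rep_id = rep(rep_ids[i], length(gr)),
      peak_index = seq_len(length(gr)),
      qValue = if (length(gr)) replicates[[i]]$qValue else numeric(),
      summit = start(summit_position(replicates[[i]])))
    gr
  }))

  empty <- GRanges()
  mcols(empty) <- S4Vectors::DataFrame(name = character(),
                                       support = integer(),
                                       n_members = integer(),
                                       members = character(),
                                       summit = integer(),
                                       best_q = numeric())
  if (length(pooled) == 0L) return(empty)

  clusters <- merge_intervals(pooled)
  hits <- findOverlaps(pooled, clusters, ignore.strand = TRUE)
  cl <- subjectHits(hits)[order(queryHits(hits))]  # one cluster per peak
  groups <- split(seq_along(pooled), cl)

  support <- vapply(groups, function(i) length(unique(pooled$rep_id[i])),
                    integer(1))
  keep <- which(support >= min_support)
  if (length(keep) == 0L) return(empty)

  cluster_idx <- as.integer(names(groups))[keep]
  out <- clusters[cluster_idx]
  out$support <- unname(support[keep])
  out$n_members <- unname(vapply(groups[keep], length, integer(1)))
  out$members <- unname(vapply(groups[keep], function(i) {
    i <- i[order(pooled$rep_id[i], pooled$peak_index[i])]
    paste(pooled$rep_id[i], pooled$peak_index[i], sep = ":", collapse = ",")
  }, character(1)))
  pick <- unname(vapply(groups[keep], function(i) {
    i <- i[pooled$qValue[i] == max(pooled$qValue[i])]
    i[which.min(pooled$summit[i])]
  }, integer(1)))
  out$summit <- pooled$summit[pick]
  out$best_q <- pooled$qValue[pick]
  out <- sort(out, ignore.strand = TRUE)
  out$name <- sprintf("consensus_%s_%s_%d", fac, cond, seq_along(out))
  mcols(out) <- mcols(out)[, c("name", "support", "n_members", "members",
                               "summit", "best_q")]
  metadata(out) <- list(factor = fac, condition = cond,
                        min_support = min_support)
  out
}

#' Write / read consensus peaks as BED6+1
#'
#' Columns: chrom, start, end, name, score (0), strand (`.`), support.
#' Regions and support survive a round trip; summits and member lists
#' do not (they live in the TSV outputs of the pipeline).
#'
#' @param consensus A consensus `GRanges` from [build_consensus()].
#' @param path File path.
#' @return `consensus_to_bed()` returns `path` invisibly;
#'   `read_consensus_bed()` returns a `GRanges` with `name` and
#'   `support`.
#' @export
consensus_to_bed <- function(consensus, path) {
  if (length(consensus) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- paste(as.character(seqnames(consensus)),
                 format_int(start(consensus) - 1L),
                 format_int(end(consensus)),
                 consensus$name, "0", ".",
                 format_int(consensus$support), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname consensus_to_bed
#' @param assembly Optional `Seqinfo` for bounds checking.
#' @export
read_consensus_bed <- function(path, assembly = NULL) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    gr <- GRanges()
    mcols(gr) <- S4Vectors::DataFrame(name = character(), support = integer())
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 7L))
    stop("consensus BED parse error in ", path,
         ": expected 7 columns at line ", which(lengths(fields) < 7L)[1L])
  m <- matrix(unlist(lapply(fields, `[`, 1:7)), ncol = 7L, byrow = TRUE)
  gr <- bed_to_granges(m[, 1L], m[, 2L], m[, 3L], assembly, "consensus peak")
  gr$name <- m[, 4L]
  gr$support <- as.integer(m[, 7L])
  gr
}
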