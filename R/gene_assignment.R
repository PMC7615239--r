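#' Assign consensus peaks to genes by summit position
#'
#' A peak is assigned to a gene when its summit falls within the gene's
#' assignment window — 1 kb upstream of the TSS to 1 kb downstream of
#' the TTS by default (see [assignment_window()]). When several genes'
#' windows contain the summit, the closest gene wins: distance is
#' measured from the summit to the gene body (0 if the summit lies
#' inside the body, otherwise the coordinate difference to the nearer
#' end base), with ties broken by the lexicographically smallest
#' `gene_id`. A peak whose summit lies in no window is left
#' unassigned (`gene_id = NA`).
#'
#' @param consensus A consensus `GRanges` from [build_consensus()] (any
#'   peak `GRanges` with a `summit` column, or summits derivable via
#'   [summit_position()], is accepted).
#' @param genes A gene `GRanges` with `gene_id`.
#' @param flank Assignment window flank in bp (default 1000).
#' @return A `data.frame` with one row per peak: `peak_id`, `chrom`,
#'   `summit` (1-based), `gene_id` (`NA` if unassigned), `distance`
#'   (bp to gene body; `NA` if unassigned; `<= flank` when assigned),
#'   `n_candidates`, and the peak set's `factor`/`condition` labels.
#' @export
assign_peaks <- function(consensus, genes, flank = 1000) {
  fac <- metadata(consensus)$factor
  cond <- metadata(consensus)$condition
  if (is.null(fac)) fac <- NA_character_
  if (is.null(cond)) cond <- NA_character_
  n <- length(consensus)
  summit <- consensus$summit
  if (is.null(summit)) summit <- start(summit_position(consensus))
  peak_id <- consensus$name
  if (is.null(peak_id)) peak_id <- sprintf("peak_%d", seq_len(n))
  out <- data.frame(peak_id = as.character(peak_id),
                    chrom = as.character(seqnames(consensus)),
                    summit = as.integer(summit),
                    gene_id = NA_character_,
                    distance = NA_integer_,
                    n_candidates = 0L,
                    factor = rep(fac, n), condition = rep(cond, n),
                    stringsAsFactors = FALSE)
  if (n == 0L || length(genes) == 0L) return(out)

  summits <- GRanges(out$chrom, IRanges(out$summit, out$summit))
  windows <- assignment_window(genes, flank)
  hits <- findOverlaps(summits, windows, ignore.strand = TRUE)
  if (length(hits) == 0L) return(out)
  qh <- queryHits(hits); sh <- subjectHits(hits)
  d <- point_to_range_distance(out$summit[qh], start(genes)[sh],
                               end(genes)[sh])
  gid <- genes$gene_id[sh]
  ## winner per peak: minimal body distance, then smallest gene_id
  ord <- order(qh, d, gid)
  first <- !duplicated(qh[ord])
  win <- ord[first]
  out$gene_id[qh[win]] <- gid[win]
  out$distance[qh[win]] <- as.integer(d[win])
  nc <- table(qh)
  out$n_candidates[as.integer(names(nc))] <- as.integer(nc)
  out
}

#' Target-gene counts per factor and condition
#'
#' Summarizes peak-to-gene assignments into the per-sample table of
#' peak and target-gene counts: `n_peaks` is the number of consensus
#' peaks and `n_genes` the number of distinct assigned genes (a gene
#' hit by several peaks counts once; unassigned peaks contribute to
#' `n_peaks` only).
#'
#' @param assignments A `data.frame` from [assign_peaks()], or a list
#'   of them (concatenated).
#' @return A `data.frame` with columns `factor`, `condition`,
#'   `n_peaks`, `n_genes`, ordered by factor then condition.
#' @export
target_gene_table <- function(assignments) {
  if (is.data.frame(assignments)) assignments <- list(assignments)
  df <- do.call(rbind, assignments)
  if (is.null(df) || nrow(df) == 0L)
    return(data.frame(factor = character(), condition = character(),
                      n_peaks = integer(), n_genes = integer(),
                      stringsAsFactors = FALSE))
  key <- paste(df$factor, df$condition, sep = "\r")
  groups <- split(seq_len(nrow(df)), key)
  res <- lapply(groups, function(i) {
    data.frame(factor = df$factor[i[1L]], condition = df$condition[i[1L]],
               n_peaks = length(i),
               n_genes = length(unique(df$gene_id[i][!is.na(df$gene_id[i])])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$factor, out$condition), , drop = FALSE]
  rownames(out) <- NULL
  out
}
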