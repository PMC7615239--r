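#' Pairwise peak overlap matrix
#'
#' For every ordered pair of peak sets, the percentage of the row set's
#' peaks that are overlapped (>= 1 bp) by at least one peak of the
#' column set. The matrix is asymmetric in general — 80% of a small
#' set may sit inside a large set that is itself mostly elsewhere.
#' Rows and columns of empty sets are `NA`, not 0; the diagonal of a
#' non-empty set is 100.
#'
#' @param sets A named list of >= 2 peak `GRanges` (typically consensus
#'   peaks) on one assembly.
#' @param digits Decimal places for the reported percentages.
#' @return A numeric matrix with `dimnames` from `names(sets)`.
#' @export
pairwise_overlap_matrix <- function(sets, digits = 1) {
  if (!is.list(sets) || length(sets) < 2L)
    stop("'sets' must be a list of at least two peak sets")
  labels <- names(sets)
  if (is.null(labels) || any(!nzchar(labels)))
    labels <- sprintf("set%d", seq_along(sets))
  k <- length(sets)
  pct <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k)) {
    if (length(sets[[i]]) == 0L) next
    for (j in seq_len(k)) {
      if (length(sets[[j]]) == 0L) next
      pct[i, j] <- round(100 * mean(overlaps_any(sets[[i]], sets[[j]])),
                         digits)
    }
  }
  pct
}

#' Multi-way co-occupancy of a reference peak set
#'
#' Partitions the peaks of a designated reference set by exactly which
#' of the other sets overlap them, giving the counts behind a
#' multi-factor co-occupancy heat map. With `k` sets there are
#' `2^(k-1)` rows (every subset of the non-reference sets, including
#' "none"), and the counts sum to the size of the reference set.
#'
#' @param sets A named list of >= 2 peak `GRanges`.
#' @param reference Name or index of the reference set (default: the
#'   first).
#' @return A `data.frame` with one logical column per non-reference
#'   set, a `combination` label (`+`-joined names, or `"none"`), and
#'   `count`.
#' @export
multiway_cooccupancy <- function(sets, reference = 1L) {
  if (!is.list(sets) || length(sets) < 2L)
    stop("'sets' must be a list of at least two peak sets")
  labels <- names(sets)
  if (is.null(labels)) labels <- sprintf("set%d", seq_along(sets))
  ref_i <- if (is.character(reference)) match(reference, labels)
           else as.integer(reference)
  if (is.na(ref_i) || ref_i < 1L || ref_i > length(sets))
    stop("unknown reference set: ", reference)
  ref <- sets[[ref_i]]
  others <- sets[-ref_i]
  other_labels <- labels[-ref_i]
  flags <- vapply(others, function(s) overlaps_any(ref, s),
                  logical(length(ref)))
  if (length(ref) == 1L) flags <- matrix(flags, nrow = 1L)
  if (length(ref) == 0L)
    flags <- matrix(logical(0), nrow = 0L, ncol = length(others))
  m <- length(others)
  ## all 2^m subsets in binary-counting order: row 1 = none
  subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m))[, m:1,
                                                                 drop = FALSE])
  colnames(subsets) <- other_labels
  obs_key <- apply(flags, 1L, function(f) paste(as.integer(f), collapse = ""))
  sub_key <- apply(subsets, 1L, function(f) paste(as.integer(f), collapse = ""))
  counts <- as.integer(table(factor(obs_key, levels = sub_key)))
  combo <- apply(subsets, 1L, function(f) {
    if (!any(f)) "none" else paste(other_labels[f], collapse = "+")
  })
  out <- data.frame(subsets, combination = combo, count = counts,
                    stringsAsFactors = FALSE, check.names = FALSE)
  attr(out, "reference") <- labels[ref_i]
  out
}

#' Compare two gene-identifier sets
#'
#' Exact set arithmetic between two gene lists — sizes, intersection,
#' and the percentage of `a` found in `b` — with an optional
#' hypergeometric enrichment test when a finite gene universe is
#' supplied (upper tail: probability of an intersection at least as
#' large under random draws). The hypergeometric p-value is an extra
#' beyond the raw overlap percentages and is flagged as such in the
#' result.
#'
#' @param a,b Character vectors of gene identifiers.
#' @param universe Optional character vector; when given, `a` and `b`
#'   must be subsets of it (offenders are reported).
#' @param normalize Normalize identifiers before comparing: trim
#'   whitespace, upper-case, strip a trailing `.N` version suffix.
#' @return A list with `n_a`, `n_b`, `n_common`, `pct_a_in_b`, and —
#'   when `universe` is supplied — `n_universe` and `p_hyper`
#'   (`p_hyper_note` marks it as an optional addition).
#' @export
gene_set_overlap <- function(a, b, universe = NULL, normalize = TRUE) {
  norm <- function(x) {
    x <- trimws(as.character(x))
    x <- x[nzchar(x)]
    if (normalize) x <- sub("\\.[0-9]+$", "", toupper(x))
    unique(x)
  }
  a <- norm(a); b <- norm(b)
  out <- list(n_a = length(a), n_b = length(b),
              n_common = length(intersect(a, b)),
              pct_a_in_b = if (length(a))
                round(100 * length(intersect(a, b)) / length(a), 1)
                else NA_real_)
  if (!is.null(universe)) {
    u <- norm(universe)
    miss_a <- setdiff(a, u); miss_b <- setdiff(b, u)
    if (length(miss_a) || length(miss_b))
      stop("gene IDs outside the universe: ",
           paste(utils::head(c(miss_a, miss_b), 5L), collapse = ", "))
    out$n_universe <- length(u)
    out$p_hyper <- phyper(out$n_common - 1L, out$n_b,
                          length(u) - out$n_b, out$n_a,
                          lower.tail = FALSE)
    out$p_hyper_note <- "optional enrichment statistic (not part of the raw overlap percentages)"
  }
  out
}

#' Read a gene-identifier list
#'
#' One identifier per line; blank lines and `#` comments are skipped.
#'
#' @param path File path.
#' @return Character vector of identifiers.
#' @export
read_gene_list <- function(path) {
  x <- trimws(read_text_lines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write an overlap matrix as TSV
#'
#' Row labels in the first column; missing values written as `NA`.
#'
#' @param pct Matrix from [pairwise_overlap_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_overlap_matrix <- function(pct, path) {
  df <- data.frame(set = rownames(pct), pct, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_file(df, path)
}
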