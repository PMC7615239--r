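#' Read and validate a pipeline run configuration
#'
#' YAML configuration describing one analysis run. Required fields:
#' `genome` (chrom.sizes TSV), `annotation` (GFF3), and `peaks` (a list
#' of entries with `factor`, `condition`, `replicate`, `path`).
#' Optional: `coverage` (entries with `factor`, `condition`, `role`
#' (`ip`/`input`), `path`) and `params` overriding `min_qneglog10`
#' (default 10), `min_support` (2), `flank` (1000), `body_bins` (100),
#' `flank_bins` (20), `min_gene_length`. Relative paths are resolved
#' against the config file's directory; every referenced file must
#' exist.
#'
#' @param path Path to a YAML config file.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    p <- ifelse(grepl("^/", p), p, file.path(base, p))
    missing <- !file.exists(p)
    if (any(missing)) stop("configured file not found: ", p[missing][1L])
    p
  }
  for (f in c("genome", "annotation"))
    if (is.null(cfg[[f]])) stop("config is missing required field '", f, "'")
  cfg$genome <- resolve(cfg$genome)
  cfg$annotation <- resolve(cfg$annotation)
  if (is.null(cfg$peaks) || length(cfg$peaks) == 0L)
    stop("config must list at least one peaks entry")
  for (i in seq_along(cfg$peaks)) {
    e <- cfg$peaks[[i]]
    if (!all(c("factor", "condition", "replicate", "path") %in% names(e)))
      stop("peaks entry ", i,
           " needs fields factor, condition, replicate, path")
    cfg$peaks[[i]]$path <- resolve(e$path)
  }
  for (i in seq_along(cfg$coverage)) {
    e <- cfg$coverage[[i]]
    if (!all(c("factor", "condition", "path") %in% names(e)))
      stop("coverage entry ", i, " needs fields factor, condition, path")
    cfg$coverage[[i]]$path <- resolve(e$path)
    if (is.null(e$role)) cfg$coverage[[i]]$role <- "ip"
  }
  defaults <- list(min_qneglog10 = 10, min_support = 2L, flank = 1000L,
                   body_bins = 100L, flank_bins = 20L,
                   min_gene_length = NULL)
  cfg$params <- utils::modifyList(defaults,
                                  if (is.null(cfg$params)) list()
                                  else cfg$params)
  cfg$config_path <- normalizePath(path)
  structure(cfg, class = "run_config")
}

#' Run the full downstream analysis pipeline
#'
#' Executes the stages in order — significance filtering, consensus
#' peak construction per factor/condition, summit-based gene
#' assignment, the target-gene table, per-condition co-occupancy
#' matrices, and (when coverage is configured) replicate-merged,
#' RPGC-normalized metagene profiles — writing deterministic TSV/BED
#' outputs plus a JSON manifest of record counts under `out_dir`.
#' Rerunning on identical inputs reproduces the outputs byte for byte.
#'
#' @param config A `run_config` from [read_run_config()], or a path to
#'   a YAML config file.
#' @param out_dir Output directory (created; existing files
#'   overwritten).
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(is(config, "run_config"))
  p <- config$params
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  loglines <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    loglines <<- c(loglines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(loglines, paste0("FAILED at stage ", name)), log_path)
      writeLines(name, file.path(out_dir, "STALE"))
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  counts <- list()

  note("stage load: reading genome, annotation and peak files")
  inputs <- stage("load", {
    assembly <- read_chrom_sizes(config$genome)
    genes <- read_gff3_genes(config$annotation, assembly = assembly)
    peaks <- lapply(config$peaks, function(e)
      read_narrowpeak(e$path, assembly, e$factor, e$condition, e$replicate))
    list(assembly = assembly, genes = genes, peaks = peaks)
  })
  counts$genes <- length(inputs$genes)
  counts$peak_files <- length(inputs$peaks)
  counts$peaks_raw <- sum(vapply(inputs$peaks, length, integer(1)))

  note(sprintf("stage filter: retaining peaks with -log10(Q) >= %s",
               p$min_qneglog10))
  filtered <- stage("filter", {
    dir.create(file.path(out_dir, "filtered"), showWarnings = FALSE)
    lapply(inputs$peaks, function(ps) {
      out <- filter_by_q(ps, p$min_qneglog10)
      m <- metadata(out)
      write_narrowpeak(out, file.path(out_dir, "filtered",
                                      sprintf("%s_%s_%s.narrowPeak",
                                              m$factor, m$condition,
                                              m$replicate)))
      out
    })
  })
  counts$peaks_filtered <- sum(vapply(filtered, length, integer(1)))

  note(sprintf("stage consensus: min_support = %d", p$min_support))
  consensus <- stage("consensus", {
    dir.create(file.path(out_dir, "consensus"), showWarnings = FALSE)
    key <- vapply(filtered, function(ps)
      paste(metadata(ps)$factor, metadata(ps)$condition, sep = "_"),
      character(1))
    groups <- split(filtered, key)
    out <- lapply(groups, build_consensus, min_support = p$min_support)
    for (nm in names(out))
      consensus_to_bed(out[[nm]],
                       file.path(out_dir, "consensus",
                                 paste0(nm, ".bed")))
    out
  })
  counts$consensus <- lapply(consensus, length)

  note("stage assign: summit-based gene assignment")
  assignments <- stage("assign", {
    dir.create(file.path(out_dir, "assignments"), showWarnings = FALSE)
    out <- lapply(consensus, assign_peaks, genes = inputs$genes,
                  flank = p$flank)
    for (nm in names(out))
      write_tsv_file(out[[nm]],
                     file.path(out_dir, "assignments",
                               paste0(nm, ".tsv")))
    out
  })

  note("stage table: target-gene counts")
  target_table <- stage("table", {
    tt <- target_gene_table(assignments)
    write_tsv_file(tt, file.path(out_dir, "target_table.tsv"))
    tt
  })

  note("stage overlap: co-occupancy matrices per condition")
  overlaps <- stage("overlap", {
    dir.create(file.path(out_dir, "overlap"), showWarnings = FALSE)
    conds <- unique(vapply(consensus, function(x) metadata(x)$condition,
                           character(1)))
    out <- list()
    for (cond in conds) {
      sets <- consensus[vapply(consensus, function(x)
        identical(metadata(x)$condition, cond), logical(1))]
      names(sets) <- vapply(sets, function(x) metadata(x)$factor,
                            character(1))
      if (length(sets) < 2L) next
      pct <- pairwise_overlap_matrix(sets)
      write_overlap_matrix(pct, file.path(out_dir, "overlap",
                                          sprintf("overlap_%s.tsv", cond)))
      multi <- multiway_cooccupancy(sets)
      write_tsv_file(multi, file.path(out_dir, "overlap",
                                      sprintf("multiway_%s.tsv", cond)))
      out[[cond]] <- list(pairwise = pct, multiway = multi)
    }
    out
  })

  profiles <- NULL
  if (length(config$coverage)) {
    note("stage metagene: replicate-merged RPGC profiles")
    profiles <- stage("metagene", {
      dir.create(file.path(out_dir, "metagene"), showWarnings = FALSE)
      key <- vapply(config$coverage, function(e)
        paste(e$factor, e$condition,
              if (identical(e$role, "input")) "input" else "ip",
              sep = "_"), character(1))
      groups <- split(config$coverage, key)
      out <- list()
      mgl <- if (is.null(p$min_gene_length)) p$body_bins
             else p$min_gene_length
      for (nm in names(groups)) {
        tracks <- lapply(groups[[nm]],
                         function(e) read_bedgraph(e$path, inputs$assembly))
        merged <- if (length(tracks) > 1L) merge_tracks(tracks)
                  else tracks[[1L]]
        prof <- mean_profile(metagene_matrix(rpgc_normalize(merged),
                                             inputs$genes,
                                             flank = p$flank,
                                             body_bins = p$body_bins,
                                             flank_bins = p$flank_bins,
                                             min_gene_length = mgl))
        write_profile(prof, file.path(out_dir, "metagene",
                                      sprintf("profile_%s.tsv", nm)))
        out[[nm]] <- prof
      }
      out
    })
  } else {
    note("stage metagene: no coverage files configured; stage skipped")
  }

  manifest <- list(
    tool = "chipsummit",
    version = as.character(utils::packageVersion("chipsummit")),
    config_md5 = unname(tools::md5sum(config$config_path)),
    params = p[!vapply(p, is.null, logical(1))],
    counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (file.exists(file.path(out_dir, "STALE")))
    unlink(file.path(out_dir, "STALE"))
  writeLines(c(loglines, "run complete"), log_path)
  invisible(list(genes = inputs$genes, filtered = filtered,
                 consensus = consensus, assignments = assignments,
                 target_table = target_table, overlaps = overlaps,
                 profiles = profiles))
}

## Deterministic TSV writing: tab-separated, header, no quoting, "NA"
## for missing values.
write_tsv_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}
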