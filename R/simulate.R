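#' Simulation configuration
#'
#' Parameters for the synthetic ChIP-seq experiment generator. The
#' defaults describe a desk-scale experiment with the structure the
#' pipeline assumes: three factors profiled in two conditions with
#' three replicates each; site numbers per factor that differ strongly
#' between factors and increase after the cold condition; high but
#' imperfect replicate reproducibility; strong inter-factor sharing;
#' summits placed preferentially at TSSs with a minor mode slightly
#' downstream of TTSs plus an intergenic remainder; and coverage
#' consisting of Gaussian enrichment bumps on a uniform background.
#'
#' @param seed Integer seed; the same seed yields byte-identical
#'   outputs. Sub-generators use documented offsets of it
#'   (annotation: `seed`; peaks: `seed + 1`; coverage: `seed + 2`).
#' @param n_chroms,chrom_length Number and length (bp) of chromosomes.
#' @param n_genes Total genes, split evenly across chromosomes.
#' @param gene_length_range Min/max gene length (bp).
#' @param gene_spacing Minimum gap between adjacent genes (bp).
#'   Default 2500 (> twice the 1 kb assignment flank, so assignment
#'   windows of neighboring genes never overlap).
#' @param factors,conditions Character vectors of factor and condition
#'   labels.
#' @param n_replicates Replicates per factor per condition.
#' @param n_sites Matrix of latent site counts (`factors` x
#'   `conditions`); `NULL` uses the built-in defaults when labels
#'   match, else 100 each.
#' @param sharing Probability that a site of the first factor is
#'   shared by (copied into) each other factor.
#' @param reproducibility Probability that a site yields a peak in any
#'   given replicate.
#' @param peak_width_range Min/max realized peak width (bp).
#' @param summit_mixture Named probabilities `c(tss=, tts=, intergenic=)`
#'   summing to 1.
#' @param summit_jitter_sd SD (bp) of Gaussian jitter on site summits
#'   around their positional anchor.
#' @param tts_offset Mean downstream displacement (bp) of the TTS
#'   mode.
#' @param q_range Range of -log10 Q for peaks passing the significance
#'   filter.
#' @param frac_subthreshold Fraction of peaks drawn below the filter.
#' @param subthreshold_q_range -log10 Q range for sub-threshold peaks.
#' @param background Uniform background coverage level.
#' @param enrichment_amplitude,enrichment_sd Height and SD (bp) of the
#'   Gaussian coverage bump at each site.
#' @param coverage_resolution Step size (bp) of generated coverage.
#' @param flank Assignment flank (bp); site summits at genes are kept
#'   inside the gene's assignment window.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L, chrom_length = 1e6, n_genes = 200L,
                       gene_length_range = c(1000L, 4000L),
                       gene_spacing = 2500L,
                       factors = c("VEL1", "VIN3", "VRN5"),
                       conditions = c("NV", "6WT0"),
                       n_replicates = 3L,
                       n_sites = NULL,
                       sharing = 0.8,
                       reproducibility = 0.9,
                       peak_width_range = c(200L, 600L),
                       summit_mixture = c(tss = 0.6, tts = 0.25,
                                          intergenic = 0.15),
                       summit_jitter_sd = 200,
                       tts_offset = 150,
                       q_range = c(10, 50),
                       frac_subthreshold = 0.3,
                       subthreshold_q_range = c(2, 10),
                       background = 1.0,
                       enrichment_amplitude = 20,
                       enrichment_sd = 200,
                       coverage_resolution = 10L,
                       flank = 1000L) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              gene_spacing = as.integer(gene_spacing),
              factors = factors, conditions = conditions,
              n_replicates = as.integer(n_replicates),
              n_sites = n_sites, sharing = sharing,
              reproducibility = reproducibility,
              peak_width_range = as.integer(peak_width_range),
              summit_mixture = summit_mixture,
              summit_jitter_sd = summit_jitter_sd,
              tts_offset = tts_offset,
              q_range = q_range, frac_subthreshold = frac_subthreshold,
              subthreshold_q_range = subthreshold_q_range,
              background = background,
              enrichment_amplitude = enrichment_amplitude,
              enrichment_sd = enrichment_sd,
              coverage_resolution = as.integer(coverage_resolution),
              flank = as.integer(flank))
  if (is.null(cfg$n_sites)) cfg$n_sites <- default_n_sites(factors, conditions)
  cfg$n_sites <- as.matrix(cfg$n_sites)
  if (!identical(dim(cfg$n_sites), c(length(factors), length(conditions))))
    stop("'n_sites' must be a factors x conditions matrix")
  dimnames(cfg$n_sites) <- list(factors, conditions)
  probs <- c(cfg$sharing, cfg$reproducibility, cfg$frac_subthreshold,
             cfg$summit_mixture)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (abs(sum(cfg$summit_mixture) - 1) > 1e-9)
    stop("'summit_mixture' must sum to 1")
  if (is.null(names(cfg$summit_mixture)) ||
      !setequal(names(cfg$summit_mixture), c("tss", "tts", "intergenic")))
    stop("'summit_mixture' needs names tss, tts, intergenic")
  for (f in c("gene_length_range", "peak_width_range", "q_range",
              "subthreshold_q_range"))
    if (length(cfg[[f]]) != 2L || any(cfg[[f]] <= 0) || diff(cfg[[f]]) < 0)
      stop("'", f, "' must be a positive (min, max) pair")
  if (cfg$background < 0 || cfg$enrichment_amplitude < 0 ||
      cfg$enrichment_sd <= 0)
    stop("coverage parameters must be non-negative (sd positive)")
  structure(cfg, class = "sim_config")
}

## Site counts mirroring the study's structure at desk scale: one
## dominant factor, the two others much sparser and strongly induced by
## the cold condition.
default_n_sites <- function(factors, conditions) {
  canonical <- matrix(c(300, 280,   # VEL1: NV, cold
                        30, 150,    # VIN3
                        120, 220),  # VRN5
                      nrow = 3L, byrow = TRUE,
                      dimnames = list(c("VEL1", "VIN3", "VRN5"),
                                      c("NV", "6WT0")))
  m <- matrix(100L, length(factors), length(conditions),
              dimnames = list(factors, conditions))
  hit_f <- intersect(factors, rownames(canonical))
  hit_c <- intersect(conditions, colnames(canonical))
  m[hit_f, hit_c] <- canonical[hit_f, hit_c]
  m
}

#' Simulate a genome and gene annotation
#'
#' Places `n_genes` non-overlapping genes (lengths uniform within the
#' configured range, random strands) on the configured chromosomes,
#' with at least `gene_spacing` bp between neighbors and random slack
#' distributed between them. Deterministic for a given seed.
#'
#' @param cfg A [sim_config()].
#' @return A list with `assembly` (`Seqinfo`) and `genes` (`GRanges`
#'   with `gene_id`).
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(is(cfg, "sim_config"))
  set.seed(cfg$seed)
  assembly <- genome_assembly(paste0("chr", seq_len(cfg$n_chroms)),
                              rep(cfg$chrom_length, cfg$n_chroms))
  per_chrom <- diff(round(seq(0, cfg$n_genes,
                              length.out = cfg$n_chroms + 1L)))
  genes <- list()
  gid <- 0L
  for (ci in seq_len(cfg$n_chroms)) {
    k <- per_chrom[ci]
    if (k == 0L) next
    len <- sample(seq(cfg$gene_length_range[1L], cfg$gene_length_range[2L]),
                  k, replace = TRUE)
    slack <- cfg$chrom_length - sum(len) - (k + 1L) * cfg$gene_spacing
    if (slack < 0)
      stop("cannot place ", k, " genes of up to ",
           cfg$gene_length_range[2L], " bp with ", cfg$gene_spacing,
           " bp spacing on a ", cfg$chrom_length,
           " bp chromosome; reduce n_genes or gene_spacing")
    extra <- as.vector(rmultinom(1L, slack, rep(1, k + 1L)))
    gaps <- cfg$gene_spacing + extra
    starts <- cumsum(gaps[seq_len(k)] + c(0L, len[-k]))  # gap before each gene
    gr <- GRanges(paste0("chr", ci),
                  IRanges(start = starts + 1L, width = len),
                  strand = sample(c("+", "-"), k, replace = TRUE),
                  seqinfo = assembly)
    gr$gene_id <- sprintf("SIMG%04d", gid + seq_len(k))
    gid <- gid + k
    genes[[ci]] <- gr
  }
  genes <- bind_assembly(sort(do.call(c, genes), ignore.strand = TRUE),
                         assembly, "gene")
  list(assembly = assembly, genes = genes)
}

#' Simulate replicate peak sets with planted truth
#'
#' Draws latent binding sites for every factor and condition using the
#' configured positional mixture (TSS-anchored, slightly-downstream-of-
#' TTS, or intergenic; gene-anchored summits are clamped into the
#' gene's assignment window so planted assignments are unambiguous).
#' Sharing: each site of the first factor is copied into every other
#' factor with probability `sharing` (small positional jitter); the
#' remaining quota of each factor is filled with its own sites. Each
#' replicate then realizes each site independently with probability
#' `reproducibility`, drawing peak width, summit offset and
#' significance scores; a `frac_subthreshold` fraction of realized
#' peaks receives a sub-threshold Q so that significance filtering has
#' something to remove.
#'
#' @param cfg A [sim_config()].
#' @param annotation Result of [simulate_annotation()] (regenerated
#'   from `cfg` when omitted).
#' @return A list with `peak_sets` (nested list:
#'   `[[condition]][[factor]][[replicate]]`, each a peak `GRanges`)
#'   and `truth` (a `data.frame` of planted sites: `site_id`, `factor`,
#'   `condition`, `chrom`, `summit` (1-based), `mode`, `gene_id`,
#'   `shared_from`).
#' @export
simulate_peaks <- function(cfg, annotation = NULL) {
  stopifnot(is(cfg, "sim_config"))
  if (is.null(annotation)) annotation <- simulate_annotation(cfg)
  set.seed(cfg$seed + 1L)
  assembly <- annotation$assembly
  genes <- annotation$genes
  windows <- assignment_window(genes, cfg$flank)
  chrom_len <- GenomeInfoDb::seqlengths(assembly)
  gpos <- tss_tts(genes)
  minus <- gpos$strand == "-"

  draw_sites <- function(n, factor, condition) {
    if (n == 0L)
      return(data.frame(site_id = character(), factor = character(),
                        condition = character(), chrom = character(),
                        summit = integer(), mode = character(),
                        gene_id = character(), shared_from = character(),
                        stringsAsFactors = FALSE))
    mode <- sample(c("tss", "tts", "intergenic"), n, replace = TRUE,
                   prob = cfg$summit_mixture[c("tss", "tts", "intergenic")])
    g <- sample.int(length(genes), n, replace = TRUE)
    jit <- round(rnorm(n, 0, cfg$summit_jitter_sd))
    dir <- ifelse(minus[g], -1L, 1L)
    summit <- ifelse(mode == "tss", gpos$tss[g] + jit,
                     gpos$tts[g] + dir * round(cfg$tts_offset) + jit)
    ## clamp gene-anchored summits into the assignment window
    summit <- pmax(start(windows)[g], pmin(end(windows)[g], summit))
    chrom <- gpos$chrom[g]
    gene_id <- gpos$gene_id[g]
    inter <- mode == "intergenic"
    if (any(inter)) {
      ic <- sample(names(chrom_len), sum(inter), replace = TRUE)
      ip <- vapply(ic, function(ch) {
        for (try in 1:200) {
          p <- sample.int(chrom_len[[ch]], 1L)
          hit <- which(as.character(seqnames(windows)) == ch &
                       start(windows) <= p & end(windows) >= p)
          if (length(hit) == 0L) return(p)
        }
        stop("could not place an intergenic site outside all gene windows; ",
             "lower gene density")
      }, integer(1))
      chrom[inter] <- ic
      summit[inter] <- ip
      gene_id[inter] <- NA_character_
    }
    data.frame(site_id = sprintf("site_%s_%s_%04d", factor, condition,
                                 seq_len(n)),
               factor = factor, condition = condition,
               chrom = chrom, summit = as.integer(summit), mode = mode,
               gene_id = gene_id, shared_from = NA_character_,
               stringsAsFactors = FALSE)
  }

  realize <- function(sites, factor, condition, rep_k) {
    hit <- runif(nrow(sites)) < cfg$reproducibility
    s <- sites[hit, , drop = FALSE]
    n <- nrow(s)
    wr <- cfg$peak_width_range
    width <- if (n) sample(seq(wr[1L], wr[2L]), n, replace = TRUE)
             else integer(0)
    offset <- if (n) vapply(width, function(w) sample.int(w, 1L) - 1L,
                            integer(1)) else integer(0)
    start1 <- s$summit - offset               # 1-based start
    ## clip to chromosome, preserving the summit inside the peak
    start1 <- pmax(1L, start1)
    end1 <- pmin(chrom_len[s$chrom], start1 + width - 1L)
    start1 <- pmax(1L, pmin(start1, s$summit))
    end1 <- pmax(end1, s$summit)
    sub <- runif(n) < cfg$frac_subthreshold
    q <- round(ifelse(sub,
                      runif(n, cfg$subthreshold_q_range[1L],
                            cfg$subthreshold_q_range[2L]),
                      runif(n, cfg$q_range[1L], cfg$q_range[2L])), 3)
    gr <- GRanges(s$chrom, IRanges(start1, end1), seqinfo = assembly)
    gr$name <- sprintf("%s_%s_rep%d_%s", factor, condition, rep_k, s$site_id)
    gr$score <- pmin(1000L, as.integer(round(q * 10)))
    gr$signalValue <- round(runif(n, 2, 30), 3)
    gr$pValue <- round(q + runif(n, 0, 5), 3)
    gr$qValue <- q
    gr$peak <- as.integer(s$summit - start1)
    gr <- sort(gr, ignore.strand = TRUE)
    metadata(gr) <- list(factor = factor, condition = condition,
                         replicate = sprintf("rep%d", rep_k))
    gr
  }

  peak_sets <- list()
  truth <- list()
  for (condition in cfg$conditions) {
    peak_sets[[condition]] <- list()
    base_sites <- NULL
    for (fi in seq_along(cfg$factors)) {
      factor <- cfg$factors[fi]
      n_target <- cfg$n_sites[factor, condition]
      if (fi == 1L) {
        sites <- draw_sites(n_target, factor, condition)
        base_sites <- sites
      } else {
        take <- runif(nrow(base_sites)) < cfg$sharing
        shared <- base_sites[take, , drop = FALSE]
        if (nrow(shared)) {
          shared$shared_from <- shared$site_id
          shared$factor <- factor
          jit <- round(rnorm(nrow(shared), 0, 50))
          shared$summit <- as.integer(
            pmax(1L, pmin(chrom_len[shared$chrom], shared$summit + jit)))
        }
        n_own <- max(0L, n_target - nrow(shared))
        own <- draw_sites(n_own, factor, condition)
        sites <- rbind(shared, own)
        sites$site_id <- sprintf("site_%s_%s_%04d", factor, condition,
                                 seq_len(nrow(sites)))
      }
      truth[[paste(condition, factor)]] <- sites
      peak_sets[[condition]][[factor]] <-
        lapply(seq_len(cfg$n_replicates),
               function(k) realize(sites, factor, condition, k))
      names(peak_sets[[condition]][[factor]]) <-
        sprintf("rep%d", seq_len(cfg$n_replicates))
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(peak_sets = peak_sets, truth = truth)
}

#' Simulate coverage tracks
#'
#' Builds one coverage track per factor/condition — a uniform
#' background plus a Gaussian bump (configured amplitude and SD) at
#' every planted site summit, evaluated on a regular grid of
#' `coverage_resolution`-bp steps — and a matched flat input-control
#' track per condition.
#'
#' @param cfg A [sim_config()].
#' @param truth Planted-site table from [simulate_peaks()].
#' @param assembly The simulated `Seqinfo`.
#' @return A named list of `RleList` tracks: `<factor>_<condition>`
#'   and `input_<condition>`.
#' @export
simulate_coverage <- function(cfg, truth, assembly) {
  stopifnot(is(cfg, "sim_config"))
  res <- cfg$coverage_resolution
  sd <- cfg$enrichment_sd
  amp <- cfg$enrichment_amplitude
  chrom_len <- GenomeInfoDb::seqlengths(assembly)
  half_span <- ceiling(5 * sd / res)

  bump_track <- function(sites) {
    out <- lapply(names(chrom_len), function(chrom) {
      len <- chrom_len[[chrom]]
      n_bins <- ceiling(len / res)
      v <- rep(cfg$background, n_bins)
      for (s in sites$summit[sites$chrom == chrom]) {
        b <- floor((s - 1) / res) + 1L
        lo <- max(1L, b - half_span); hi <- min(n_bins, b + half_span)
        mids <- (seq(lo, hi) - 0.5) * res
        v[lo:hi] <- v[lo:hi] + amp * exp(-(mids - s)^2 / (2 * sd^2))
      }
      v <- round(v, 6)
      widths <- rep(res, n_bins)
      widths[n_bins] <- len - (n_bins - 1L) * res
      Rle(rep(v, widths))
    })
    out <- as(setNames(out, names(chrom_len)), "RleList")
    metadata(out) <- list(normalization = "raw")
    out
  }

  tracks <- list()
  for (condition in unique(truth$condition)) {
    for (factor in unique(truth$factor[truth$condition == condition])) {
      sel <- truth$factor == factor & truth$condition == condition
      tracks[[paste(factor, condition, sep = "_")]] <-
        bump_track(truth[sel, , drop = FALSE])
    }
    flat <- as(lapply(chrom_len, function(l) Rle(cfg$background, l)),
               "RleList")
    metadata(flat) <- list(normalization = "raw")
    tracks[[paste0("input_", condition)]] <- flat
  }
  tracks
}

#' Simulate and write a complete experiment fixture
#'
#' Runs annotation, peak and coverage simulation in a fixed order and
#' writes a self-contained fixture directory: `genome.tsv`,
#' `genes.gff3`, `peaks/<factor>_<condition>_rep<k>.narrowPeak`,
#' `coverage/<sample>.bedgraph`, `truth.tsv` and `sim_config.yaml`.
#' Running twice with the same config produces byte-identical trees.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param coverage Also generate coverage tracks (slowest part).
#' @return Invisibly, a list with the in-memory `assembly`, `genes`,
#'   `peak_sets`, `truth` and (optionally) `tracks`.
#' @export
simulate_experiment <- function(cfg, dir, coverage = TRUE) {
  stopifnot(is(cfg, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  ann <- simulate_annotation(cfg)
  sim <- simulate_peaks(cfg, ann)
  write_chrom_sizes(ann$assembly, file.path(dir, "genome.tsv"))
  write_gff3_genes(ann$genes, file.path(dir, "genes.gff3"))
  for (condition in names(sim$peak_sets))
    for (factor in names(sim$peak_sets[[condition]])) {
      reps <- sim$peak_sets[[condition]][[factor]]
      for (k in seq_along(reps))
        write_narrowpeak(reps[[k]],
                         file.path(dir, "peaks",
                                   sprintf("%s_%s_rep%d.narrowPeak",
                                           factor, condition, k)))
    }
  write_tsv_file(sim$truth, file.path(dir, "truth.tsv"))
  writeLines(yaml::as.yaml(unclass(cfg)), file.path(dir, "sim_config.yaml"))
  tracks <- NULL
  if (coverage) {
    dir.create(file.path(dir, "coverage"), showWarnings = FALSE)
    tracks <- simulate_coverage(cfg, sim$truth, ann$assembly)
    for (nm in names(tracks))
      write_bedgraph(tracks[[nm]],
                     file.path(dir, "coverage", paste0(nm, ".bedgraph")))
  }
  invisible(list(assembly = ann$assembly, genes = ann$genes,
                 peak_sets = sim$peak_sets, truth = sim$truth,
                 tracks = tracks))
}
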