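small_cfg <- function(...) {
  sim_config(seed = 5, n_chroms = 1, chrom_length = 3e5, n_genes = 30,
             coverage_resolution = 20, ...)
}

test_that("sim_config validates its parameters", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(sharing = 1.2), "probabilities")
  expect_error(sim_config(summit_mixture = c(tss = 0.5, tts = 0.5,
                                             intergenic = 0.5)), "sum to 1")
  expect_error(sim_config(peak_width_range = c(600, 200)), "pair")
  expect_error(sim_config(n_sites = matrix(1, 2, 2)), "factors x conditions")
})

test_that("the same seed yields byte-identical fixture directories", {
  cfg <- small_cfg()
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  simulate_experiment(cfg, d1)
  simulate_experiment(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  # a different seed changes the peaks
  d3 <- file.path(tempfile(), "c")
  simulate_experiment(sim_config(seed = 6, n_chroms = 1,
                                 chrom_length = 3e5, n_genes = 30),
                      d3, coverage = FALSE)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "truth.tsv"))),
    unname(tools::md5sum(file.path(d3, "truth.tsv")))))
})

test_that("simulated genes respect spacing and length bounds", {
  cfg <- sim_config(seed = 8, n_chroms = 2, chrom_length = 5e5,
                    n_genes = 100, gene_length_range = c(800L, 2500L),
                    gene_spacing = 2100L)
  ann <- simulate_annotation(cfg)
  expect_equal(length(ann$genes), 100L)
  w <- width(ann$genes)
  expect_true(all(w >= 800L & w <= 2500L))
  for (chrom in c("chr1", "chr2")) {
    g <- ann$genes[seqnames(ann$genes) == chrom]
    gaps <- start(g)[-1] - end(g)[-length(g)] - 1L
    expect_true(all(gaps >= 2100L))
  }
  # infeasible density errors out with advice
  expect_error(simulate_annotation(
    sim_config(n_genes = 100, n_chroms = 1, chrom_length = 1e5)),
    "reduce")
})

test_that("reproducibility bounds behave at the extremes", {
  cfg <- small_cfg(reproducibility = 0,
                   factors = "A", conditions = "NV",
                   n_sites = matrix(50L, 1, 1))
  sim <- simulate_peaks(cfg)
  expect_true(all(vapply(sim$peak_sets$NV$A, length, integer(1)) == 0L))

  cfg1 <- small_cfg(reproducibility = 1, sharing = 1,
                    factors = c("A", "B"), conditions = "NV",
                    n_sites = matrix(50L, 2, 1))
  sim1 <- simulate_peaks(cfg1)
  expect_true(all(vapply(sim1$peak_sets$NV$A, length, integer(1)) == 50L))
  # full sharing: every B site is a jittered copy of an A site
  truth_b <- sim1$truth[sim1$truth$factor == "B", ]
  expect_true(all(!is.na(truth_b$shared_from)))
})

test_that("sub-threshold fraction survives the Q filter as expected", {
  cfg <- sim_config(seed = 17, n_chroms = 1, chrom_length = 5e6,
                    n_genes = 50, factors = "A", conditions = "NV",
                    n_sites = matrix(400L, 1, 1), n_replicates = 1,
                    reproducibility = 1, frac_subthreshold = 0.3)
  sim <- simulate_peaks(cfg)
  ps <- sim$peak_sets$NV$A[[1]]
  kept <- length(filter_by_q(ps, 10))
  p <- 0.7
  se <- sqrt(p * (1 - p) * 400)
  expect_lt(abs(kept - p * 400), 3 * se)
})

test_that("planted summits respect the positional mixture", {
  cfg <- small_cfg(factors = "A", conditions = "NV",
                   n_sites = matrix(200L, 1, 1),
                   summit_mixture = c(tss = 1, tts = 0, intergenic = 0),
                   summit_jitter_sd = 100)
  ann <- simulate_annotation(cfg)
  sim <- simulate_peaks(cfg, ann)
  tt <- tss_tts(ann$genes)
  idx <- match(sim$truth$gene_id, tt$gene_id)
  # all summits within the gene's window, anchored near the TSS
  expect_true(all(abs(sim$truth$summit - tt$tss[idx]) <= 1000))
  expect_lt(median(abs(sim$truth$summit - tt$tss[idx])), 300)
})

test_that("coverage bumps integrate to amplitude * sd * sqrt(2*pi)", {
  cfg <- sim_config(seed = 19, n_chroms = 1, chrom_length = 1e5,
                    n_genes = 5, enrichment_amplitude = 10,
                    enrichment_sd = 150, background = 0.5,
                    coverage_resolution = 10)
  truth <- data.frame(factor = "A", condition = "NV", chrom = "chr1",
                      summit = 50000L, stringsAsFactors = FALSE)
  asm <- genome_assembly("chr1", 1e5)
  tr <- simulate_coverage(cfg, truth, asm)
  t <- tr$A_NV
  total <- sum(as.numeric(runValue(t$chr1)) * runLength(t$chr1))
  bump_mass <- total - 0.5 * 1e5
  expect_equal(bump_mass, 10 * 150 * sqrt(2 * pi), tolerance = 0.01)
  # track maximum sits at the summit bin
  expect_equal(as.integer(which.max(as.numeric(t$chr1))), 50000L,
               tolerance = 10)
  # amplitude 0 -> flat background
  cfg0 <- sim_config(seed = 19, n_chroms = 1, chrom_length = 1e5,
                     n_genes = 5, enrichment_amplitude = 0,
                     background = 0.5)
  t0 <- simulate_coverage(cfg0, truth, asm)$A_NV
  expect_equal(as.numeric(runValue(t0$chr1)), 0.5)
  # matched input carries background only
  expect_equal(as.numeric(runValue(tr$input_NV$chr1)), 0.5)
})

test_that("gene length sampling covers the configured range", {
  cfg <- sim_config(seed = 23, n_chroms = 4, chrom_length = 3e6,
                    n_genes = 2000, gene_length_range = c(500L, 1500L),
                    gene_spacing = 300L)
  ann <- simulate_annotation(cfg)
  w <- width(ann$genes)
  expect_true(all(w >= 500L & w <= 1500L))
  # roughly uniform: quartiles near the theoretical ones
  expect_lt(abs(mean(w) - 1000), 25)
})
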