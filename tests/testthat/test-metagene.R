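test_that("read_bedgraph fills uncovered bases with zero", {
  asm <- genome_assembly("chr1", 1000L)
  path <- tempfile(fileext = ".bedgraph")
  writeLines("chr1\t0\t500\t2.0", path)
  t <- read_bedgraph(path, asm)
  expect_equal(length(t$chr1), 1000L)
  expect_equal(as.numeric(t$chr1[1:500]), rep(2, 500))
  expect_equal(as.numeric(t$chr1[501:1000]), rep(0, 500))
  expect_identical(metadata(t)$normalization, "raw")
  # empty file -> all-zero track
  empty <- tempfile(); writeLines(character(0), empty)
  t0 <- read_bedgraph(empty, asm)
  expect_equal(sum(as.numeric(t0$chr1)), 0)
})

test_that("overlapping bedGraph steps are a format error", {
  asm <- genome_assembly("chr1", 1000L)
  path <- tempfile()
  writeLines(c("chr1\t0\t500\t1.0", "chr1\t400\t600\t2.0"), path)
  expect_error(read_bedgraph(path, asm), "overlapping steps")
})

test_that("bedGraph write/read round trip is lossless", {
  asm <- toy_assembly(5000L)
  set.seed(701)
  steps <- rand_intervals(40, chrom_len = 4500L, max_width = 200L)
  steps$value <- round(runif(40, 0.1, 9), 6)
  ## drop overlaps to get a valid track
  gr <- df_to_gr(steps)
  keep <- countOverlaps(gr, gr) == 1L
  steps <- steps[keep, ]
  t <- mk_track(steps, asm)
  p1 <- tempfile(); p2 <- tempfile()
  write_bedgraph(t, p1)
  back <- read_bedgraph(p1, asm)
  expect_equal(lapply(back, as.numeric), lapply(t, as.numeric))
  write_bedgraph(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("rpgc normalization fixes the genome-wide mean at one", {
  asm <- genome_assembly("chr1", 1000L)
  # uniform 0.5 over a fully covered genome -> uniform 1.0
  t <- mk_track(data.frame(chrom = "chr1", start = 1, end = 1000,
                           value = 0.5), asm)
  n <- rpgc_normalize(t)
  expect_equal(as.numeric(runValue(n$chr1)), 1.0)
  expect_identical(metadata(n)$normalization, "RPGC")
  # value 2 over half the genome: sum = G, already mean 1 -> unchanged
  t2 <- mk_track(data.frame(chrom = "chr1", start = 1, end = 500,
                            value = 2), asm)
  n2 <- rpgc_normalize(t2)
  expect_equal(as.numeric(n2$chr1[1:500]), rep(2, 500))
  # all-zero track is an error
  z <- mk_track(data.frame(chrom = "chr1", start = 1, end = 10,
                           value = 0), asm)
  expect_error(rpgc_normalize(z), "all-zero")
})

test_that("rpgc weighted mean is 1 within 1e-9 on random tracks", {
  set.seed(702)
  asm <- toy_assembly(10000L)
  for (rep in 1:5) {
    steps <- rand_intervals(50, chrom_len = 9000L, max_width = 150L)
    steps <- steps[countOverlaps(df_to_gr(steps), df_to_gr(steps)) == 1L, ]
    steps$value <- runif(nrow(steps), 0, 20)
    n <- rpgc_normalize(mk_track(steps, asm))
    total <- sum(vapply(n, function(r)
      sum(as.numeric(runValue(r)) * runLength(r)), numeric(1)))
    expect_equal(total / assembly_length(asm), 1, tolerance = 1e-9)
  }
  # explicit effective genome size scales accordingly
  t <- mk_track(data.frame(chrom = "chr1", start = 1, end = 100,
                           value = 4), asm)
  n <- rpgc_normalize(t, effective_genome_size = 100)
  expect_equal(as.numeric(n$chr1[1]), 1)
})

test_that("metagene bins agree with the per-base oracle", {
  set.seed(703)
  asm <- genome_assembly("chr1", 10000L)
  steps <- rand_intervals(60, chroms = "chr1", chrom_len = 9500L,
                          max_width = 120L)
  steps <- steps[countOverlaps(df_to_gr(steps), df_to_gr(steps)) == 1L, ]
  steps$value <- runif(nrow(steps), 0, 10)
  t <- mk_track(steps, asm)
  genes <- mk_genes(c(2001, 5301, 9501), c(3500, 5800, 9900),
                    strand = c("+", "-", "+"))
  mat <- metagene_matrix(t, genes, flank = 1000, body_bins = 50,
                         flank_bins = 10)
  cov_vec <- as.numeric(t$chr1)
  for (g in seq_along(genes)) {
    want <- oracle_metagene_row(cov_vec, start(genes)[g], end(genes)[g],
                                as.character(strand(genes))[g],
                                1000, 50, 10)
    expect_equal(unname(mat[g, ]), want, tolerance = 1e-9)
  }
  # the last gene's downstream flank leaves the chromosome -> NA bins
  expect_true(anyNA(mat[3, ]))
  expect_false(anyNA(mat[1, ]))
})

test_that("uniform coverage gives flat unit profiles on random genes", {
  set.seed(704)
  asm <- toy_assembly(50000L, 1L)
  t <- mk_track(data.frame(chrom = "chr1", start = 1, end = 50000,
                           value = 3), asm)
  n <- rpgc_normalize(t)
  gdf <- rand_intervals(10, chroms = "chr1", chrom_len = 40000L,
                        max_width = 4000L)
  genes <- mk_genes(gdf$start + 2000L, gdf$end + 2500L,
                    strand = sample(c("+", "-"), 10, replace = TRUE))
  prof <- mean_profile(metagene_matrix(n, genes))
  expect_equal(prof$values, rep(1, 140), tolerance = 1e-9)
  expect_equal(prof$n_genes, 10L)
})

test_that("mirrored minus-strand coverage yields identical rows", {
  # a track and its mirror about the gene midpoint, profiled on
  # opposite strands, must give the same row
  asm <- genome_assembly("chr1", 20000L)
  g_plus <- mk_genes(8001, 12000, strand = "+")
  g_minus <- mk_genes(8001, 12000, strand = "-")
  set.seed(705)
  steps <- rand_intervals(40, chroms = "chr1", chrom_len = 19000L,
                          max_width = 150L)
  steps <- steps[countOverlaps(df_to_gr(steps), df_to_gr(steps)) == 1L, ]
  steps$value <- runif(nrow(steps), 0, 5)
  t <- mk_track(steps, asm)
  # mirror about the midpoint of [8001,12000]: pos -> 20001 - pos
  mirrored <- data.frame(chrom = "chr1",
                         start = 20001 - steps$end,
                         end = 20001 - steps$start,
                         value = steps$value)
  tm <- mk_track(mirrored, asm)
  row_plus <- metagene_matrix(t, g_plus)[1, ]
  row_minus <- metagene_matrix(tm, g_minus)[1, ]
  expect_equal(unname(row_plus), unname(row_minus), tolerance = 1e-12)
})

test_that("metagene profiles are translation invariant", {
  asm1 <- genome_assembly("chr1", 30000L)
  set.seed(706)
  steps <- rand_intervals(30, chroms = "chr1", chrom_len = 8000L,
                          max_width = 100L)
  steps <- steps[countOverlaps(df_to_gr(steps), df_to_gr(steps)) == 1L, ]
  steps$value <- runif(nrow(steps), 0, 5)
  genes <- mk_genes(3001, 6000, strand = "+")
  shift_bp <- 10000L
  shifted <- data.frame(chrom = "chr1", start = steps$start + shift_bp,
                        end = steps$end + shift_bp, value = steps$value)
  m1 <- metagene_matrix(mk_track(steps, asm1), genes)
  m2 <- metagene_matrix(mk_track(shifted, asm1),
                        GenomicRanges::shift(genes, shift_bp))
  expect_equal(unname(m1), unname(m2))
})

test_that("replicate merging sums tracks and cancels out in RPGC", {
  asm <- toy_assembly(2000L)
  steps <- data.frame(chrom = c("chr1", "chr2"), start = c(101, 501),
                      end = c(300, 900), value = c(2, 5))
  t <- mk_track(steps, asm)
  merged <- merge_tracks(list(t, t, t))
  expect_equal(as.numeric(merged$chr1[150]), 6)
  p1 <- mean_profile(metagene_matrix(rpgc_normalize(t),
                                     mk_genes(501, 1500, chrom = "chr1"),
                                     body_bins = 20, flank_bins = 5,
                                     flank = 500))
  p3 <- mean_profile(metagene_matrix(rpgc_normalize(merged),
                                     mk_genes(501, 1500, chrom = "chr1"),
                                     body_bins = 20, flank_bins = 5,
                                     flank = 500))
  expect_equal(p1$values, p3$values, tolerance = 1e-12)
})

test_that("short genes are excluded with a message", {
  asm <- genome_assembly("chr1", 10000L)
  t <- mk_track(data.frame(chrom = "chr1", start = 1, end = 10000,
                           value = 1), asm)
  genes <- mk_genes(c(2001, 5001), c(2050, 8000))  # 50 bp and 3000 bp
  expect_message(mat <- metagene_matrix(t, genes, body_bins = 100),
                 "excluded")
  expect_equal(nrow(mat), 1L)
  expect_error(suppressMessages(metagene_matrix(t, genes[1],
                                                body_bins = 100)),
               "no genes")
})

test_that("planted TSS enrichment peaks at the TSS boundary bin", {
  cfg <- sim_config(seed = 31, n_chroms = 1, chrom_length = 5e5,
                    n_genes = 60, factors = "VEL1", conditions = "NV",
                    n_sites = matrix(120L, 1, 1),
                    summit_mixture = c(tss = 1, tts = 0, intergenic = 0),
                    summit_jitter_sd = 200, enrichment_sd = 200)
  ann <- simulate_annotation(cfg)
  sim <- simulate_peaks(cfg, ann)
  tracks <- simulate_coverage(cfg, sim$truth, ann$assembly)
  prof <- mean_profile(metagene_matrix(rpgc_normalize(tracks$VEL1_NV),
                                       ann$genes))
  # TSS boundary sits between bins 20 (last upstream) and 21 (first body)
  expect_lte(abs(which.max(prof$values) - 20.5), 2.5)
  # the input control stays flat at 1 after RPGC
  ctrl <- mean_profile(metagene_matrix(rpgc_normalize(tracks$input_NV),
                                       ann$genes))
  expect_equal(ctrl$values, rep(1, 140), tolerance = 1e-9)
})

test_that("mean_profile averages rows and tracks NA support", {
  mat <- rbind(c(0, 2, NA), c(2, 2, NA))
  attr(mat, "role") <- c("upstream", "body", "downstream")
  p <- mean_profile(mat)
  expect_equal(p$values, c(1, 2, NA))
  expect_equal(p$n, c(2L, 2L, 0L))
  df <- as.data.frame(p)
  expect_equal(df$mean, c(1, 2, NA))
})
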