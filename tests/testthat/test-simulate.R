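test_that("every generator is byte-identical for a fixed seed", {
  cfg <- sim_config(9)
  loc1 <- simulate_locus(cfg)
  loc2 <- simulate_locus(cfg)
  expect_identical(loc1$transcripts, loc2$transcripts)
  expect_identical(loc1$annotation$exons, loc2$annotation$exons)
  r1 <- simulate_drs_reads(cfg, loc1, 300, 1)
  r2 <- simulate_drs_reads(cfg, loc1, 300, 1)
  expect_identical(r1, r2)
  n1 <- simulate_ngs_coverage(sim_config(9, ngs_depth = 20), loc1)
  n2 <- simulate_ngs_coverage(sim_config(9, ngs_depth = 20), loc1)
  expect_identical(n1$track$counts, n2$track$counts)
  cfg_img <- sim_config(9, n_cells = 9L)
  f1 <- simulate_fish_images(cfg_img, 1)
  f2 <- simulate_fish_images(cfg_img, 1)
  expect_identical(f1, f2)
  p1 <- simulate_presence_table(cfg, 40L)
  p2 <- simulate_presence_table(cfg, 40L)
  expect_identical(p1, p2)
  # a different seed changes the stochastic outputs
  expect_false(identical(r1$blocks,
                         simulate_drs_reads(sim_config(10), loc1, 300, 1)$blocks))
})

test_that("the synthetic locus satisfies its structural contract", {
  cfg <- sim_config(1)
  loc <- simulate_locus(cfg)
  ann <- loc$annotation
  expect_equal(nrow(ann$exons), 12L)
  expect_equal(ann$exons$exon, c(-1L, 1:11))
  term <- ann$exons[ann$exons$exon == 11L, ]
  expect_true(ann$pas_position >= term$start && ann$pas_position < term$end)
  expect_equal(ann$strand, "-")
  # alternative promoter upstream (higher coordinates) of the canonical one
  pk <- ann$cage_peaks
  expect_gt(min(pk$summit[pk$promoter_id == "alternative"]),
            max(pk$summit[pk$promoter_id == "canonical"]))
  # initiation regions exist and are disjoint (validated on construction)
  regs <- initiation_regions(ann)
  expect_equal(nrow(regs), 6L)
  # transcript lengths are consistent with the exon model
  expect_equal(nchar(loc$transcripts[["canonical_fl"]]),
               sum(ann$exons$end - ann$exons$start))
  expect_equal(nchar(loc$transcripts[["longFOXP3_fl"]]) -
                 nchar(loc$transcripts[["longFOXP3_d2"]]), 105L)
  # mirrored template: the reflected annotation mirrors every exon
  m <- mirror_locus(ann)
  expect_equal(m$strand, "+")
  expect_equal(sort(m$exons$end - m$exons$start),
               sort(ann$exons$end - ann$exons$start))
  expect_identical(mirror_locus(m)$exons, ann$exons)
})

test_that("jitter-free generation puts every surviving 5' end on a summit", {
  cfg <- sim_config(21, decay_fraction = 0, tss_jitter_sd = 0,
                    tech_loss_range = c(0L, 0L))
  loc <- simulate_locus(cfg)
  reads <- simulate_drs_reads(cfg, loc, 400, 1)
  five <- read_five_prime(reads)
  expect_true(all(five %in% loc$annotation$cage_peaks$summit))
})

test_that("single-species coverage is uniform over the transcript interior", {
  cfg <- sim_config(33, nonadenylated_ratio = 0,
                    mixture = c(canonical_fl = 1, canonical_d2 = 0,
                                novel_canonical = 0, longFOXP3_fl = 0,
                                longFOXP3_d2 = 0, longFOXP3_minor = 0,
                                short_upstream = 0),
                    ngs_depth = 400)
  loc <- simulate_locus(cfg)
  ngs <- simulate_ngs_coverage(cfg, loc)
  # deep interior of the terminal exon, away from fragment-length ramps
  ex11 <- loc$annotation$exons[loc$annotation$exons$exon == 11L, ]
  idx <- (ex11$start + 200):(ex11$end - 200) - ngs$track$start + 1L
  v <- ngs$track$counts[idx]
  expect_lt(stats::sd(v) / mean(v), 0.10)
  expect_equal(mean(v), 400, tolerance = 0.1)
})

test_that("a null non-adenylated world yields an estimate near zero", {
  cfg <- sim_config(35, decay_fraction = 0, nonadenylated_ratio = 0,
    mixture = c(canonical_fl = 2.7, canonical_d2 = 3.3, novel_canonical = 1,
                longFOXP3_fl = 0.555, longFOXP3_d2 = 0.84,
                longFOXP3_minor = 0.105, short_upstream = 0.04))
  loc <- simulate_locus(cfg)
  reads <- simulate_drs_reads(cfg, loc, 3000, 1)
  cl <- classify_reads(reads, loc$annotation)
  ngs <- simulate_ngs_coverage(cfg, loc)
  dm <- dual_modality_report(cl, loc$annotation, ngs$track,
                             coverage_regions = synthetic_anchor_regions())
  expect_lt(abs(dm$R), 0.15)
})

test_that("image generation respects positivity and spot bookkeeping", {
  cfg <- sim_config(51, n_cells = 12L, upa_positive_prob = 0)
  f <- simulate_fish_images(cfg, 1)[[1]]
  expect_equal(sum(f$cell_truth$n_upa), 0L)
  expect_false(any(f$spot_truth$channel == "upa"))
  cfg2 <- sim_config(52, n_cells = 12L)
  f2 <- simulate_fish_images(cfg2, 1)[[1]]
  per_cell <- dplyr::count(f2$spot_truth[f2$spot_truth$channel == "upa", ],
                           .data$cell)
  truth <- f2$cell_truth[f2$cell_truth$n_upa > 0, ]
  expect_equal(per_cell$n, truth$n_upa)
  expect_equal(sum(f2$cell_truth$n_coloc),
               sum(f2$spot_truth$colocalized, na.rm = TRUE))
})

test_that("the presence generator plants the configured probabilities", {
  cfg <- sim_config(61, donor_logit_sd = 0)
  rec <- simulate_presence_table(cfg, n_per_group = 400L)
  p_hat <- tapply(rec$present, rec$cell_type, mean)
  for (ct in names(cfg$cell_type_prob)) {
    p <- cfg$cell_type_prob[[ct]]
    expect_lt(abs(p_hat[[ct]] - p), 3 * sqrt(p * (1 - p) / 1600) + 1e-9)
  }
  expect_error(simulate_presence_table(cfg, cell_types = "naive_treg"))
})

test_that("a full study directory round-trips through its readers", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(71, n_cells = 9L)
  simulate_study(dir, cfg, n_reads = 200L, replicates = 2L, n_fields = 1L)
  expect_true(file.exists(file.path(dir, "locus.json")))
  ann <- read_locus_json(file.path(dir, "locus.json"))
  loc <- simulate_locus(cfg)
  expect_equal(ann$exons, loc$annotation$exons)
  expect_equal(ann$cage_peaks$summit, loc$annotation$cage_peaks$summit)
  expect_equal(ann$allowed_splice_patterns,
               loc$annotation$allowed_splice_patterns)
  reads <- read_drs_tsv(file.path(dir, "drs_reads.tsv"))
  expect_equal(nrow(reads), 400L)
  expect_identical(reads$blocks,
                   simulate_drs_reads(cfg, loc, 200L, 2L)$blocks)
  tr <- read_bedgraph(file.path(dir, "ngs_coverage.bedgraph"))
  ngs <- simulate_ngs_coverage(cfg, loc)
  anchors <- synthetic_anchor_regions()
  for (k in 1:2) {
    expect_equal(
      region_coverage(tr, anchors$start[k], anchors$end[k]),
      region_coverage(ngs$track, anchors$start[k], anchors$end[k])
    )
  }
  fa <- read_transcripts_fasta(file.path(dir, "transcripts.fasta"))
  expect_identical(fa[["longFOXP3_fl"]], loc$transcripts[["longFOXP3_fl"]])
  img <- read_pgm(file.path(dir, "field01_dapi.pgm"))
  f <- simulate_fish_images(cfg, 1)[[1]]
  expect_equal(dim(img), dim(f$dapi))
  expect_lt(max(abs(img - f$dapi)), 1e-3) # 16-bit quantization
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"))
  expect_equal(prov$seed, 71L)
})
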