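test_that("ORF finder equals the brute-force scan on assorted sequences", {
  set.seed(42)
  seqs <- list(
    random_short = paste(sample(c("A", "C", "G", "U"), 600, TRUE),
                         collapse = ""),
    random_long = paste(sample(c("A", "C", "G", "U"), 1800, TRUE),
                        collapse = ""),
    planted = cached_sim()$locus$transcripts[["longFOXP3_fl"]]
  )
  for (nm in names(seqs)) {
    for (minlen in c(30, 150)) {
      got <- find_orfs(seqs[[nm]], min_len_nt = minlen)
      want <- brute_find_orfs(seqs[[nm]], min_len_nt = minlen)
      expect_equal(got$start_offset, want$start_offset, info = nm)
      expect_equal(got$start_codon, want$start_codon, info = nm)
      expect_equal(got$length_nt, want$length_nt, info = nm)
      expect_equal(got$length_aa, got$length_nt / 3 - 1, info = nm)
    }
  }
})

test_that("ORF length thresholds and degenerate inputs behave as specified", {
  # AUG + 48 sense codons + UAA = 150 nt including the stop
  orf150 <- paste0("AUG", strrep("GCU", 48), "UAA")
  expect_equal(nchar(orf150), 150)
  hit <- find_orfs(orf150, starts = "AUG", min_len_nt = 150)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$length_aa, 49L)
  expect_equal(nrow(find_orfs(orf150, starts = "AUG", min_len_nt = 153)), 0L)
  # no start codons at all
  expect_equal(nrow(find_orfs("GGGCCCAAAGGG")), 0L)
  # a start without an in-frame stop is not an ORF
  expect_equal(nrow(find_orfs(paste0("AUG", strrep("GCU", 60)),
                              min_len_nt = 30)), 0L)
  expect_error(find_orfs("AUGXXX"), "alphabet")
  expect_error(find_orfs("AUGUAA", min_len_nt = 7), "min_len_nt")
  # region restriction only admits starts inside the window
  two <- paste0("AUG", strrep("GCA", 20), "AUG", strrep("GCA", 20), "UAA")
  all_hits <- find_orfs(two, starts = "AUG", min_len_nt = 30)
  expect_equal(nrow(all_hits), 2L)
  win <- find_orfs(two, starts = "AUG", min_len_nt = 30, region = c(2, 70))
  expect_equal(nrow(win), 1L)
})

test_that("Kozak scoring is anchored at the consensus and dominated by -3/+4", {
  expect_equal(kozak_score("GCCGCCAUGG", 7), 1.0)
  expect_equal(kozak_score("NNNNNNAUGN", 7), 0.0)
  # purine at -3 strictly beats pyrimidine, all else equal
  ctx <- function(b3) paste0("GCC", b3, "CCAUGG")
  for (pur in c("A", "G")) {
    for (pyr in c("C", "U")) {
      expect_gt(kozak_score(ctx(pur), 7), kozak_score(ctx(pyr), 7))
    }
  }
  # content outside the 10-base window is irrelevant
  a <- paste0("AAAAAAAAAA", "GCCGCCAUGG", "AAAAAAAAAA")
  b <- paste0("CGCGCGCGCG", "GCCGCCAUGG", "UUUUUUUUUU")
  expect_equal(kozak_score(a, 17), kozak_score(b, 17))
  expect_equal(kozak_score(a, 17), 1.0)
  # all scores within [0, 1] over random contexts
  set.seed(7)
  for (k in 1:50) {
    s <- paste(sample(c("A", "C", "G", "U"), 10, TRUE), collapse = "")
    sc <- kozak_score(s, 7)
    expect_gte(sc, 0)
    expect_lte(sc, 1)
  }
})

test_that("molecular weights use average residue masses plus one water", {
  expect_equal(protein_mw(""), 0.01801524, tolerance = 1e-9)
  expect_equal(round(protein_mw("GG"), 3), 0.132)
  expect_equal(protein_mw("GG") * 1000, 2 * 57.0519 + 18.01524,
               tolerance = 1e-6)
  expect_error(protein_mw("GXZ"), "unknown amino-acid")
  # additivity: mw(a + b) == mw(a) + mw(b) - water
  set.seed(11)
  aas <- names(foxlocus:::aa_avg_mass)
  for (k in 1:20) {
    a <- paste(sample(aas, sample(1:30, 1), TRUE), collapse = "")
    b <- paste(sample(aas, sample(1:30, 1), TRUE), collapse = "")
    expect_equal(protein_mw(paste0(a, b)),
                 protein_mw(a) + protein_mw(b) - 0.01801524,
                 tolerance = 1e-6)
  }
})

test_that("proteoform enumeration categorizes main, extended and upstream ORFs", {
  # planted inventory of the synthetic 5'-extended transcript
  sim <- cached_sim()
  tx <- sim$locus$transcripts[["longFOXP3_fl"]]
  main <- sim$locus$main_starts[["longFOXP3_fl"]]
  pf <- enumerate_proteoforms(tx, main)
  expect_equal(sum(pf$category == "main_proteoform"), 1L)
  expect_equal(sum(pf$category == "n_extended_proteoform"), 2L)
  expect_equal(sum(pf$category == "uORF"), 5L)
  truth <- sim$locus$orf_truth
  expect_setequal(pf$start_offset, truth$start_offset)
  expect_equal(nrow(pf), nrow(brute_find_orfs(tx)))
  # delta-2 variant keeps the same inventory, shorter main ORF
  pf2 <- enumerate_proteoforms(sim$locus$transcripts[["longFOXP3_d2"]],
                               sim$locus$main_starts[["longFOXP3_d2"]])
  expect_equal(as.vector(table(pf2$category)[c("main_proteoform",
                                               "n_extended_proteoform",
                                               "uORF")]), c(1L, 2L, 5L))
  main_aa <- pf$length_aa[pf$category == "main_proteoform"]
  main_aa2 <- pf2$length_aa[pf2$category == "main_proteoform"]
  expect_equal(main_aa - main_aa2, 35L) # exon 2 encodes 35 residues
})

test_that("in-frame upstream CUG extends the main proteoform by the frame offset", {
  # CUG 54 nt upstream of the main AUG, same frame, no stop in between
  utr <- strrep("CAC", 30)
  body <- paste0("AUG", strrep("GCA", 60), "UAA")
  seq <- paste0(utr, "CUG", strrep("GCA", 17), body)
  main <- nchar(utr) + 3 + 51 + 1
  pf <- enumerate_proteoforms(seq, main, min_len_nt = 60)
  ext <- pf[pf$category == "n_extended_proteoform", ]
  expect_equal(nrow(ext), 1L)
  expect_equal(ext$length_aa - pf$length_aa[pf$category == "main_proteoform"],
               18L)
  # a stop between the CUG and the AUG breaks the extension
  seq2 <- paste0(utr, "CUG", strrep("GCA", 8), "UAA", strrep("GCA", 8), body)
  main2 <- nchar(utr) + 3 + 24 + 3 + 24 + 1
  pf2 <- enumerate_proteoforms(seq2, main2, min_len_nt = 60)
  expect_equal(sum(pf2$category == "n_extended_proteoform"), 0L)
  # main start must be a permitted initiator
  expect_error(enumerate_proteoforms("GGGAAAUAG", 1), "not one of")
})

test_that("initiator codons translate to methionine and report runs per variant", {
  aa <- translate_orf(paste0("CUG", "GCA", "UAA"), 1, 9)
  expect_equal(aa, "MA")
  sim <- cached_sim()
  rep <- coding_potential_report(sim$locus$transcripts[c("longFOXP3_fl",
                                                         "longFOXP3_d2")],
                                 sim$locus$main_starts)
  expect_equal(sort(unique(rep$variant)), c("longFOXP3_d2", "longFOXP3_fl"))
  expect_true(all(rep$mw_kda > 0))
  expect_true(all(rep$kozak_score >= 0 & rep$kozak_score <= 1))
  expect_equal(nrow(rep), 16L) # 8 ORFs per splice variant
})
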