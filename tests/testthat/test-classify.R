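test_that("read filters apply in order with the first violated rule recorded", {
  ann <- mini_locus()
  reads <- dplyr::bind_rows(
    mini_read("neighbor", "10-300;400-500;600-660;800-1052"),
    mini_read("neighbor_and_short", "10-900"), # violates (i) and (iii)
    mini_read("decayed", "95-300;400-500;600-660;800-1052"),
    mini_read("short_utr", "150-300;400-500;600-660;800-991"),
    mini_read("utr_boundary", "150-300;400-500;600-660;800-1001"),
    mini_read("retained_intron", "150-300;400-660;800-1052"),
    mini_read("bad_junction", "150-300;405-500;600-660;800-1052"),
    mini_read("skip_exon1", "150-300;600-660;800-1052"),
    mini_read("antisense", "150-300;400-500;600-660;800-1052", strand = "-")
  )
  cl <- classify_reads(reads, ann)
  res <- setNames(cl$exclusion_reason, cl$read_id)
  expect_equal(res[["neighbor"]], "neighbor_promoter")
  expect_equal(res[["neighbor_and_short"]], "neighbor_promoter")
  expect_equal(res[["decayed"]], "outside_init_region")
  expect_equal(res[["short_utr"]], "short_3utr")
  expect_equal(res[["utr_boundary"]], "none") # exactly 50 nt short is kept
  expect_equal(res[["retained_intron"]], "aberrant_structure")
  expect_equal(res[["bad_junction"]], "aberrant_structure")
  expect_equal(res[["skip_exon1"]], "aberrant_structure")
  expect_equal(res[["antisense"]], "aberrant_structure")
  # partition: every read gets exactly one class; excluded iff reason set
  expect_true(all((cl$class == "excluded") == (cl$exclusion_reason != "none")))
  expect_error(classify_reads(mini_read("x", ""), ann))
})

test_that("surviving reads are assigned the expected promoter and isoform", {
  ann <- mini_locus()
  reads <- dplyr::bind_rows(
    mini_read("can_fl", "150-300;400-500;600-660;800-1052"),
    mini_read("can_d2", "150-300;400-500;800-1052"),
    mini_read("novel", "150-260;400-500;600-660;800-1052"),
    mini_read("long_fl", "60-300;400-500;600-660;800-1052"),
    mini_read("long_d2", "60-300;400-500;800-1052"),
    mini_read("short_up", "60-350"),
    mini_read("short_intron1", "60-320")
  )
  cl <- classify_reads(reads, ann)
  res <- setNames(cl$class, cl$read_id)
  expect_equal(res[["can_fl"]], "canonical_fl")
  expect_equal(res[["can_d2"]], "canonical_d2")
  expect_equal(res[["novel"]], "novel_canonical")
  expect_equal(res[["long_fl"]], "longFOXP3_fl")
  expect_equal(res[["long_d2"]], "longFOXP3_d2")
  expect_equal(res[["short_up"]], "short_upstream")
  expect_equal(res[["short_intron1"]], "short_upstream")
  expect_equal(unname(cl$promoter[cl$read_id == "long_fl"]), "alternative")
})

test_that("abundance report computes ratios, medians and the output ratio", {
  ann <- mini_locus()
  mk <- function(class, n, rep) {
    blocks <- switch(class,
      canonical_fl = "150-300;400-500;600-660;800-1052",
      canonical_d2 = "150-300;400-500;800-1052",
      novel_canonical = "150-260;400-500;600-660;800-1052",
      longFOXP3_fl = "60-300;400-500;600-660;800-1052",
      short_upstream = "60-350")
    purrr::map_dfr(seq_len(n), function(i) {
      mini_read(paste(class, rep, i, sep = "_"), blocks, replicate_id = rep)
    })
  }
  reads <- dplyr::bind_rows(
    mk("canonical_fl", 20, "r1"), mk("canonical_d2", 20, "r1"),
    mk("longFOXP3_fl", 10, "r1"),
    mk("canonical_fl", 40, "r2"), mk("longFOXP3_fl", 10, "r2"),
    mk("novel_canonical", 8, "r2"), mk("short_upstream", 2, "r2")
  )
  rep <- abundance_report(classify_reads(reads, ann))
  r1 <- rep$per_replicate[rep$per_replicate$replicate_id == "r1", ]
  r2 <- rep$per_replicate[rep$per_replicate$replicate_id == "r2", ]
  expect_equal(r1$ratio_canonical_longfoxp3, 4.0)
  expect_true(is.na(r1$ratio_canonical_novel))   # flagged, not infinite
  expect_true(is.na(r1$ratio_canonical_short))
  expect_equal(r2$ratio_canonical_novel, 5.0)
  expect_equal(r2$ratio_canonical_short, 20.0)
  # pooled promoter output ratio: (80 + 8) / (20 + 2)
  expect_equal(rep$promoter_output_ratio, 4.0)
  expect_equal(sum(rep$pooled), nrow(reads))
  # medians: even number of replicates -> mean of the central pair
  expect_equal(rep$medians$median[rep$medians$ratio == "canonical:longFOXP3"],
               4.0)
  expect_equal(median(c(3, 4, 11)), 4) # odd-count convention used throughout
  expect_equal(median(c(3, 5, 7, 11)), 6)
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(glance(rep)$n_total, nrow(reads))
})

test_that("splice fractions sum to one per replicate and average as stated", {
  per_rep <- tibble::tibble(
    replicate_id = c(rep("a", 100), rep("b", 100)),
    class = c(rep("longFOXP3_fl", 40), rep("longFOXP3_d2", 60),
              rep("longFOXP3_fl", 34), rep("longFOXP3_d2", 52),
              rep("longFOXP3_minor", 14))
  )
  sf <- splice_fractions(per_rep)
  expect_equal(sf$per_replicate$frac_fl + sf$per_replicate$frac_d2 +
                 sf$per_replicate$frac_minor, c(1, 1))
  expect_equal(sf$means$frac_fl, 0.37)
  expect_equal(sf$means$frac_d2, 0.56)
  expect_equal(sf$means$frac_minor, 0.07)
  expect_equal(sf$means$frac_fl_d2, 0.93)
  empty <- splice_fractions(tibble::tibble(replicate_id = "a",
                                           class = "canonical_fl"))
  expect_true(is.na(empty$per_replicate$frac_fl))
})

test_that("cleavage offsets are signed in the transcription direction", {
  ann <- mini_locus() # plus strand, PAS at 1050
  reads <- dplyr::bind_rows(
    mini_read("at_pas", "150-300;400-500;600-660;800-1051"),
    mini_read("past_pas", "150-300;400-500;600-660;800-1053")
  )
  off <- cleavage_offsets(classify_reads(reads, ann), ann)
  expect_equal(off$offset[off$read_id == "at_pas"], 0)
  expect_equal(off$offset[off$read_id == "past_pas"], 2)
  # minus-strand check on the synthetic locus: a read ending 2 bases below
  # the PAS has gone 2 nt further in the transcription direction -> +2
  sim <- cached_sim()
  soff <- cleavage_offsets(sim$classified, sim$locus$annotation)
  expect_true(all(abs(soff$offset) <= 2)) # generated jitter support {-2..2}
  h <- cleavage_histogram(soff)
  expect_equal(sum(h$n), nrow(soff))
  expect_equal(sum(h$n[h$bin %in% as.character(-2:2)]), nrow(soff))
})

test_that("poly(A) statistics use the smallest-tie mode and rank-sum test", {
  tb <- tibble::tibble(class = "x", polya_len = c(88, 89, 89, 90),
                       replicate_id = "r1")
  st <- polya_stats(tb)
  expect_equal(st$mode, 89)
  expect_equal(st$median, 89)
  tie <- polya_stats(tibble::tibble(class = "x", polya_len = c(1, 1, 2, 2)))
  expect_equal(tie$mode, 1) # tie broken toward the smallest length
  # identical groups: U = n^2/2 and p ~ 1
  same <- polya_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$U, 4.5)
  expect_gt(same$p_value, 0.9)
  # exact test against full enumeration of rank assignments
  or <- brute_mannwhitney(c(1, 2, 3), c(4, 5, 6))
  got <- polya_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$U, or$U)
  expect_equal(got$p_value, or$p, tolerance = 1e-12)
  or2 <- brute_mannwhitney(c(5, 9, 12, 2), c(7, 8, 14))
  got2 <- polya_compare(c(5, 9, 12, 2), c(7, 8, 14))
  expect_equal(got2$U, or2$U)
  expect_equal(got2$p_value, or2$p, tolerance = 1e-12)
})

test_that("generated class mixture is recovered within 3 multinomial SE", {
  sim <- cached_sim()
  cl <- sim$classified
  kept <- cl[cl$class != "excluded", ]
  w <- sim$cfg$mixture / sum(sim$cfg$mixture)
  # decay is class-independent, so surviving proportions estimate the mixture
  for (k in names(w)) {
    p_hat <- mean(kept$class == k)
    se <- sqrt(w[[k]] * (1 - w[[k]]) / nrow(kept))
    expect_lt(abs(p_hat - w[[k]]), 3 * se + 1e-9)
  }
  # classification never crosses classes on clean structures; a decayed read
  # whose truncated 5' end falls back inside a region is indistinguishable
  # from an intact molecule with that structure, so only intact reads are held
  # to the truth label
  intact <- kept[!kept$decayed, ]
  expect_true(all(intact$class == intact$true_class))
  # decayed reads truncated past the initiation regions are never classified
  regions <- initiation_regions(sim$locus$annotation)
  outside <- is.na(assign_five_prime(cl$five_prime, regions))
  expect_true(all(cl$class[cl$decayed & outside] == "excluded"))
})

test_that("classification is invariant under coordinate reflection", {
  sim <- cached_sim()
  ann <- sim$locus$annotation
  C <- ann$chrom_length
  reads <- sim$reads[1:400, ]
  m_ann <- mirror_locus(ann)
  m_reads <- mirror_reads(reads, C)
  a <- classify_reads(reads, ann)
  b <- classify_reads(m_reads, m_ann)
  expect_identical(a$class, b$class)
  expect_identical(a$exclusion_reason, b$exclusion_reason)
  expect_identical(a$promoter, b$promoter)
})
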