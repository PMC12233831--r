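# planted-disk helpers ------------------------------------------------------
disk_image <- function(H, W, centers, radius, amp = 1, bg = 0.05,
                       noise = 0.02, seed = 1) {
  set.seed(seed)
  img <- matrix(bg, H, W)
  for (k in seq_len(nrow(centers))) {
    yy <- pmax(1, centers[k, 1] - radius):pmin(H, centers[k, 1] + radius)
    xx <- pmax(1, centers[k, 2] - radius):pmin(W, centers[k, 2] + radius)
    dd <- outer((yy - centers[k, 1])^2, (xx - centers[k, 2])^2, "+") <= radius^2
    img[yy, xx][dd] <- amp
  }
  img + matrix(rnorm(H * W, 0, noise), H, W)
}

spot_image <- function(H, W, centers, sigma = 1.5, amp = 1, noise_sd = 0.125,
                       seed = 2) {
  set.seed(seed)
  img <- matrix(0.02, H, W)
  st <- foxlocus:::gauss_stencil(sigma, amp)
  for (k in seq_len(nrow(centers))) {
    img <- foxlocus:::add_stencil(img, centers[k, 1], centers[k, 2], st)
  }
  img + matrix(rnorm(H * W, 0, noise_sd), H, W)
}

test_that("nucleus segmentation finds planted disks and splits touching pairs", {
  expect_equal(max(segment_nuclei(matrix(0, 60, 60))), 0L)
  centers <- cbind(c(30, 30, 90, 90, 60), c(30, 90, 30, 90, 60))
  img <- disk_image(120, 120, centers, radius = 12)
  lab <- segment_nuclei(img)
  expect_equal(max(lab), 5L)
  # two disks overlapping by ~20% of their diameter -> split into 2
  img2 <- disk_image(80, 120, cbind(c(40, 40), c(45, 64)), radius = 12)
  lab2 <- segment_nuclei(img2)
  expect_equal(max(lab2), 2L)
  # without splitting they merge into one object
  lab3 <- segment_nuclei(img2, split_touching = FALSE)
  expect_equal(max(lab3), 1L)
  # size filter rejects specks and giant blobs
  img4 <- disk_image(100, 100, cbind(50, 50), radius = 2)
  expect_equal(max(segment_nuclei(img4, min_diameter = 10)), 0L)
})

test_that("cell expansion converts microns to pixels and partitions by distance", {
  nuc <- matrix(0L, 100, 140)
  nuc[46:54, 26:34] <- 1L
  nuc[46:54, 96:104] <- 2L
  ex <- expand_cells(nuc, radius_um = 3, pixel_size_nm = 104)
  expect_equal(ex$radius_px, 29L)
  # nucleus subset of cell; cytoplasm disjoint from nucleus
  expect_true(all(ex$cells[nuc > 0] == nuc[nuc > 0]))
  expect_true(all(ex$cytoplasm[nuc > 0] == 0L))
  expect_true(all(ex$cells[ex$cytoplasm > 0] == ex$cytoplasm[ex$cytoplasm > 0]))
  # zero radius: cell == nucleus, empty cytoplasm
  ex0 <- expand_cells(nuc, radius_um = 0)
  expect_identical(ex0$cells, nuc)
  expect_equal(sum(ex0$cytoplasm), 0L)
  # Voronoi check against brute-force nearest-nucleus distance
  idx <- which(ex$cells > 0 & nuc == 0, arr.ind = TRUE)
  n1 <- which(nuc == 1L, arr.ind = TRUE)
  n2 <- which(nuc == 2L, arr.ind = TRUE)
  mind <- function(p, set) sqrt(min((set[, 1] - p[1])^2 + (set[, 2] - p[2])^2))
  sel <- idx[seq(1, nrow(idx), by = 17), , drop = FALSE]
  for (k in seq_len(nrow(sel))) {
    d1 <- mind(sel[k, ], n1)
    d2 <- mind(sel[k, ], n2)
    lab <- ex$cells[sel[k, 1], sel[k, 2]]
    if (abs(d1 - d2) > 1e-9) {
      expect_equal(lab, if (d1 < d2) 1L else 2L)
    }
    expect_lte(min(d1, d2), 29 + 1e-9)
  }
})

test_that("spot detection is exact on planted fields and merges agglomerates", {
  blank <- matrix(0.02, 80, 80) + matrix(rnorm(6400, 0, 0.01), 80, 80)
  expect_equal(nrow(detect_spots(blank)$spots), 0L)
  # 10 spots, min separation 6 px, SNR 8 -> 100% recall
  centers <- cbind(rep(c(15, 30, 45, 60, 75), 2),
                   rep(c(20, 50), each = 5))
  img <- spot_image(90, 70, centers)
  found <- detect_spots(img)
  expect_equal(nrow(found$spots), 10L)
  # detected centroids within 1.5 px of planted positions
  for (k in seq_len(nrow(centers))) {
    d <- sqrt((found$spots$row - centers[k, 1])^2 +
                (found$spots$col - centers[k, 2])^2)
    expect_lt(min(d), 1.5)
  }
  # two spots 1 px apart form one connected component -> one spot
  img2 <- spot_image(60, 60, cbind(c(30, 31), c(30, 30)))
  expect_equal(nrow(detect_spots(img2)$spots), 1L)
})

test_that("co-localization uses the fractional overlap of the UPA spot", {
  mk_set <- function(mask) {
    lab <- foxlocus:::.cc_label(mask)
    idx <- which(lab > 0, arr.ind = TRUE)
    lv <- lab[lab > 0]
    structure(list(labels = lab, spots = tibble::tibble(
      spot_id = sort(unique(lv)),
      area = as.integer(tabulate(lv)[sort(unique(lv))]),
      row = as.numeric(tapply(idx[, 1], lv, mean)),
      col = as.numeric(tapply(idx[, 2], lv, mean))
    )), class = "spot_set")
  }
  m <- matrix(FALSE, 20, 20)
  m[5:8, 5:8] <- TRUE # 16-px spot
  upa <- mk_set(m)
  # identical masks: fully co-localized
  tag <- colocalize(upa, mk_set(m))
  expect_true(all(tag$colocalized))
  expect_equal(tag$overlap_frac, 1)
  # 4 of 16 px overlapped = 25% < 0.3 -> not co-localized
  m2 <- matrix(FALSE, 20, 20)
  m2[7:8, 7:8] <- TRUE
  tag2 <- colocalize(upa, mk_set(m2))
  expect_equal(tag2$overlap_frac, 0.25)
  expect_false(any(tag2$colocalized))
  expect_true(colocalize(upa, mk_set(m2), min_overlap = 0.2)$colocalized)
  # anti-monotone in the threshold
  set.seed(3)
  ru <- matrix(runif(900) < 0.2, 30, 30)
  rm <- matrix(runif(900) < 0.2, 30, 30)
  upa_r <- mk_set(ru)
  mrna_r <- mk_set(rm)
  counts <- vapply(seq(0.1, 1, by = 0.1), function(th) {
    sum(colocalize(upa_r, mrna_r, th)$colocalized)
  }, 1)
  expect_true(all(diff(counts) <= 0))
})

test_that("culture summaries reproduce the event-ratio arithmetic", {
  expect_equal(round(ratio_upa_only_to_coloc(1713, 850), 1), 2.0)
  expect_true(is.na(ratio_upa_only_to_coloc(10, 0)))
  cells <- tibble::tibble(
    cell_id = 1:4, nucleus_area = 100L,
    n_mrna = c(5L, 0L, 2L, 3L), n_mrna_nuclear = c(4L, 0L, 1L, 3L),
    n_upa = c(4L, 0L, 0L, 2L), n_upa_nuclear = c(3L, 0L, 0L, 2L),
    n_coloc = c(1L, 0L, 0L, 1L), n_coloc_nuclear = c(1L, 0L, 0L, 1L)
  )
  cs <- summarize_culture(cells)
  expect_equal(cs$n_cells, 4L)
  expect_equal(cs$pct_cells_with_mrna, 75)
  expect_equal(cs$pct_cells_with_upa, 50)
  expect_equal(cs$pct_upa_colocalized, 100 * 2 / 6)
  expect_equal(cs$ratio_upa_only_to_coloc, 2)
  expect_equal(cs$pct_nuclear_upa, 100 * 5 / 6)
  empty <- summarize_culture(dplyr::mutate(cells, n_mrna = 0L, n_upa = 0L,
                                           n_coloc = 0L))
  expect_equal(empty$pct_cells_with_mrna, 0)
  expect_true(is.na(empty$ratio_upa_only_to_coloc))
  expect_s3_class(tidy(cs), "tbl_df")
})

test_that("planted per-cell counts are recovered from simulated fields", {
  cfg <- sim_config(31, n_cells = 36L)
  fields <- simulate_fish_images(cfg, 2) # scaled down for runtime
  per_cell_truth <- integer()
  per_cell_found <- integer()
  for (f in fields) {
    q <- quantify_fish_field(f)
    expect_equal(nrow(q$cells), nrow(f$cell_truth))
    # match detected cells to planted cells by nucleus centre
    nuc <- segment_nuclei(f$dapi)
    at <- cbind(f$cell_truth$cy, f$cell_truth$cx)
    ids <- nuc[at]
    expect_true(all(ids > 0))
    per_cell_truth <- c(per_cell_truth, f$cell_truth$n_mrna)
    per_cell_found <- c(per_cell_found, q$cells$n_mrna[ids])
  }
  expect_gte(suppressWarnings(cor(per_cell_truth, per_cell_found,
                                  method = "spearman")), 0.9)
  expect_lte(abs(sum(per_cell_found) - sum(per_cell_truth)) /
               sum(per_cell_truth), 0.10)
})

test_that("planted positive fractions are recovered within the binomial CI", {
  # the pipeline can only recover the realized Bernoulli draw planted in the
  # images, so recovery is judged against the per-cell truth: cell-for-cell
  # concordance, and the recovered fraction inside the binomial 95% CI of the
  # planted fraction
  for (p in c(0.1, 0.5, 0.9)) {
    cfg <- sim_config(round(100 * p) + 7, n_cells = 49L,
                      upa_positive_prob = p)
    f <- simulate_fish_images(cfg, 1)[[1]]
    q <- quantify_fish_field(f)
    nuc <- segment_nuclei(f$dapi)
    ids <- nuc[cbind(f$cell_truth$cy, f$cell_truth$cx)]
    expect_true(all(ids > 0))
    planted <- f$cell_truth$upa_positive
    found <- q$cells$n_upa[ids] > 0
    expect_gte(mean(found == planted), 0.95)
    n <- length(planted)
    p_hat <- mean(found)
    p_planted <- mean(planted)
    ci <- p_planted + c(-1.96, 1.96) *
      sqrt(max(p_planted * (1 - p_planted), 0.25 / n) / n)
    expect_true(p_hat >= ci[1] && p_hat <= ci[2])
  }
})

test_that("nuclear fractions are bounded by the planted compartments", {
  cfg_nuc <- sim_config(41, n_cells = 16L, nuclear_fraction = 1)
  f <- simulate_fish_images(cfg_nuc, 1)[[1]]
  cs <- summarize_culture(quantify_fish_field(f)$cells)
  expect_equal(cs$pct_nuclear_mrna, 100)
  cfg_cyt <- sim_config(43, n_cells = 16L, nuclear_fraction = 0)
  f2 <- simulate_fish_images(cfg_cyt, 1)[[1]]
  cs2 <- summarize_culture(quantify_fish_field(f2)$cells)
  expect_lte(cs2$pct_nuclear_mrna, 5)
})
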