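# Independent oracles and small fixtures used across the suite.

# Brute-force ORF scan: every position x {AUG, CUG}, walk codon by codon to
# the first stop. Deliberately naive and independent of find_orfs.
brute_find_orfs <- function(seq, starts = c("AUG", "CUG"), min_len_nt = 150) {
  s <- chartr("T", "U", toupper(seq))
  n <- nchar(s)
  out <- list()
  for (p in seq_len(max(0, n - 2))) {
    codon <- substr(s, p, p + 2)
    if (!codon %in% starts) next
    q <- p
    len <- NA
    while (q + 2 <= n) {
      c2 <- substr(s, q, q + 2)
      if (q > p && c2 %in% c("UAA", "UAG", "UGA")) {
        len <- q + 3 - p
        break
      }
      q <- q + 3
    }
    if (!is.na(len) && len >= min_len_nt) {
      out[[length(out) + 1]] <- data.frame(start_offset = p,
                                           start_codon = codon,
                                           length_nt = len)
    }
  }
  if (length(out) == 0) {
    data.frame(start_offset = integer(), start_codon = character(),
               length_nt = integer())
  } else {
    do.call(rbind, out)
  }
}

# Exact two-sided Mann-Whitney by full enumeration of group assignments.
brute_mannwhitney <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(length(pooled), nx)
  us <- apply(idx, 2, function(i) sum(r[i]) - nx * (nx + 1) / 2)
  mu <- nx * length(y) / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
  list(U = u_obs, p = p)
}

# Reflect a read table through constant C (intervals [s,e) -> [C-e, C-s)).
mirror_reads <- function(reads, C) {
  bl <- lapply(strsplit(reads$blocks, ";"), function(b) {
    m <- matrix(as.integer(unlist(strsplit(b, "-"))), ncol = 2, byrow = TRUE)
    m2 <- cbind(C - m[, 2], C - m[, 1])
    m2[order(m2[, 1]), , drop = FALSE]
  })
  reads$blocks <- vapply(bl, function(m) {
    paste(sprintf("%d-%d", m[, 1], m[, 2]), collapse = ";")
  }, "")
  reads$strand <- ifelse(reads$strand == "+", "-", "+")
  reads
}

# A small plus-strand 4-exon locus for targeted filter tests: alternative
# promoter upstream (lower coordinates), canonical promoter inside exon -1.
mini_locus <- function() {
  locus_annotation(
    chrom = "chrT", strand = "+",
    exons = tibble::tibble(exon = c(-1L, 1L, 2L, 3L),
                           start = c(100L, 400L, 600L, 800L),
                           end = c(300L, 500L, 660L, 1100L)),
    pas_position = 1050L,
    cage_peaks = tibble::tibble(
      promoter_id = c("canonical", "alternative"),
      peak_number = c(1L, 1L),
      start = c(146L, 57L), end = c(155L, 64L),
      summit = c(150L, 60L), score = c(1000, 300), sigma = c(4, 3)
    ),
    neighbor_promoter = c(0L, 30L),
    allowed_splice_patterns = list(integer(0), 2L),
    alt_first_exons = tibble::tibble(start = 100L, end = 260L),
    cds_exons = 1:3,
    chrom_length = 2000L
  )
}

mini_read <- function(id, blocks, strand = "+", polya = 80,
                      replicate_id = "rep1") {
  tibble::tibble(read_id = id, strand = strand, blocks = blocks,
                 polya_len = polya, replicate_id = replicate_id)
}

# Cached standard simulation shared by several tests (built once per run).
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function() {
  if (is.null(.sim_cache$std)) {
    cfg <- sim_config(101)
    locus <- simulate_locus(cfg)
    reads <- simulate_drs_reads(cfg, locus, n_reads = 4000L, replicates = 2L)
    classified <- classify_reads(reads, locus$annotation)
    .sim_cache$std <- list(cfg = cfg, locus = locus, reads = reads,
                           classified = classified)
  }
  .sim_cache$std
}

# Shared image run for the UPA-positivity and co-localization recovery
# criteria (built once; 3 fields at the published naive-Treg medians).
fish_recovery_run <- function() {
  if (is.null(.sim_cache$fish)) {
    summaries <- purrr::map(1:3, function(k) {
      cfg <- sim_config(300 + k, n_cells = 49L,
                        upa_positive_prob = 0.88, coloc_fraction = 0.22)
      field <- simulate_fish_images(cfg, 1)[[1]]
      summarize_culture(quantify_fish_field(field)$cells)
    })
    .sim_cache$fish <- summaries
  }
  .sim_cache$fish
}

# Small planted-spot image for acceptance property checks.
spot_image_acc <- function(centers, H = 80, W = 80, seed = 12) {
  set.seed(seed)
  img <- matrix(0.02, H, W)
  st <- foxlocus:::gauss_stencil(1.5, 1)
  for (k in seq_len(nrow(centers))) {
    img <- foxlocus:::add_stencil(img, centers[k, 1], centers[k, 2], st)
  }
  img + matrix(rnorm(H * W, 0, 0.1), H, W)
}
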