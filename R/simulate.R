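#' Simulation configuration
#'
#' One object stating the synthetic world for every generator. Defaults are
#' the conditions of the study the pipeline emulates: a minus-strand 12-exon
#' locus with a dominant canonical promoter (two CAGE peaks, one 59-fold
#' stronger) and a broad alternative promoter (four peaks) 1.6 kb upstream;
#' read-class mixture reproducing the published median abundance ratios
#' (canonical : novel canonical : longFOXP3 : short upstream = 6 : 1 : 1.5 :
#' 0.35); 30% 5'-decayed reads with a geometric truncation law; cleavage
#' jitter of +/-2 nt around the PAS; log-normal poly(A) tails with modes 89 nt
#' (FOXP3-like classes) and 53 nt (background/short classes); a
#' non-adenylated:adenylated upstream ratio of 4; and imaging fields of T-cell
#' like nuclei at 104 nm pixels with diffraction-limited spots at SNR 8, 88%
#' UPA-positive cells, a 22% co-localized UPA fraction and 85% nuclear spots.
#'
#' @param seed Integer seed; mandatory — every generator is deterministic
#'   given the seed.
#' @param ... Named overrides of any default listed above (see the source for
#'   the complete field list).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  defaults <- list(
    seed = as.integer(seed),
    chrom = "chrS",
    chrom_length = 60000L,
    strand = "-",
    # read-class mixture (relative copy numbers; canonical split ~45:55
    # fl:delta2 and longFOXP3 split 37:56:7 as published)
    mixture = c(canonical_fl = 2.7, canonical_d2 = 3.3, novel_canonical = 1,
                longFOXP3_fl = 0.555, longFOXP3_d2 = 0.84,
                longFOXP3_minor = 0.105, short_upstream = 0.35),
    decay_fraction = 0.3,
    decay_mean_nt = 400,
    tss_jitter_sd = NA_real_, # NA -> per-peak sigma
    tech_loss_range = c(5L, 15L), # 5' nt lost by the sequencing chemistry
    pas_jitter = -2:2,
    polya_mode_foxp3 = 89,
    polya_mode_background = 53,
    polya_sdlog = 0.25,
    nonadenylated_ratio = 4,
    ngs_depth = 250,
    ngs_fragment_len = 150L,
    # imaging
    pixel_size_nm = 104,
    n_cells = 60L,
    nucleus_radius_px = c(22L, 28L), # ~2.3-2.9 um radius at 104 nm pixels
    cell_expand_um = 3,
    spot_sigma_px = 1.5,
    snr = 8,
    mrna_mu = 6, mrna_size = 8,
    upa_extra_lambda = 2, # UPA count in positive cells = 1 + Poisson(lambda)
    upa_positive_prob = 0.88,
    coloc_fraction = 0.22,
    nuclear_fraction = 0.85,
    # presence-table world
    donors = paste0("HD", 1:4),
    cell_type_prob = c(naive_tconv = 0.06, memory_tconv = 0.11,
                       memory_treg = 0.18, naive_treg = 0.88),
    donor_logit_sd = 0.3
  )
  cfg <- utils::modifyList(defaults, list(...))
  stopifnot(all(cfg$mixture >= 0), cfg$decay_fraction >= 0,
            cfg$decay_fraction <= 1,
            cfg$upa_positive_prob >= 0, cfg$upa_positive_prob <= 1,
            cfg$coloc_fraction >= 0, cfg$coloc_fraction <= 1,
            cfg$nuclear_fraction >= 0, cfg$nuclear_fraction <= 1)
  class(cfg) <- "sim_config"
  cfg
}

# deterministic sub-seed per generator so generators are independent of the
# order in which they are called
sub_seed <- function(cfg, k) (cfg$seed * 97L + k * 10007L) %% 2147483647L

# ---------------------------------------------------------------------------
# locus + transcripts

# exon lengths in transcription order (exon -1 then 1..11) and intron lengths
synth_exon_lengths <- c(320L, 180L, 105L, 87L, 60L, 75L, 90L, 81L, 102L,
                        120L, 96L, 1000L)
synth_intron_lengths <- c(770L, 300L, 250L, 400L, 350L, 500L, 450L, 300L,
                          380L, 420L, 600L)
synth_exon_numbers <- c(-1L, 1:11)

#' Simulate the locus annotation and transcript sequences
#'
#' Builds a minus-strand FOXP3-like locus (12 exons numbered -1 and 1..11,
#' PAS inside the terminal exon, two canonical and four alternative CAGE
#' peaks, a neighbouring promoter upstream of the alternative cluster, and
#' one alternative first-exon structure for novel canonical transcripts), and
#' the transcript sequences of the canonical and 5'-extended (longFOXP3-like)
#' isoforms in full-length and delta-2 forms.
#'
#' The sequence background is generated T-free so that every start codon
#' (AUG/CUG) and stop in the transcripts is planted explicitly: the extended
#' transcript carries exactly 5 upstream ORFs (4 in the 5' extension, 1
#' starting in the canonical 5' UTR and overlapping the main start), 2
#' in-frame upstream starts sharing the main stop (N-extended proteoforms),
#' and the main ORF. The planted inventory is returned as the truth table.
#'
#' @param config A [sim_config()].
#' @return List: `annotation` ([locus_annotation()]), `transcripts` (named
#'   character, DNA alphabet), `main_starts` (named 1-based offsets),
#'   `orf_truth` (tibble of planted elements for the extended full-length
#'   transcript), `mirrored` (function returning the reflected annotation).
#' @export
simulate_locus <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  # --- genomic geometry (deterministic) ------------------------------------
  top <- 50220L # genomic end (exclusive) of exon -1 on the minus strand
  starts <- integer(12)
  ends <- integer(12)
  cur <- top
  for (k in 1:12) {
    ends[k] <- cur
    starts[k] <- cur - synth_exon_lengths[k]
    if (k < 12) cur <- starts[k] - synth_intron_lengths[k]
  }
  exons <- tibble::tibble(exon = synth_exon_numbers, start = starts,
                          end = ends)
  pas <- starts[12] + 8L
  peaks <- tibble::tibble(
    promoter_id = c("canonical", "canonical", rep("alternative", 4)),
    peak_number = c(1L, 2L, 1L, 2L, 3L, 4L),
    start = c(50204L, 50061L, 51644L, 51739L, 51809L, 51944L),
    end = c(50217L, 50074L, 51657L, 51752L, 51822L, 51957L),
    summit = c(50210L, 50067L, 51650L, 51745L, 51815L, 51950L),
    score = c(18671, 315, 396, 195, 453, 261),
    sigma = c(8, 6, 6, 6, 6, 6)
  )
  ann <- locus_annotation(
    chrom = config$chrom, strand = config$strand, exons = exons,
    pas_position = pas, cage_peaks = peaks,
    neighbor_promoter = c(52200L, 52500L),
    alt_first_exons = tibble::tibble(start = 49970L, end = 50220L),
    chrom_length = config$chrom_length
  )
  # --- transcript sequences -------------------------------------------------
  set.seed(sub_seed(config, 1L))
  main_tss <- 51815L # alternative peak 3, the highest-scoring alt peak
  ext_len <- main_tss - (top - 1L) # 5' extension upstream of exon -1
  canonical_len <- sum(synth_exon_lengths)
  L <- ext_len + canonical_len
  base <- sample(c("A", "C", "G"), L, replace = TRUE)
  plant <- function(x, at, what) {
    w <- strsplit(what, "", fixed = TRUE)[[1]]
    x[at:(at + length(w) - 1L)] <- w
    x
  }
  tfree_codons <- apply(expand.grid(c("A", "C", "G"), c("A", "C", "G"),
                                    c("A", "C", "G")), 1, paste, collapse = "")
  fill_codons <- function(x, from, to) {
    n <- (to - from + 1L) %/% 3L
    if (n > 0) {
      x[from:(from + 3L * n - 1L)] <-
        unlist(strsplit(sample(tfree_codons, n, replace = TRUE), ""))
    }
    x
  }
  utr5_exon1 <- 30L
  main_start <- ext_len + synth_exon_lengths[1] + utr5_exon1 + 1L # 1947
  cds_len <- 1086L # incl. stop; ends inside exon 11
  uorfs <- tibble::tibble(
    name = paste0("uORF", 1:5),
    start_offset = c(101L, 401L, 701L, 1101L, main_start - 50L),
    start_codon = c("CTG", "CTG", "CTG", "ATG", "CTG"),
    length_nt = c(156L, 150L, 216L, 285L, 165L)
  )
  # uORF5 starts in the canonical 5' UTR, in a different frame from the main
  # start, and overlaps the main ORF
  stopifnot((uorfs$start_offset[5] - main_start) %% 3L != 0L)
  ext_starts <- tibble::tibble(
    name = c("n_ext_AUG", "n_ext_CUG"),
    start_offset = c(main_start - 501L, main_start - 402L),
    start_codon = c("ATG", "CTG")
  )
  stopifnot(all((main_start - ext_starts$start_offset) %% 3L == 0L),
            all(ext_starts$start_offset + 2L < ext_len))
  # main ORF
  base <- plant(base, main_start, "ATG")
  base <- plant(base, main_start + 3L, "GCC") # keeps uORF5's frame stop-free
  base <- fill_codons(base, main_start + 6L, main_start + cds_len - 4L)
  base <- plant(base, main_start + cds_len - 3L, "TAA")
  # N-extended starts (share the main stop; T-free background in between)
  for (k in 1:2) base <- plant(base, ext_starts$start_offset[k],
                               ext_starts$start_codon[k])
  # upstream ORFs
  for (k in 1:5) {
    st <- uorfs$start_offset[k]
    len <- uorfs$length_nt[k]
    base <- plant(base, st, uorfs$start_codon[k])
    if (k < 5L) base <- fill_codons(base, st + 3L, st + len - 4L)
    # uORF5's interior crosses the planted main start; only its stop is
    # written, at an offset that keeps the main frame stop-free
    base <- plant(base, st + len - 3L, "TAA")
  }
  long_fl <- paste(base, collapse = "")
  # transcript-local exon boundaries (extension + exon -1 + exons 1..11)
  loc_ends <- ext_len + cumsum(synth_exon_lengths)
  loc_starts <- c(ext_len + 1L, loc_ends[-12] + 1L)
  drop_exon <- function(s, numbers) {
    keep <- rep(TRUE, nchar(s))
    for (nb in numbers) {
      k <- which(synth_exon_numbers == nb)
      keep[loc_starts[k]:loc_ends[k]] <- FALSE
    }
    paste(strsplit(s, "")[[1]][keep], collapse = "")
  }
  long_d2 <- drop_exon(long_fl, 2L)
  canonical_fl <- substr(long_fl, ext_len + 1L, L)
  canonical_d2 <- {
    k <- which(synth_exon_numbers == 2L)
    st <- loc_starts[k] - ext_len
    en <- loc_ends[k] - ext_len
    paste0(substr(canonical_fl, 1, st - 1L),
           substr(canonical_fl, en + 1L, nchar(canonical_fl)))
  }
  transcripts <- c(longFOXP3_fl = long_fl, longFOXP3_d2 = long_d2,
                   canonical_fl = canonical_fl, canonical_d2 = canonical_d2)
  main_starts <- c(longFOXP3_fl = main_start,
                   longFOXP3_d2 = main_start,
                   canonical_fl = main_start - ext_len,
                   canonical_d2 = main_start - ext_len)
  orf_truth <- dplyr::bind_rows(
    tibble::tibble(name = "main", start_offset = main_start,
                   start_codon = "ATG", length_nt = cds_len,
                   category = "main_proteoform"),
    tibble::tibble(name = ext_starts$name,
                   start_offset = ext_starts$start_offset,
                   start_codon = ext_starts$start_codon,
                   length_nt = main_start + cds_len - ext_starts$start_offset,
                   category = "n_extended_proteoform"),
    tibble::tibble(name = uorfs$name, start_offset = uorfs$start_offset,
                   start_codon = uorfs$start_codon,
                   length_nt = uorfs$length_nt, category = "uORF")
  )
  list(annotation = ann, transcripts = transcripts,
       main_starts = main_starts, orf_truth = orf_truth,
       main_tss = main_tss, ext_len = ext_len)
}

# ---------------------------------------------------------------------------
# direct-RNA reads

class_skip <- list(
  canonical_fl = integer(0), canonical_d2 = 2L, novel_canonical = integer(0),
  longFOXP3_fl = integer(0), longFOXP3_d2 = 2L
)

#' Simulate aligned direct-RNA reads with ground truth
#'
#' Draws reads from the configured class mixture: 5' ends are sampled from
#' the promoter's CAGE peaks (score-weighted) with per-peak Gaussian TSS
#' jitter and a uniform 5'-terminal loss of `tech_loss_range` nt (the
#' sequencing chemistry misses the first nucleotides); 3' ends jitter by
#' `pas_jitter` around the PAS (short upstream transcripts instead terminate
#' uniformly between the promoters); splice blocks follow the class's exon
#' structure; a `decay_fraction` of reads is additionally 5'-truncated by a
#' geometric decay law (mean `decay_mean_nt`). Poly(A) lengths are log-normal
#' with the class's mode. Byte-identical output for a given seed.
#'
#' @param config A [sim_config()].
#' @param locus Output of [simulate_locus()] (defaults to building it).
#' @param n_reads Reads per replicate.
#' @param replicates Number of replicates.
#' @return Tibble of reads (see [drs_reads]) plus truth columns `true_class`,
#'   `decayed`.
#' @export
simulate_drs_reads <- function(config, locus = simulate_locus(config),
                               n_reads = 10000L, replicates = 4L) {
  stopifnot(n_reads > 0, replicates >= 1)
  set.seed(sub_seed(config, 2L))
  ann <- locus$annotation
  peaks <- ann$cage_peaks
  w <- config$mixture / sum(config$mixture)
  exons <- ann$exons
  exon11 <- exons[exons$exon == 11L, ]
  first_exon <- exons[1, ]
  out <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cls <- sample(names(w), n_reads, replace = TRUE, prob = w)
    promoter <- ifelse(cls %in% c("canonical_fl", "canonical_d2",
                                  "novel_canonical"),
                       "canonical", "alternative")
    # 5' ends: score-weighted peak choice + jitter - technology loss
    five <- integer(n_reads)
    for (p in c("canonical", "alternative")) {
      idx <- which(promoter == p)
      if (length(idx) == 0) next
      pk <- peaks[peaks$promoter_id == p, ]
      pick <- sample(nrow(pk), length(idx), replace = TRUE, prob = pk$score)
      sd <- if (is.na(config$tss_jitter_sd)) pk$sigma[pick] else
        rep(config$tss_jitter_sd, length(idx))
      loss <- if (config$tech_loss_range[2] > 0) {
        sample(config$tech_loss_range[1]:config$tech_loss_range[2],
               length(idx), replace = TRUE)
      } else 0L
      jit <- round(rnorm(length(idx), 0, sd))
      five[idx] <- pk$summit[pick] + if (ann$strand == "+") -jit + loss else
        jit - loss
    }
    # 3' ends
    three <- integer(n_reads)
    reach11 <- !(cls %in% "short_upstream")
    o <- sample(config$pas_jitter, sum(reach11), replace = TRUE)
    three[reach11] <- if (ann$strand == "+") ann$pas_position + o else
      ann$pas_position - o
    if (any(!reach11)) {
      # short upstream transcripts end between the two promoters
      lo <- first_exon$end + 80L
      hi <- min(peaks$start[peaks$promoter_id == "alternative"]) - 120L
      three[!reach11] <- sample(lo:hi, sum(!reach11), replace = TRUE)
    }
    blocks <- character(n_reads)
    for (i in seq_len(n_reads)) {
      blocks[i] <- build_read_blocks(cls[i], five[i], three[i], ann)
    }
    # 5' decay
    decayed <- runif(n_reads) < config$decay_fraction
    if (any(decayed)) {
      for (i in which(decayed)) {
        m <- parse_blocks(blocks[i])[[1]]
        span <- sum(m[, 2] - m[, 1])
        dlen <- 1L + rgeom(1, 1 / config$decay_mean_nt)
        dlen <- min(dlen, span - 100L)
        if (dlen > 0) {
          m2 <- truncate_blocks_5p(m, dlen, ann$strand)
          blocks[i] <- format_blocks(list(m2))
          five[i] <- if (ann$strand == "+") m2[1, 1] else m2[nrow(m2), 2] - 1L
        }
      }
    }
    polya <- numeric(n_reads)
    fox <- cls %in% c("canonical_fl", "canonical_d2", "novel_canonical",
                      "longFOXP3_fl", "longFOXP3_d2", "longFOXP3_minor")
    mode_of <- ifelse(fox, config$polya_mode_foxp3,
                      config$polya_mode_background)
    polya <- rlnorm(n_reads, log(mode_of) + config$polya_sdlog^2,
                    config$polya_sdlog)
    out[[r]] <- tibble::tibble(
      read_id = sprintf("r%d_%06d", r, seq_len(n_reads)),
      strand = ann$strand, blocks = blocks,
      polya_len = polya, replicate_id = paste0("rep", r),
      true_class = cls, decayed = decayed
    )
  }
  dplyr::bind_rows(out)
}

# genomic block chain for one read of a given class
build_read_blocks <- function(cls, five, three, ann) {
  exons <- ann$exons
  strand <- ann$strand
  if (cls == "short_upstream") {
    m <- if (strand == "+") cbind(five, three + 1L) else cbind(three, five + 1L)
    return(format_blocks(list(unname(m))))
  }
  skip <- if (cls == "longFOXP3_minor") {
    if (runif(1) < 0.5) 7L else c(2L, 7L)
  } else {
    class_skip[[cls]]
  }
  first <- exons[1, ]
  if (cls == "novel_canonical") {
    v <- ann$alt_first_exons[1, ]
    first <- tibble::tibble(exon = -1L, start = v$start, end = v$end)
  }
  chain <- dplyr::bind_rows(
    first,
    exons[-1, ][!exons$exon[-1] %in% skip, ]
  )
  # clip the first exon to the 5' end and the last to the 3' end
  if (strand == "+") {
    chain$start[1] <- five
    chain$end[nrow(chain)] <- three + 1L
    m <- cbind(chain$start, chain$end)
  } else {
    chain$end[1] <- five + 1L
    chain$start[nrow(chain)] <- three
    m <- cbind(rev(chain$start), rev(chain$end))
  }
  format_blocks(list(unname(m)))
}

# remove dlen transcribed nt from the 5' side of a block matrix
truncate_blocks_5p <- function(m, dlen, strand) {
  if (strand == "-") {
    # 5' side is the genomic top: walk blocks from the last down
    k <- nrow(m)
    while (dlen > 0 && k >= 1) {
      w <- m[k, 2] - m[k, 1]
      if (dlen < w) {
        m[k, 2] <- m[k, 2] - dlen
        dlen <- 0
      } else {
        dlen <- dlen - w
        m <- m[-k, , drop = FALSE]
        k <- k - 1L
      }
    }
  } else {
    while (dlen > 0 && nrow(m) >= 1) {
      w <- m[1, 2] - m[1, 1]
      if (dlen < w) {
        m[1, 1] <- m[1, 1] + dlen
        dlen <- 0
      } else {
        dlen <- dlen - w
        m <- m[-1, , drop = FALSE]
      }
    }
  }
  m
}

# ---------------------------------------------------------------------------
# short-read coverage

#' Simulate short-read coverage over the locus
#'
#' Uniform fragment sampling along each transcript species, projected through
#' the species' exon structure onto the genome. Species and relative copy
#' numbers follow the configured mixture; additionally, non-adenylated
#' upstream transcripts (spanning the alternative promoter down to just above
#' the canonical promoter region — they are invisible to poly(A)-selected
#' long reads) are included at `nonadenylated_ratio` times the adenylated
#' upstream copies. `ngs_depth` calibrates the expected coverage contributed
#' per unit copy weight.
#'
#' @param config A [sim_config()].
#' @param locus Output of [simulate_locus()].
#' @return List: `track` (a [coverage_track()] over the locus span) and
#'   `species` (tibble of species, copies and fragment counts).
#' @export
simulate_ngs_coverage <- function(config, locus = simulate_locus(config)) {
  set.seed(sub_seed(config, 3L))
  ann <- locus$annotation
  exons <- ann$exons
  w <- config$mixture
  stopifnot(config$ngs_depth > 0)
  # genomic footprints (tx order) per species
  exon_chain <- function(skip, first_top) {
    ch <- exons
    ch <- ch[!ch$exon %in% skip, ]
    ch$end[1] <- first_top
    ch
  }
  short_bottom <- 50300L # just above the canonical initiation regions
  main_tss <- locus$main_tss
  footprints <- list(
    canonical = exon_chain(integer(0), exons$end[1]),
    canonical_d2 = exon_chain(2L, exons$end[1]),
    longFOXP3 = exon_chain(integer(0), main_tss + 1L),
    longFOXP3_d2 = exon_chain(2L, main_tss + 1L),
    upstream_short = tibble::tibble(exon = NA_integer_, start = short_bottom,
                                    end = main_tss + 1L)
  )
  alt_polya <- w[["longFOXP3_fl"]] + w[["longFOXP3_d2"]] +
    w[["longFOXP3_minor"]] + w[["short_upstream"]]
  copies <- c(
    canonical = w[["canonical_fl"]] + w[["novel_canonical"]],
    canonical_d2 = w[["canonical_d2"]],
    longFOXP3 = w[["longFOXP3_fl"]] + w[["longFOXP3_minor"]],
    longFOXP3_d2 = w[["longFOXP3_d2"]],
    upstream_short = w[["short_upstream"]] +
      config$nonadenylated_ratio * alt_polya
  )
  # depth scaling: coverage contributed by one copy unit ~ ngs_depth
  span_lo <- min(exons$start) - 200L
  span_hi <- 52600L
  frag <- config$ngs_fragment_len
  cov <- numeric(span_hi - span_lo)
  species <- vector("list", length(copies))
  for (k in seq_along(copies)) {
    fp <- footprints[[k]]
    lens <- fp$end - fp$start
    L <- sum(lens)
    # interior coverage density = nf * frag / (L - frag) = depth * copies
    nf <- round(config$ngs_depth * copies[k] * max(1L, L - frag) / frag)
    if (nf == 0) next
    a <- sample.int(max(1L, L - frag), nf, replace = TRUE) - 1L
    # project transcript interval [a, a+frag) through the exon chain;
    # tx order on the minus strand runs from the chain top downward
    cum <- c(0L, cumsum(lens))
    for (j in seq_len(nrow(fp))) {
      s <- pmax(a, cum[j])
      e <- pmin(a + frag, cum[j + 1L])
      ok <- which(e > s)
      if (length(ok) == 0) next
      if (ann$strand == "-") {
        gs <- fp$end[j] - (e[ok] - cum[j])
        ge <- fp$end[j] - (s[ok] - cum[j])
      } else {
        gs <- fp$start[j] + (s[ok] - cum[j])
        ge <- fp$start[j] + (e[ok] - cum[j])
      }
      ir <- IRanges::IRanges(start = gs - span_lo + 1L, end = ge - span_lo)
      rc <- IRanges::coverage(ir, width = length(cov))
      cov <- cov + as.numeric(rc)
    }
    species[[k]] <- tibble::tibble(species = names(copies)[k],
                                   copies = unname(copies[k]),
                                   n_fragments = nf)
  }
  list(track = coverage_track(ann$chrom, span_lo, cov),
       species = dplyr::bind_rows(species))
}

#' Coverage anchor regions for the synthetic locus
#'
#' Regions over which promoter coverage is measured for the dual-modality
#' estimate on synthetic data. They sit far enough downstream of each
#' promoter's TSS cluster that every transcript of that promoter covers them
#' completely (no fragment-length ramp), and above the 3' end of the
#' non-adenylated upstream species in the canonical case, mirroring the
#' published choice of a single representative initiation region per
#' promoter.
#'
#' @return Tibble usable as the `coverage_regions` of
#'   [dual_modality_report()].
#' @export
synthetic_anchor_regions <- function() {
  tibble::tibble(
    promoter_id = c("canonical", "alternative"),
    peak_number = c(1L, 1L),
    start = c(49950L, 51450L),
    end = c(50010L, 51510L)
  )
}

# ---------------------------------------------------------------------------
# imaging

gauss_stencil <- function(sigma, amp) {
  r <- ceiling(3 * sigma)
  d <- -r:r
  g <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  list(r = r, m = amp * g)
}

add_stencil <- function(img, y, x, st) {
  nr <- nrow(img); nc <- ncol(img); r <- st$r
  ys <- max(1, y - r):min(nr, y + r)
  xs <- max(1, x - r):min(nc, x + r)
  img[ys, xs] <- img[ys, xs] + st$m[ys - y + r + 1, xs - x + r + 1]
  img
}

#' Simulate RNA-FISH fields with ground truth
#'
#' Each field contains `n_cells` nuclei (noisy bright disks on a jittered
#' grid, spaced so that 3-um cell expansions cannot collide), mRNA and UPA
#' channels with diffraction-limited Gaussian spots (sigma `spot_sigma_px`),
#' and Gaussian noise at the configured SNR (spot amplitude / noise SD).
#' Per-cell mRNA counts are negative binomial; a cell is UPA-positive with
#' probability `upa_positive_prob` and then carries `1 + Poisson` UPA spots;
#' each UPA spot co-localizes with probability `coloc_fraction`, in which
#' case a paired mRNA spot is planted at the same position (the two probes
#' detect the same molecule); UPA-only spots are kept at least 6 px away from
#' every mRNA spot so the planted label is the ground truth. Spots are
#' nuclear with probability `nuclear_fraction`.
#'
#' @param config A [sim_config()].
#' @param n_fields Number of fields.
#' @return List of fields; each field is a list with matrices `dapi`,
#'   `mrna`, `upa`, and tibbles `cell_truth` (per-cell planted counts and
#'   positivity) and `spot_truth` (planted spot positions).
#' @export
simulate_fish_images <- function(config, n_fields = 1L) {
  set.seed(sub_seed(config, 4L))
  n <- config$n_cells
  rmax <- max(config$nucleus_radius_px)
  expand_px <- as.integer(round(config$cell_expand_um * 1000 /
                                  config$pixel_size_nm))
  cell_r <- rmax + expand_px
  pitch <- 2L * cell_r + 8L
  ncol_grid <- ceiling(sqrt(n))
  nrow_grid <- ceiling(n / ncol_grid)
  H <- nrow_grid * pitch + pitch
  W <- ncol_grid * pitch + pitch
  purrr::map(seq_len(n_fields), function(f) simulate_fish_field(config, n,
    nrow_grid, ncol_grid, pitch, H, W, expand_px))
}

simulate_fish_field <- function(config, n, nrow_grid, ncol_grid, pitch,
                                H, W, expand_px) {
  dapi <- matrix(0.05, H, W)
  mrna <- matrix(0.02, H, W)
  upa <- matrix(0.02, H, W)
  st <- gauss_stencil(config$spot_sigma_px, 1)
  cells <- vector("list", n)
  spots <- list()
  for (i in seq_len(n)) {
    gy <- (i - 1) %/% ncol_grid
    gx <- (i - 1) %% ncol_grid
    cy <- round(pitch * (gy + 1) + runif(1, -4, 4))
    cx <- round(pitch * (gx + 1) + runif(1, -4, 4))
    rn <- sample(config$nucleus_radius_px[1]:config$nucleus_radius_px[2], 1)
    yy <- pmax(1, cy - rn):pmin(H, cy + rn)
    xx <- pmax(1, cx - rn):pmin(W, cx + rn)
    dd <- outer((yy - cy)^2, (xx - cx)^2, "+") <= rn^2
    dapi[yy, xx][dd] <- dapi[yy, xx][dd] + 1
    # spot placement helpers
    place <- function(nuclear) {
      repeat {
        if (nuclear) {
          rr <- (rn - 3) * sqrt(runif(1))
        } else {
          rr <- runif(1, rn + 4, rn + expand_px - 4)
        }
        th <- runif(1, 0, 2 * pi)
        y <- round(cy + rr * sin(th)); x <- round(cx + rr * cos(th))
        if (y > 3 && y < H - 3 && x > 3 && x < W - 3) return(c(y, x))
      }
    }
    min_sep_ok <- function(p, others, d) {
      length(others) == 0 ||
        all((vapply(others, `[`, 1, 1) - p[1])^2 +
              (vapply(others, `[`, 1, 2) - p[2])^2 >= d^2)
    }
    n_mrna <- rnbinom(1, mu = config$mrna_mu, size = config$mrna_size)
    mrna_pos <- list()
    for (k in seq_len(n_mrna)) {
      nuclear <- runif(1) < config$nuclear_fraction
      for (try in 1:25) {
        p <- place(nuclear)
        if (min_sep_ok(p, mrna_pos, 7)) break
      }
      mrna_pos[[length(mrna_pos) + 1]] <- p
    }
    upa_positive <- runif(1) < config$upa_positive_prob
    n_upa <- if (upa_positive) 1L + rpois(1, config$upa_extra_lambda) else 0L
    upa_pos <- list()
    upa_coloc <- logical(0)
    for (k in seq_len(n_upa)) {
      coloc <- runif(1) < config$coloc_fraction
      nuclear <- runif(1) < config$nuclear_fraction
      if (coloc) {
        for (try in 1:25) {
          p <- place(nuclear)
          if (min_sep_ok(p, c(mrna_pos, upa_pos), 7)) break
        }
        # the co-detected molecule appears in both channels
        mrna_pos[[length(mrna_pos) + 1]] <- p
      } else {
        for (try in 1:25) {
          p <- place(nuclear)
          if (min_sep_ok(p, c(mrna_pos, upa_pos), 7)) break
        }
      }
      upa_pos[[length(upa_pos) + 1]] <- p
      upa_coloc <- c(upa_coloc, coloc)
    }
    for (p in mrna_pos) mrna <- add_stencil(mrna, p[1], p[2], st)
    for (p in upa_pos) upa <- add_stencil(upa, p[1], p[2], st)
    cells[[i]] <- tibble::tibble(
      cell = i, cy = cy, cx = cx, nucleus_radius = rn,
      n_mrna = length(mrna_pos), n_upa = n_upa,
      n_coloc = sum(upa_coloc), upa_positive = upa_positive
    )
    sp <- function(pos, ch, coloc) {
      if (length(pos) == 0) return(NULL)
      tibble::tibble(cell = i, channel = ch,
                     y = vapply(pos, `[`, 1, 1), x = vapply(pos, `[`, 1, 2),
                     colocalized = coloc)
    }
    spots[[length(spots) + 1]] <- dplyr::bind_rows(
      sp(mrna_pos, "mrna", NA),
      sp(upa_pos, "upa", if (n_upa > 0) upa_coloc else logical(0))
    )
  }
  noise_sd <- 1 / config$snr
  dapi <- dapi + matrix(rnorm(H * W, 0, noise_sd), H, W)
  mrna <- mrna + matrix(rnorm(H * W, 0, noise_sd), H, W)
  upa <- upa + matrix(rnorm(H * W, 0, noise_sd), H, W)
  list(dapi = dapi, mrna = mrna, upa = upa,
       cell_truth = dplyr::bind_rows(cells),
       spot_truth = dplyr::bind_rows(spots))
}

# ---------------------------------------------------------------------------
# presence table

#' Simulate a long-format speckle-presence table
#'
#' Bernoulli draws from a logistic model: per-cell speckle presence with
#' cell-type base probabilities (`cell_type_prob`, on the probability scale)
#' and donor effects drawn once per donor from
#' `N(0, donor_logit_sd)` on the logit scale.
#'
#' @param config A [sim_config()].
#' @param n_per_group Cells per donor x cell-type group.
#' @param cell_types Cell types to include (>= 2; default all configured).
#' @return Tibble `donor`, `cell_type`, `empty` (1 = no speckle), `present`.
#' @export
simulate_presence_table <- function(config, n_per_group = 250L,
                                    cell_types = names(config$cell_type_prob)) {
  stopifnot(length(cell_types) >= 2)
  set.seed(sub_seed(config, 5L))
  donors <- config$donors
  stopifnot(length(donors) >= 1)
  donor_eff <- rnorm(length(donors), 0, config$donor_logit_sd)
  grid <- tidyr::expand_grid(donor = donors, cell_type = cell_types)
  purrr::pmap_dfr(grid, function(donor, cell_type) {
    logit <- stats::qlogis(config$cell_type_prob[[cell_type]]) +
      donor_eff[match(donor, donors)]
    pr <- stats::plogis(logit)
    present <- rbinom(n_per_group, 1, pr)
    tibble::tibble(donor = donor, cell_type = cell_type,
                   empty = 1L - present, present = present)
  })
}
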