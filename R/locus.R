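#' Build a locus annotation
#'
#' The locus annotation is the shared coordinate authority for read
#' classification: a strand-aware exon model of a two-promoter gene (exons
#' numbered -1 and 1..11 as for human FOXP3), the cleavage/polyadenylation
#' site, the CAGE peaks of both promoters, the neighbouring gene's promoter
#' (used by read filter i), the whitelist of splice patterns, and any
#' alternative first-exon structures seen for novel canonical-promoter
#' transcripts.
#'
#' All coordinates are 0-based half-open (see [parse_span()] for conversion
#' from printed 1-based spans). Exons must be non-overlapping and ordered
#' along the direction of transcription; the PAS must fall inside the
#' terminal exon.
#'
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"` (human FOXP3 is minus-strand).
#' @param exons Tibble with columns `exon` (integer, -1 then 1..11 in
#'   transcription order), `start`, `end`.
#' @param pas_position Cleavage/polyadenylation site (single base, 0-based).
#' @param cage_peaks Tibble with columns `promoter_id`
#'   (`"canonical"`/`"alternative"`), `peak_number`, `start`, `end`, `summit`,
#'   `score`, and optionally `sigma` (positional SD in nt; defaulted to
#'   cluster width / 4 when absent, treating the cluster as ~±2 SD).
#' @param neighbor_promoter Length-2 numeric `c(start, end)`: promoter of the
#'   neighbouring gene (PPP1R3F for FOXP3); reads starting here are excluded.
#' @param allowed_splice_patterns List of integer vectors of skipped exon
#'   numbers; default none, delta-2, delta-7, delta-2+7.
#' @param alt_first_exons Tibble (`start`, `end`) of alternative first-exon
#'   structures generating "novel canonical" transcripts; may be empty.
#' @param cds_exons Integer vector of coding exon numbers.
#' @param utr3_min_nt Reads whose 3' end stops more than this many nt short of
#'   the PAS are discarded by filter (iii); default 50.
#' @param chrom_length Chromosome length (bounds for region construction).
#' @return An object of class `locus_annotation`.
#' @export
locus_annotation <- function(chrom, strand, exons, pas_position, cage_peaks,
                             neighbor_promoter,
                             allowed_splice_patterns = list(
                               integer(0), 2L, 7L, c(2L, 7L)
                             ),
                             alt_first_exons = tibble::tibble(
                               start = integer(), end = integer()
                             ),
                             cds_exons = 1:11,
                             utr3_min_nt = 50L,
                             chrom_length = .Machine$integer.max) {
  stopifnot(strand %in% c("+", "-"))
  exons <- tibble::as_tibble(exons)
  stopifnot(all(c("exon", "start", "end") %in% names(exons)))
  stopifnot(all(exons$start < exons$end))
  # ordered along transcription, non-overlapping
  txs <- tx_pos(exons$start, strand)
  txe <- tx_pos(exons$end, strand)
  lo <- pmin(txs, txe)
  hi <- pmax(txs, txe)
  if (any(diff(lo) <= 0) || any(hi[-nrow(exons)] > lo[-1])) {
    stop("exons must be non-overlapping and ordered along transcription",
         call. = FALSE)
  }
  term <- exons[nrow(exons), ]
  if (!point_in(pas_position, term$start, term$end)) {
    stop("pas_position must lie within the terminal exon", call. = FALSE)
  }
  cage_peaks <- tibble::as_tibble(cage_peaks)
  if (!"sigma" %in% names(cage_peaks)) cage_peaks$sigma <- NA_real_
  cage_peaks$sigma <- ifelse(
    is.na(cage_peaks$sigma),
    (cage_peaks$end - cage_peaks$start) / 4,
    cage_peaks$sigma
  )
  stopifnot(all(cage_peaks$score >= 0))
  stopifnot(all(point_in(cage_peaks$summit, cage_peaks$start, cage_peaks$end)))
  # filter (iii) threshold: the position `utr3_min_nt` transcription-upstream
  # of the PAS; reads whose 3' end has not reached it are rejected.
  pas_min_3prime <- if (strand == "+") {
    pas_position - utr3_min_nt
  } else {
    pas_position + utr3_min_nt
  }
  ann <- structure(
    list(
      chrom = chrom, strand = strand, exons = exons,
      pas_position = as.integer(pas_position),
      pas_min_3prime = as.integer(pas_min_3prime),
      utr3_min_nt = as.integer(utr3_min_nt),
      cage_peaks = cage_peaks,
      neighbor_promoter = as.integer(neighbor_promoter),
      allowed_splice_patterns = lapply(allowed_splice_patterns, as.integer),
      alt_first_exons = tibble::as_tibble(alt_first_exons),
      cds_exons = as.integer(cds_exons),
      chrom_length = chrom_length
    ),
    class = "locus_annotation"
  )
  ann
}

#' @export
print.locus_annotation <- function(x, ...) {
  cat("<locus_annotation> ", x$chrom, " (", x$strand, "), ",
      nrow(x$exons), " exons, PAS at ", x$pas_position, "\n", sep = "")
  invisible(x)
}

#' Build one region of probable transcription initiation
#'
#' A CAGE peak summit is broadened by `broaden_factor` times its positional
#' standard deviation on each side (asymmetric SDs may be supplied), then the
#' whole interval is translated `tech_shift_nt` bases in the direction of
#' transcription, because direct RNA sequencing misses the 5'-terminal 5-15 nt
#' of each molecule so observed 5' ends sit downstream of the true TSS.
#'
#' @param summit TSS position (0-based single base).
#' @param sigma Positional standard deviation in nt (upstream side if
#'   `sigma_downstream` given).
#' @param strand `"+"` or `"-"`.
#' @param broaden_factor Multiplier on sigma; default 5.
#' @param tech_shift_nt Technology shift in nt toward the direction of
#'   transcription; default 10.
#' @param sigma_downstream Optional downstream-side SD for asymmetric peaks.
#' @param chrom_length Clip bound.
#' @return Tibble with `start`, `end` (0-based half-open). For a symmetric
#'   peak the width is `2 * broaden_factor * sigma + 1`, independent of shift.
#' @examples
#' build_initiation_region(1000, sigma = 5, strand = "-") # [965, 1016)
#' @export
build_initiation_region <- function(summit, sigma, strand,
                                    broaden_factor = 5, tech_shift_nt = 10,
                                    sigma_downstream = NULL,
                                    chrom_length = .Machine$integer.max) {
  if (sigma < 0 || (!is.null(sigma_downstream) && sigma_downstream < 0)) {
    stop("sigma must be non-negative", call. = FALSE)
  }
  stopifnot(tech_shift_nt >= 0, broaden_factor > 0)
  sig_up <- sigma
  sig_dn <- if (is.null(sigma_downstream)) sigma else sigma_downstream
  up <- round(broaden_factor * sig_up)
  dn <- round(broaden_factor * sig_dn)
  # genomic extents: upstream is against transcription
  if (strand == "+") {
    start <- summit - up
    end <- summit + dn + 1L
    start <- start + tech_shift_nt
    end <- end + tech_shift_nt
  } else {
    start <- summit - dn
    end <- summit + up + 1L
    start <- start - tech_shift_nt
    end <- end - tech_shift_nt
  }
  if (start < 0 || end > chrom_length) {
    stop("initiation region falls outside the chromosome", call. = FALSE)
  }
  tibble::tibble(start = as.integer(start), end = as.integer(end))
}

#' Regions of probable transcription initiation for a locus
#'
#' Applies [build_initiation_region()] to every CAGE peak of the annotation
#' and checks that the resulting regions are pairwise non-overlapping (a
#' configuration error otherwise, since 5'-end assignment must be unique).
#'
#' @param ann A [locus_annotation()].
#' @inheritParams build_initiation_region
#' @return Tibble: `promoter_id`, `peak_number`, `start`, `end`.
#' @export
initiation_regions <- function(ann, broaden_factor = 5, tech_shift_nt = 10) {
  stopifnot(inherits(ann, "locus_annotation"))
  regions <- dplyr::bind_cols(
    ann$cage_peaks[, c("promoter_id", "peak_number")],
    purrr::map2_dfr(
      ann$cage_peaks$summit, ann$cage_peaks$sigma,
      function(s, sg) {
        build_initiation_region(s, sg, ann$strand, broaden_factor,
                                tech_shift_nt,
                                chrom_length = ann$chrom_length)
      }
    )
  )
  check_regions_disjoint(regions)
  nb <- ann$neighbor_promoter
  if (any(pmax(regions$start, nb[1]) < pmin(regions$end, nb[2]))) {
    stop("neighbor promoter overlaps an initiation region", call. = FALSE)
  }
  regions
}

check_regions_disjoint <- function(regions) {
  if (nrow(regions) > 1) {
    o <- order(regions$start)
    s <- regions$start[o]
    e <- regions$end[o]
    if (any(e[-length(e)] > s[-1])) {
      stop("initiation regions overlap; regions must be pairwise disjoint",
           call. = FALSE)
    }
  }
  invisible(regions)
}

#' Assign a 5' end to a promoter
#'
#' Returns the `promoter_id` of the unique initiation region containing each
#' position (half-open membership), or `NA` when the position falls outside
#' all regions — such reads are interpreted as decay products or aborted
#' sequencing and are excluded from classification.
#'
#' @param pos Vector of 5'-end genomic positions.
#' @param regions Tibble from [initiation_regions()] (pairwise disjoint).
#' @return Character vector of promoter ids (`NA` = outside all regions).
#' @export
assign_five_prime <- function(pos, regions) {
  check_regions_disjoint(regions)
  out <- rep(NA_character_, length(pos))
  for (k in seq_len(nrow(regions))) {
    hit <- point_in(pos, regions$start[k], regions$end[k])
    out[hit] <- regions$promoter_id[k]
  }
  out
}

#' Mirror a locus annotation
#'
#' Reflects every coordinate (`p -> C - 1 - p`, intervals `[s,e) -> [C-e,
#' C-s)`) and flips the strand. Used by mirror-symmetry property tests: all
#' classification logic must give identical results on the mirrored locus.
#'
#' @param ann A [locus_annotation()].
#' @param C Reflection constant (defaults to `chrom_length`).
#' @return The reflected `locus_annotation`.
#' @export
mirror_locus <- function(ann, C = ann$chrom_length) {
  refl_tbl <- function(tb) {
    r <- reflect_interval(tb$start, tb$end, C)
    tb$start <- r$start
    tb$end <- r$end
    tb
  }
  exons <- refl_tbl(ann$exons)
  peaks <- refl_tbl(ann$cage_peaks)
  peaks$summit <- reflect_pos(ann$cage_peaks$summit, C)
  nb <- reflect_interval(ann$neighbor_promoter[1], ann$neighbor_promoter[2], C)
  locus_annotation(
    chrom = ann$chrom,
    strand = if (ann$strand == "+") "-" else "+",
    exons = exons,
    pas_position = reflect_pos(ann$pas_position, C),
    cage_peaks = peaks,
    neighbor_promoter = c(nb$start, nb$end),
    allowed_splice_patterns = ann$allowed_splice_patterns,
    alt_first_exons = refl_tbl(ann$alt_first_exons),
    cds_exons = ann$cds_exons,
    utr3_min_nt = ann$utr3_min_nt,
    chrom_length = ann$chrom_length
  )
}

#' FOXP3 locus reference fixtures
#'
#' Small reference tables shipped with the package:
#' * `foxp3_cage_peaks()` — the robust FANTOM5 CAGE peaks of the human FOXP3
#'   locus (two canonical-promoter peaks, four alternative-promoter peaks),
#'   with cluster bounds, TSS summit and CAGE score, converted to 0-based
#'   half-open coordinates.
#' * `foxp3_initiation_regions()` — the two published regions of probable
#'   transcription initiation used in the dual-modality estimate (canonical
#'   peak 1 and alternative peak 1), with their short-read coverages. These
#'   are shipped verbatim as configuration: the per-peak SDs and asymmetries
#'   that produced them are not recoverable, so they are not reconstructed
#'   by [build_initiation_region()].
#' * `foxp3_dual_modality_counts()` — the worked long-read counts and
#'   coverages of the published non-adenylated:adenylated estimate. The
#'   alternative-region coverage is printed as 272 in prose but 279 in the
#'   equation; both are kept (`coverage_alt` follows the equation).
#' * `foxp3_rnascope_counts()` — per-donor totals of co-localization and
#'   UPA-only speckle events from the RNAscope experiment.
#'
#' @return Tibbles (or a named list for the dual-modality counts).
#' @export
foxp3_cage_peaks <- function() {
  raw <- readr::read_csv(
    system.file("extdata", "foxp3_cage_peaks.csv", package = "foxlocus"),
    show_col_types = FALSE
  )
  tibble::tibble(
    promoter_id = raw$promoter_id,
    peak_number = as.integer(raw$peak_number),
    chrom = raw$chrom,
    start = as.integer(raw$cluster_start) - 1L,
    end = as.integer(raw$cluster_end),
    summit = as.integer(raw$tss) - 1L,
    score = as.numeric(raw$score),
    sigma = NA_real_
  )
}

#' @rdname foxp3_cage_peaks
#' @export
foxp3_initiation_regions <- function() {
  raw <- readr::read_csv(
    system.file("extdata", "foxp3_initiation_regions.csv",
                package = "foxlocus"),
    show_col_types = FALSE
  )
  tibble::tibble(
    promoter_id = raw$promoter_id,
    peak_number = as.integer(raw$peak_number),
    chrom = raw$chrom,
    start = as.integer(raw$region_start) - 1L,
    end = as.integer(raw$region_end),
    ngs_coverage = as.numeric(raw$ngs_coverage)
  )
}

#' @rdname foxp3_cage_peaks
#' @export
foxp3_dual_modality_counts <- function() {
  jsonlite::read_json(
    system.file("extdata", "foxp3_dual_modality_counts.json",
                package = "foxlocus"),
    simplifyVector = TRUE
  )
}

#' @rdname foxp3_cage_peaks
#' @export
foxp3_rnascope_counts <- function() {
  readr::read_csv(
    system.file("extdata", "foxp3_rnascope_counts.csv", package = "foxlocus"),
    show_col_types = FALSE
  )
}
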