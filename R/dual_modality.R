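#' Per-base coverage track
#'
#' A minimal container for per-base, non-negative coverage over a stated
#' half-open interval: `counts[k]` is the coverage of genomic position
#' `start + k - 1`.
#'
#' @param chrom Chromosome name.
#' @param start 0-based start of the covered span.
#' @param counts Numeric vector of per-base counts (length = span width).
#' @return Object of class `coverage_track`.
#' @export
coverage_track <- function(chrom, start, counts) {
  stopifnot(all(counts >= 0), length(counts) > 0)
  structure(
    list(chrom = chrom, start = as.integer(start),
         end = as.integer(start) + length(counts), counts = as.numeric(counts)),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track> ", x$chrom, ":", x$start, "-", x$end,
      " (max ", max(x$counts), ")\n", sep = "")
  invisible(x)
}

#' Aggregate coverage over a region
#'
#' Mean or max of the per-base counts over a half-open region (the value a
#' genome browser reports for a zoomed window). Promoter-region comparisons
#' use the mean; the cross-technology terminal-exon anchor uses the max.
#'
#' @param track A [coverage_track()].
#' @param start,end Region bounds (0-based half-open), within the track span.
#' @param mode `"mean"` or `"max"`.
#' @return Non-negative scalar.
#' @export
region_coverage <- function(track, start, end, mode = c("mean", "max")) {
  mode <- match.arg(mode)
  stopifnot(inherits(track, "coverage_track"))
  if (end <= start) stop("empty region", call. = FALSE)
  if (start < track$start || end > track$end) {
    stop("region outside track span", call. = FALSE)
  }
  idx <- (start - track$start + 1L):(end - track$start)
  if (mode == "mean") mean(track$counts[idx]) else max(track$counts[idx])
}

#' Fraction of canonical-promoter coverage attributable to longFOXP3
#'
#' Coverage over the canonical initiation region, in either sequencing
#' modality, comes from intact canonical-promoter transcripts plus longFOXP3
#' molecules (intact or 5'-degraded) that span the region. The long-read data
#' measure each contribution directly:
#' `f = n_intact_longfoxp3 / (n_canonical_output + n_intact_longfoxp3 +
#' n_degraded_longfoxp3)`.
#'
#' @param n_canonical_output Reads assigned to the canonical promoter
#'   (canonical fl/delta-2 plus novel canonical transcripts).
#' @param n_intact_longfoxp3 Classified longFOXP3 reads.
#' @param n_degraded_longfoxp3 Decayed reads whose 5' end lies between the two
#'   promoters' regions but whose alignment fully spans the canonical
#'   initiation region.
#' @return Tibble `f`, `n_spanning` (denominator), `undefined` flag.
#' @export
estimate_f <- function(n_canonical_output, n_intact_longfoxp3,
                       n_degraded_longfoxp3) {
  stopifnot(n_canonical_output >= 0, n_intact_longfoxp3 >= 0,
            n_degraded_longfoxp3 >= 0)
  den <- n_canonical_output + n_intact_longfoxp3 + n_degraded_longfoxp3
  tibble::tibble(
    f = if (den > 0) n_intact_longfoxp3 / den else NA_real_,
    n_spanning = den,
    undefined = den == 0
  )
}

#' Non-adenylated to adenylated output ratio of the alternative promoter
#'
#' With `f` the fraction of canonical-region coverage due to adenylated
#' alternative-promoter transcripts (longFOXP3), `f * C_canon` predicts the
#' short-read coverage the adenylated output alone would produce over the
#' alternative initiation region; any excess must come from non-adenylated
#' species invisible to poly(A)-selected long reads:
#' `R = (C_alt - f * C_canon) / (f * C_canon)`.
#'
#' @param c_alt Short-read coverage over the alternative initiation region.
#' @param c_canon Short-read coverage over the canonical initiation region.
#' @param f Fraction from [estimate_f()].
#' @return Tibble `R` (unrounded), `R_rounded` (nearest integer, the printed
#'   convention), `negative` warning flag (no detectable non-adenylated
#'   excess) and `undefined` flag (`f * c_canon == 0`).
#' @export
estimate_nonadenylated_ratio <- function(c_alt, c_canon, f) {
  stopifnot(c_alt >= 0, c_canon >= 0)
  base <- f * c_canon
  if (is.na(base) || base == 0) {
    return(tibble::tibble(R = NA_real_, R_rounded = NA_real_,
                          negative = FALSE, undefined = TRUE))
  }
  R <- (c_alt - base) / base
  if (R < 0) {
    warning("estimated ratio is negative: no detectable non-adenylated excess",
            call. = FALSE)
  }
  tibble::tibble(R = R, R_rounded = round(R), negative = R < 0,
                 undefined = FALSE)
}

#' Cross-technology coverage anchor over the terminal exon
#'
#' Ratio of the maximum short-read (NGS) to maximum long-read (DRS) coverage
#' over the terminal exon; a value near 1 licenses direct visual comparison
#' of the two coverage tracks without normalization.
#'
#' @param ngs_track,drs_track [coverage_track()]s spanning the terminal exon.
#' @param start,end Terminal-exon bounds (half-open).
#' @return Tibble `ngs_max`, `drs_max`, `ratio` (`NA` when the DRS max is 0).
#' @export
coverage_ratio_exon11 <- function(ngs_track, drs_track, start, end) {
  ngs <- region_coverage(ngs_track, start, end, "max")
  drs <- region_coverage(drs_track, start, end, "max")
  tibble::tibble(ngs_max = ngs, drs_max = drs,
                 ratio = if (drs > 0) ngs / drs else NA_real_)
}

#' Long-read counts feeding the dual-modality estimator
#'
#' Extracts from a classified read table the three counts used by
#' [estimate_f()]: canonical-promoter output (canonical fl/delta-2 + novel
#' canonical), intact longFOXP3, and degraded longFOXP3 — reads excluded by
#' filter (ii) whose 5' end lies between the alternative regions and the
#' canonical region while their alignment fully spans the canonical
#' initiation region (these still contribute coverage over it).
#'
#' @param classified Output of [classify_reads()].
#' @param ann The [locus_annotation()].
#' @param regions Initiation regions used for classification.
#' @param canonical_peak Peak number anchoring the canonical region (default 1,
#'   the dominant peak).
#' @return Tibble with the three counts.
#' @export
dual_modality_counts <- function(classified, ann,
                                 regions = initiation_regions(ann),
                                 canonical_peak = 1L) {
  canon <- regions[regions$promoter_id == "canonical" &
                     regions$peak_number == canonical_peak, ]
  stopifnot(nrow(canon) == 1)
  alt <- regions[regions$promoter_id == "alternative", ]
  strand <- ann$strand
  canon_first_tx <- if (strand == "+") canon$start else -(canon$end - 1L)
  alt_last_tx <- if (strand == "+") max(alt$end - 1L) else max(-alt$start)
  n_canon <- sum(classified$class %in%
                   c("canonical_fl", "canonical_d2", "novel_canonical"))
  n_intact <- sum(classified$class %in%
                    c("longFOXP3_fl", "longFOXP3_d2", "longFOXP3_minor"))
  cand <- dplyr::filter(classified,
                        .data$exclusion_reason == "outside_init_region")
  n_degraded <- 0L
  if (nrow(cand) > 0) {
    five_tx <- tx_pos(cand$five_prime, strand)
    between <- five_tx > alt_last_tx & five_tx < canon_first_tx
    spans <- vapply(parse_blocks(cand$blocks), function(m) {
      any(m[, 1] <= canon$start & m[, 2] >= canon$end)
    }, TRUE)
    n_degraded <- sum(between & spans)
  }
  tibble::tibble(n_canonical_output = n_canon,
                 n_intact_longfoxp3 = n_intact,
                 n_degraded_longfoxp3 = as.integer(n_degraded))
}

#' End-to-end dual-modality estimate
#'
#' Runs the full estimator: long-read counts from a classified read table,
#' mean short-read coverage over the canonical and alternative initiation
#' regions, then `f` and `R`.
#'
#' @inheritParams dual_modality_counts
#' @param ngs_track Short-read [coverage_track()].
#' @param alt_peak Peak number anchoring the alternative region (default 1,
#'   the published choice that avoids diluting the mean over the whole
#'   promoter).
#' @param coverage_regions Regions over which the short-read coverage is
#'   averaged (defaults to `regions`; a downstream anchor such as
#'   [synthetic_anchor_regions()] avoids the fragment-length coverage ramp at
#'   the TSS).
#' @param round_f Round `f` to this many decimals before forming `R`
#'   (`NULL` = no rounding; the published chain uses 2).
#' @return Object of class `dual_modality` (list of inputs and estimates);
#'   `tidy()` returns a one-row tibble.
#' @export
dual_modality_report <- function(classified, ann, ngs_track,
                                 regions = initiation_regions(ann),
                                 canonical_peak = 1L, alt_peak = 1L,
                                 coverage_regions = regions,
                                 round_f = NULL) {
  counts <- dual_modality_counts(classified, ann, regions, canonical_peak)
  canon <- coverage_regions[coverage_regions$promoter_id == "canonical" &
                              coverage_regions$peak_number == canonical_peak, ]
  alt <- coverage_regions[coverage_regions$promoter_id == "alternative" &
                            coverage_regions$peak_number == alt_peak, ]
  stopifnot(nrow(canon) == 1, nrow(alt) == 1)
  c_canon <- region_coverage(ngs_track, canon$start, canon$end, "mean")
  c_alt <- region_coverage(ngs_track, alt$start, alt$end, "mean")
  fest <- estimate_f(counts$n_canonical_output, counts$n_intact_longfoxp3,
                     counts$n_degraded_longfoxp3)
  f_used <- if (is.null(round_f)) fest$f else round(fest$f, round_f)
  rest <- estimate_nonadenylated_ratio(c_alt, c_canon, f_used)
  structure(
    list(counts = counts, c_canon = c_canon, c_alt = c_alt,
         f = fest$f, f_used = f_used, R = rest$R, R_rounded = rest$R_rounded,
         negative = rest$negative, undefined = fest$undefined | rest$undefined),
    class = "dual_modality"
  )
}

#' @export
print.dual_modality <- function(x, ...) {
  cat("<dual_modality> f = ", round(x$f, 4), ", C_canon = ",
      round(x$c_canon, 1), ", C_alt = ", round(x$c_alt, 1),
      ", R = ", round(x$R, 3), " (~", x$R_rounded, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.dual_modality <- function(x, ...) {
  dplyr::bind_cols(
    x$counts,
    tibble::tibble(c_canon = x$c_canon, c_alt = x$c_alt, f = x$f,
                   f_used = x$f_used, R = x$R, R_rounded = x$R_rounded,
                   negative = x$negative, undefined = x$undefined)
  )
}

#' Write a dual-modality report as JSON
#' @param x A `dual_modality` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dual_modality_json <- function(x, path) {
  jsonlite::write_json(as.list(tidy(x)), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
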