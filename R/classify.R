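#' Long-read table conventions
#'
#' Aligned long reads are handled as a tibble with one row per read:
#' * `read_id` — unique identifier.
#' * `strand` — `"+"`/`"-"` of the alignment.
#' * `blocks` — aligned segments as `"start-end;start-end"` (0-based
#'   half-open, ascending genomic order); gaps between consecutive blocks are
#'   the implied introns.
#' * `polya_len` — poly(A) tail estimate in nt (`NA` when absent).
#' * `replicate_id` — biological replicate label.
#'
#' `read_five_prime()`/`read_three_prime()` return the transcription-start-side
#' and PAS-side terminal bases implied by `blocks` and `strand`.
#'
#' @param reads A read tibble.
#' @return Integer vectors of terminal base positions.
#' @name drs_reads
NULL

parse_blocks <- function(blocks) {
  lapply(strsplit(blocks, ";", fixed = TRUE), function(b) {
    m <- matrix(as.integer(unlist(strsplit(b, "-", fixed = TRUE))),
                ncol = 2, byrow = TRUE)
    colnames(m) <- c("start", "end")
    m
  })
}

format_blocks <- function(block_list) {
  vapply(block_list, function(m) {
    paste(sprintf("%d-%d", m[, 1], m[, 2]), collapse = ";")
  }, "")
}

#' @rdname drs_reads
#' @export
read_five_prime <- function(reads) {
  bl <- parse_blocks(reads$blocks)
  mapply(function(m, s) {
    if (s == "+") m[1, 1] else m[nrow(m), 2] - 1L
  }, bl, reads$strand)
}

#' @rdname drs_reads
#' @export
read_three_prime <- function(reads) {
  bl <- parse_blocks(reads$blocks)
  mapply(function(m, s) {
    if (s == "+") m[nrow(m), 2] - 1L else m[1, 1]
  }, bl, reads$strand)
}

# exon table in transcription coordinates: first/last base of each exon
exon_tx_table <- function(ann) {
  e <- ann$exons
  if (ann$strand == "+") {
    tibble::tibble(exon = e$exon, tx_first = e$start, tx_last = e$end - 1L,
                   start = e$start, end = e$end)
  } else {
    tibble::tibble(exon = e$exon, tx_first = -(e$end - 1L), tx_last = -e$start,
                   start = e$start, end = e$end)
  }
}

# blocks (genomic, ascending) -> tx-ordered intervals [tx_first, tx_last]
blocks_tx <- function(m, strand) {
  if (strand == "+") {
    out <- cbind(tx_first = m[, 1], tx_last = m[, 2] - 1L)
  } else {
    out <- cbind(tx_first = -(m[, 2] - 1L), tx_last = -m[, 1])
    out <- out[rev(seq_len(nrow(out))), , drop = FALSE]
  }
  out
}

# Splice-pattern validation against the annotation (rule iv). Returns
# list(ok, skipped, novel_first, reason).
check_splice <- function(m, ann, ext, junction_slack = 0L,
                         novel_overlap = 0.5) {
  strand <- ann$strand
  txb <- blocks_tx(m, strand)
  # footprint: every base must fall in an exon or in the 5' flank upstream of
  # the first exon (the extended first-exon region used by the alternative
  # promoter); anything else (retained intron, readthrough) is aberrant.
  for (k in seq_len(nrow(m))) {
    s <- m[k, 1]; e <- m[k, 2]
    covered <- 0L
    for (j in seq_len(nrow(ann$exons))) {
      covered <- covered +
        max(0L, min(e, ann$exons$end[j]) - max(s, ann$exons$start[j]))
    }
    # flank portion (contiguous with the first exon in transcription order)
    if (strand == "+") {
      covered <- covered + max(0L, min(e, ext$first_exon_start) - s)
    } else {
      covered <- covered + max(0L, e - max(s, ext$first_exon_end))
    }
    if (covered + junction_slack * 2L < e - s) {
      return(list(ok = FALSE, skipped = integer(), novel_first = FALSE,
                  reason = "intronic_bases"))
    }
  }
  ex <- ext$exon_tx
  skipped <- integer()
  novel_first <- FALSE
  nj <- nrow(txb) - 1L
  if (nj > 0) {
    for (k in seq_len(nj)) {
      donor <- txb[k, "tx_last"]
      acceptor <- txb[k + 1L, "tx_first"]
      di <- which(abs(ex$tx_last - donor) <= junction_slack)
      ai <- which(abs(ex$tx_first - acceptor) <= junction_slack)
      if (length(di) == 0 && k == 1L && nrow(ann$alt_first_exons) > 0) {
        # maybe a novel first-exon structure: donor must match a variant's
        # 3' edge and the 5' block must overlap the variant sufficiently
        v <- ann$alt_first_exons
        v_tx_last <- if (strand == "+") v$end - 1L else -v$start
        vi <- which(abs(v_tx_last - donor) <= junction_slack)
        if (length(vi) == 1) {
          b1 <- if (strand == "+") m[1, , drop = FALSE] else m[nrow(m), , drop = FALSE]
          frac <- overlap_frac(b1[1, 1], b1[1, 2], v$start[vi], v$end[vi])
          if (frac >= novel_overlap) {
            novel_first <- TRUE
            di <- 1L # placeholder: variant sits in place of the first exon
          }
        }
      }
      if ((length(di) != 1 && !(novel_first && k == 1L)) || length(ai) != 1) {
        return(list(ok = FALSE, skipped = integer(), novel_first = FALSE,
                    reason = "unannotated_junction"))
      }
      if (!(novel_first && k == 1L)) {
        if (ai <= di) {
          return(list(ok = FALSE, skipped = integer(), novel_first = FALSE,
                      reason = "unannotated_junction"))
        }
        if (ai > di + 1L) {
          skipped <- c(skipped, ex$exon[(di + 1L):(ai - 1L)])
        }
      }
    }
  }
  ok <- any(vapply(ann$allowed_splice_patterns,
                   function(p) setequal(p, skipped), TRUE))
  list(ok = ok, skipped = sort(skipped), novel_first = novel_first,
       reason = if (ok) "none" else "disallowed_skip")
}

#' Filter and classify long reads
#'
#' Applies the read filters in order and assigns each surviving read to a
#' promoter and isoform class:
#'
#' 1. (i) reads whose 5' end maps to the neighbouring gene's promoter are
#'    excluded (`neighbor_promoter`);
#' 2. (ii) reads whose 5' end falls outside every region of probable
#'    transcription initiation are excluded as decay products or aborted
#'    sequencing (`outside_init_region`);
#' 3. alternative-promoter reads whose 3' end stops before the first coding
#'    exon are the *short upstream transcript* class and are exempt from the
#'    remaining filters (they terminate early by definition);
#' 4. (iii) reads whose 3'-most base stops transcription-side of the position
#'    `utr3_min_nt` (default 50 nt) short of the PAS are excluded
#'    (`short_3utr`);
#' 5. (iv) reads with retained introns or splice junctions not matching the
#'    annotation under an allowed exon-skip signature are excluded
#'    (`aberrant_structure`).
#'
#' Surviving reads are labelled `canonical_fl`/`canonical_d2` (annotated first
#' exon, exon-2 status), `novel_canonical` (alternative first-exon structure),
#' `longFOXP3_fl`/`longFOXP3_d2`/`longFOXP3_minor` (alternative promoter,
#' reaching the terminal exon, by skip signature) or `short_upstream`.
#' A read violating several rules reports the first one.
#'
#' @param reads Read tibble (see [drs_reads]).
#' @param ann A [locus_annotation()].
#' @param regions Initiation regions; default [initiation_regions()] of `ann`.
#' @param junction_slack Junction matching tolerance in nt (default 0: exact).
#' @param novel_overlap Minimum fraction of the 5' block overlapping an
#'   alternative first-exon structure to call `novel_canonical` (default 0.5).
#' @return The input tibble plus columns `five_prime`, `three_prime`,
#'   `promoter`, `class`, `exclusion_reason`, `skip_signature`.
#' @export
classify_reads <- function(reads, ann, regions = initiation_regions(ann),
                           junction_slack = 0L, novel_overlap = 0.5) {
  stopifnot(inherits(ann, "locus_annotation"))
  reads <- tibble::as_tibble(reads)
  if (nrow(reads) == 0) {
    return(dplyr::mutate(reads, five_prime = integer(), three_prime = integer(),
                         promoter = character(), class = character(),
                         exclusion_reason = character(),
                         skip_signature = character()))
  }
  bl <- parse_blocks(reads$blocks)
  if (any(vapply(bl, nrow, 1L) == 0)) {
    stop("read with zero aligned blocks", call. = FALSE)
  }
  ex <- exon_tx_table(ann)
  first_exon <- ann$exons[1, ]
  ext <- list(
    exon_tx = ex,
    first_exon_start = first_exon$start,
    first_exon_end = first_exon$end
  )
  exon1 <- ann$exons[ann$exons$exon == 1L, ]
  exon1_first_tx <- if (ann$strand == "+") exon1$start else -(exon1$end - 1L)
  strand <- ann$strand
  five <- mapply(function(m, s) {
    if (s == "+") m[1, 1] else m[nrow(m), 2] - 1L
  }, bl, reads$strand)
  three <- mapply(function(m, s) {
    if (s == "+") m[nrow(m), 2] - 1L else m[1, 1]
  }, bl, reads$strand)
  promoter <- assign_five_prime(five, regions)
  n <- nrow(reads)
  class <- character(n)
  reason <- rep("none", n)
  sig <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (reads$strand[i] != strand) {
      class[i] <- "excluded"; reason[i] <- "aberrant_structure"; next
    }
    if (point_in(five[i], ann$neighbor_promoter[1], ann$neighbor_promoter[2])) {
      class[i] <- "excluded"; reason[i] <- "neighbor_promoter"; next
    }
    if (is.na(promoter[i])) {
      class[i] <- "excluded"; reason[i] <- "outside_init_region"; next
    }
    if (promoter[i] == "alternative" &&
        tx_pos(three[i], strand) < exon1_first_tx) {
      class[i] <- "short_upstream"; next
    }
    if (tx_pos(three[i], strand) < tx_pos(ann$pas_min_3prime, strand)) {
      class[i] <- "excluded"; reason[i] <- "short_3utr"; next
    }
    sp <- check_splice(bl[[i]], ann, ext, junction_slack, novel_overlap)
    if (!sp$ok) {
      class[i] <- "excluded"; reason[i] <- "aberrant_structure"; next
    }
    sig[i] <- paste(sp$skipped, collapse = "+")
    if (promoter[i] == "alternative") {
      class[i] <- if (setequal(sp$skipped, integer(0))) {
        "longFOXP3_fl"
      } else if (setequal(sp$skipped, 2L)) {
        "longFOXP3_d2"
      } else {
        "longFOXP3_minor"
      }
    } else if (sp$novel_first) {
      class[i] <- "novel_canonical"
    } else {
      class[i] <- if (2L %in% sp$skipped) "canonical_d2" else "canonical_fl"
    }
  }
  dplyr::mutate(reads, five_prime = as.integer(five),
                three_prime = as.integer(three),
                promoter = promoter, class = class,
                exclusion_reason = reason, skip_signature = sig)
}

read_classes <- c("canonical_fl", "canonical_d2", "novel_canonical",
                  "longFOXP3_fl", "longFOXP3_d2", "longFOXP3_minor",
                  "short_upstream")

safe_ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)

#' Abundance report for classified reads
#'
#' Per-replicate class counts and the relative-abundance ratios of the
#' canonical transcript (fl + delta-2) to the novel canonical, longFOXP3 and
#' short-upstream classes, with cross-replicate medians (the median of an
#' even number of replicates is the mean of the central pair), plus the
#' pooled promoter output ratio
#' `(canonical + novel canonical) / (longFOXP3 + short upstream)`.
#' Ratios with a zero denominator are reported as `NA`, never as infinities.
#'
#' @param classified Output of [classify_reads()].
#' @return An object of class `abundance_report` with elements
#'   `per_replicate` (counts and ratios), `medians`, `pooled` (pooled class
#'   counts) and `promoter_output_ratio`. `tidy()` returns the per-replicate
#'   table.
#' @export
abundance_report <- function(classified) {
  stopifnot(nrow(classified) > 0)
  kept <- dplyr::filter(classified, .data$class != "excluded")
  counts <- kept |>
    dplyr::count(.data$replicate_id, .data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L)
  for (cl in read_classes) {
    if (!cl %in% names(counts)) counts[[cl]] <- 0L
  }
  per_rep <- counts |>
    dplyr::mutate(
      canonical = .data$canonical_fl + .data$canonical_d2,
      longFOXP3 = .data$longFOXP3_fl + .data$longFOXP3_d2 +
        .data$longFOXP3_minor,
      ratio_canonical_novel = safe_ratio(.data$canonical,
                                         .data$novel_canonical),
      ratio_canonical_longfoxp3 = safe_ratio(.data$canonical,
                                             .data$longFOXP3),
      ratio_canonical_short = safe_ratio(.data$canonical,
                                         .data$short_upstream)
    ) |>
    dplyr::arrange(.data$replicate_id)
  med <- function(x) if (all(is.na(x))) NA_real_ else median(x, na.rm = TRUE)
  medians <- tibble::tibble(
    ratio = c("canonical:novel_canonical", "canonical:longFOXP3",
              "canonical:short_upstream"),
    median = c(med(per_rep$ratio_canonical_novel),
               med(per_rep$ratio_canonical_longfoxp3),
               med(per_rep$ratio_canonical_short))
  )
  pooled <- colSums(per_rep[, read_classes])
  num <- pooled[["canonical_fl"]] + pooled[["canonical_d2"]] +
    pooled[["novel_canonical"]]
  den <- pooled[["longFOXP3_fl"]] + pooled[["longFOXP3_d2"]] +
    pooled[["longFOXP3_minor"]] + pooled[["short_upstream"]]
  structure(
    list(per_replicate = per_rep, medians = medians, pooled = pooled,
         promoter_output_ratio = safe_ratio(num, den),
         n_excluded = sum(classified$class == "excluded"),
         n_total = nrow(classified)),
    class = "abundance_report"
  )
}

#' @export
print.abundance_report <- function(x, ...) {
  cat("<abundance_report> ", x$n_total, " reads (", x$n_excluded,
      " excluded)\n", sep = "")
  print(x$medians)
  cat("promoter output ratio (canonical:alternative): ",
      round(x$promoter_output_ratio, 2), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.abundance_report <- function(x, ...) x$per_replicate

#' @export
glance.abundance_report <- function(x, ...) {
  tibble::tibble(
    n_total = x$n_total, n_excluded = x$n_excluded,
    promoter_output_ratio = x$promoter_output_ratio,
    median_canonical_longfoxp3 = x$medians$median[2],
    median_canonical_short = x$medians$median[3]
  )
}

#' Splice-variant fractions of longFOXP3 reads
#'
#' Fractions of the full-length, delta-2 and minor splice variants among
#' longFOXP3 reads, per replicate (summing to 1) with cross-replicate means.
#'
#' @param classified Output of [classify_reads()].
#' @return List with `per_replicate` and `means` tibbles; replicates without
#'   longFOXP3 reads are flagged with `NA` fractions.
#' @export
splice_fractions <- function(classified) {
  lf <- dplyr::filter(classified,
                      .data$class %in% c("longFOXP3_fl", "longFOXP3_d2",
                                         "longFOXP3_minor"))
  reps <- unique(classified$replicate_id)
  per_rep <- purrr::map_dfr(reps, function(r) {
    x <- lf$class[lf$replicate_id == r]
    n <- length(x)
    tibble::tibble(
      replicate_id = r, n_longfoxp3 = n,
      frac_fl = if (n > 0) mean(x == "longFOXP3_fl") else NA_real_,
      frac_d2 = if (n > 0) mean(x == "longFOXP3_d2") else NA_real_,
      frac_minor = if (n > 0) mean(x == "longFOXP3_minor") else NA_real_
    )
  })
  means <- tibble::tibble(
    frac_fl = mean(per_rep$frac_fl, na.rm = TRUE),
    frac_d2 = mean(per_rep$frac_d2, na.rm = TRUE),
    frac_minor = mean(per_rep$frac_minor, na.rm = TRUE)
  )
  means$frac_fl_d2 <- means$frac_fl + means$frac_d2
  list(per_replicate = per_rep, means = means)
}

#' Cleavage-site offsets from the annotated PAS
#'
#' Signed distance of each non-excluded read's 3' end from the annotated
#' cleavage/polyadenylation site, positive in the direction of transcription
#' (a read ending past the PAS has a positive offset on either strand).
#'
#' @param classified Output of [classify_reads()].
#' @param ann The [locus_annotation()].
#' @param terminal_only Restrict to reads of classes reaching the terminal
#'   exon (default TRUE: short-upstream reads end elsewhere by definition).
#' @return Tibble `read_id`, `class`, `offset`.
#' @export
cleavage_offsets <- function(classified, ann, terminal_only = TRUE) {
  kept <- dplyr::filter(classified, .data$class != "excluded")
  if (terminal_only) {
    kept <- dplyr::filter(kept, .data$class != "short_upstream")
  }
  tibble::tibble(
    read_id = kept$read_id, class = kept$class,
    offset = tx_pos(kept$three_prime, ann$strand) -
      tx_pos(ann$pas_position, ann$strand)
  )
}

#' @rdname cleavage_offsets
#' @param offsets Tibble from `cleavage_offsets()`.
#' @param window Half-width of the central histogram (default 10).
#' @return `cleavage_histogram()`: tibble `bin` (factor including overflow
#'   bins) and `n`.
#' @export
cleavage_histogram <- function(offsets, window = 10L) {
  lv <- c(paste0("<", -window), as.character(seq(-window, window)),
          paste0(">", window))
  binned <- cut(
    pmax(pmin(offsets$offset, window + 1L), -window - 1L),
    breaks = c(-Inf, seq(-window - 0.5, window + 0.5), Inf),
    labels = lv
  )
  tibble::tibble(bin = factor(lv, levels = lv),
                 n = as.integer(table(binned)[lv]))
}

#' Poly(A) tail statistics per class group
#'
#' Mean, median and modal tail length per group; the mode is the most
#' frequent integer-rounded length (ties broken toward the smallest length).
#'
#' @param classified Output of [classify_reads()] (or any tibble with
#'   `polya_len` and a grouping column).
#' @param group Column name to group by (default `"class"`).
#' @return Tibble `group`, `n`, `mean`, `median`, `mode`; groups with no tail
#'   lengths report `NA`.
#' @export
polya_stats <- function(classified, group = "class") {
  x <- dplyr::filter(classified, !is.na(.data$polya_len))
  x |>
    dplyr::group_by(group = .data[[group]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$polya_len),
      median = median(.data$polya_len),
      mode = polya_mode(.data$polya_len),
      .groups = "drop"
    )
}

polya_mode <- function(x) {
  if (length(x) == 0) return(NA_real_)
  tb <- table(round(x))
  as.numeric(names(tb)[which.max(tb)]) # which.max takes the first = smallest
}

#' Compare poly(A) tail lengths between two groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test; the reported `U` is the
#' rank-sum statistic for `x`. Exact when the combined sample size is at most
#' 20 and there are no ties, normal approximation with tie correction
#' otherwise.
#'
#' @param x,y Numeric vectors of tail lengths.
#' @return Tibble `U`, `p_value`, `method`.
#' @export
polya_compare <- function(x, y) {
  exact <- (length(x) + length(y)) <= 20 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  tibble::tibble(U = unname(wt$statistic), p_value = wt$p.value,
                 method = if (exact) "exact" else "normal approximation")
}
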