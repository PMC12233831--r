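#' Otsu threshold of an intensity image
#'
#' Global threshold maximizing between-class variance over a 256-bin
#' histogram. Returns `Inf` for constant images (nothing to segment).
#'
#' @param img Numeric matrix.
#' @param nbins Histogram bins (default 256).
#' @return Scalar threshold on the intensity scale of `img`.
#' @export
otsu_threshold <- function(img, nbins = 256L) {
  v <- as.numeric(img)
  lo <- min(v)
  hi <- max(v)
  if (hi - lo < .Machine$double.eps) return(Inf)
  h <- tabulate(pmin(nbins, 1L + floor((v - lo) / (hi - lo) * nbins)), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  k <- which.max(sb)
  lo + k / nbins * (hi - lo)
}

#' Segment nuclei from a DAPI image
#'
#' Primary-object segmentation: automatic global (Otsu) threshold,
#' 8-connected labelling, optional splitting of touching nuclei by seeded
#' watershed on the Euclidean distance transform, and size filtering to a
#' configured equivalent-diameter range.
#'
#' @param dapi 2-D numeric intensity matrix.
#' @param min_diameter,max_diameter Accepted equivalent-diameter range in
#'   pixels (defaults 10 and 80).
#' @param split_touching Split touching nuclei by distance-transform watershed
#'   (default TRUE).
#' @return Integer label matrix (0 = background, labels 1..k). A blank image
#'   yields 0 labels.
#' @export
segment_nuclei <- function(dapi, min_diameter = 10, max_diameter = 80,
                           split_touching = TRUE) {
  stopifnot(is.matrix(dapi))
  thr <- otsu_threshold(dapi)
  mask <- fill_holes(dapi > thr)
  if (!any(mask)) return(matrix(0L, nrow(dapi), ncol(dapi)))
  lab <- .cc_label(mask)
  if (split_touching) {
    edt <- .dist_to_background(mask, as.integer(ceiling(max_diameter / 2)) + 2L)
    # seeds: plateaus of local maxima of the distance transform; the plateau
    # window is half the minimum nucleus diameter so rim irregularities do
    # not seed spurious fragments
    r_seed <- max(3L, as.integer(ceiling(min_diameter / 2)))
    dil <- .grey_morph(edt, r_seed, TRUE)
    maxima <- mask & (edt >= dil - 1e-9) & (edt >= min_diameter / 4)
    if (any(maxima)) {
      seeds <- .cc_label(maxima)
      lab <- .watershed_flood(edt, seeds, mask)
    }
  }
  filter_labels_by_size(lab, min_diameter, max_diameter)
}

# set to TRUE any background component not touching the image border
# (noise holes inside nuclei corrupt the distance transform and compartment
# lookups)
fill_holes <- function(mask) {
  bg <- .cc_label(!mask)
  if (max(bg) == 0) return(mask)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  holes <- setdiff(seq_len(max(bg)), border)
  if (length(holes) > 0) {
    mask[matrix(bg %in% holes, nrow(mask))] <- TRUE
  }
  mask
}

filter_labels_by_size <- function(lab, min_diameter, max_diameter) {
  if (max(lab) == 0) return(lab)
  areas <- tabulate(lab[lab > 0], max(lab))
  dia <- 2 * sqrt(areas / pi)
  keep <- which(dia >= min_diameter & dia <= max_diameter)
  relabel <- integer(max(lab))
  relabel[keep] <- seq_along(keep)
  out <- lab
  out[out > 0] <- relabel[out[out > 0]]
  out
}

#' Expand nuclei into cell and cytoplasm masks
#'
#' Each nucleus is dilated isotropically by a physical radius (default 3 um,
#' the approximate cytoplasm size of a T cell; at 104 nm pixels that is 29
#' pixels). Where expansions collide, pixels go to the nearest nucleus
#' (Voronoi partition on exact Euclidean distance). The cytoplasm is the cell
#' minus its nucleus.
#'
#' @param nuclei Integer label matrix from [segment_nuclei()].
#' @param radius_um Expansion radius in micrometres (default 3).
#' @param pixel_size_nm Pixel size in nanometres (default 104).
#' @return List `cells`, `cytoplasm` (integer label matrices) and
#'   `radius_px` (the applied dilation radius in pixels).
#' @export
expand_cells <- function(nuclei, radius_um = 3, pixel_size_nm = 104) {
  stopifnot(radius_um >= 0, pixel_size_nm > 0)
  r <- as.integer(round(radius_um * 1000 / pixel_size_nm))
  cells <- if (r > 0) .expand_labels(nuclei, r) else nuclei
  cyto <- cells
  cyto[nuclei > 0] <- 0L
  list(cells = cells, cytoplasm = cyto, radius_px = r)
}

#' Detect diffraction-limited spots in a fluorescence channel
#'
#' Spot enhancement by white top-hat (opening subtracted from the image) with
#' a structuring radius near the expected spot radius, Otsu threshold on the
#' enhanced image, 8-connected labelling, and a minimum-area filter. Each
#' connected component counts as one spot: merged blobs (agglomerates) are
#' deliberately counted once.
#'
#' Thresholding combines the Otsu value with a robust-background floor
#' (`median + robust_k * MAD` of the enhanced image): with diffraction-limited
#' spots occupying well under 1% of pixels, a plain two-class Otsu threshold
#' can split the background mode instead of separating spots from it; the
#' floor is inactive on high-contrast images.
#'
#' @param img 2-D numeric intensity matrix.
#' @param spot_radius Structuring-element radius in pixels (default 4).
#' @param min_area Minimum spot area in pixels (default 3).
#' @param robust_k Robust-background floor multiplier (default 4; set to
#'   `-Inf` for pure Otsu).
#' @return Object of class `spot_set`: list with `labels` (integer matrix)
#'   and `spots` (tibble `spot_id`, `area`, `row`, `col` centroid).
#' @export
detect_spots <- function(img, spot_radius = 4L, min_area = 3L, robust_k = 4) {
  stopifnot(is.matrix(img))
  opened <- .grey_morph(.grey_morph(img, spot_radius, FALSE), spot_radius, TRUE)
  enhanced <- img - opened
  thr <- max(otsu_threshold(enhanced),
             median(enhanced) + robust_k * stats::mad(enhanced))
  mask <- enhanced > thr
  empty <- function() {
    structure(list(labels = matrix(0L, nrow(img), ncol(img)),
                   spots = tibble::tibble(spot_id = integer(),
                                          area = integer(),
                                          row = numeric(), col = numeric())),
              class = "spot_set")
  }
  if (!any(mask)) return(empty())
  lab <- .cc_label(mask)
  areas <- tabulate(lab[lab > 0], max(lab))
  keep <- which(areas >= min_area)
  relabel <- integer(max(lab))
  relabel[keep] <- seq_along(keep)
  lab[lab > 0] <- relabel[lab[lab > 0]]
  if (max(lab) == 0) return(empty())
  idx <- which(lab > 0, arr.ind = TRUE)
  lv <- lab[lab > 0]
  spots <- tibble::tibble(
    spot_id = sort(unique(lv)),
    area = as.integer(tabulate(lv, max(lv))[sort(unique(lv))]),
    row = as.numeric(tapply(idx[, 1], lv, mean)),
    col = as.numeric(tapply(idx[, 2], lv, mean))
  )
  structure(list(labels = lab, spots = spots), class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat("<spot_set> ", nrow(x$spots), " spots\n", sep = "")
  invisible(x)
}

#' Tag UPA spots co-localizing with mRNA spots
#'
#' A UPA spot co-localizes when the fraction of its own area overlapped by
#' the union of all mRNA spots is at least `min_overlap` (default 0.3, the
#' MaskObjects convention: the UPA object is masked by the mRNA objects and
#' the overlap is normalized to the UPA spot's area). The alternative
#' normalization — relative to the mRNA spot — is available via
#' `normalize = "mrna"`.
#'
#' @param upa,mrna `spot_set` objects from [detect_spots()] on the two
#'   channels (same image shape).
#' @param min_overlap Required overlap fraction in `(0, 1]` (default 0.3).
#' @param normalize `"upa"` (default) or `"mrna"`.
#' @return The `upa` spot tibble plus `overlap_frac` and `colocalized`;
#'   the applied threshold and normalization are recorded as attributes.
#' @export
colocalize <- function(upa, mrna, min_overlap = 0.3,
                       normalize = c("upa", "mrna")) {
  normalize <- match.arg(normalize)
  stopifnot(min_overlap > 0, min_overlap <= 1)
  stopifnot(inherits(upa, "spot_set"), inherits(mrna, "spot_set"))
  spots <- upa$spots
  if (nrow(spots) == 0) {
    out <- dplyr::mutate(spots, overlap_frac = numeric(),
                         colocalized = logical())
  } else {
    mrna_mask <- mrna$labels > 0
    inter <- tabulate(upa$labels[upa$labels > 0 & mrna_mask],
                      nbins = max(upa$labels))
    denom <- if (normalize == "upa") {
      spots$area
    } else {
      # area of the overlapped mRNA spot(s): use the union area of mRNA spots
      # touched by this UPA spot
      vapply(spots$spot_id, function(id) {
        touched <- unique(mrna$labels[upa$labels == id & mrna_mask])
        if (length(touched) == 0) 1L else
          sum(tabulate(mrna$labels[mrna$labels > 0],
                       max(mrna$labels))[touched])
      }, 1L)
    }
    frac <- inter[spots$spot_id] / denom
    out <- dplyr::mutate(spots, overlap_frac = frac,
                         colocalized = frac >= min_overlap)
  }
  attr(out, "min_overlap") <- min_overlap
  attr(out, "normalize") <- normalize
  out
}

#' Quantify one RNA-FISH field
#'
#' Full per-field pipeline: nuclei from the DAPI channel, cell/cytoplasm
#' expansion, spot detection in the mRNA and UPA channels, co-localization
#' tagging of UPA spots, and per-cell per-compartment counting. Spots are
#' assigned to the cell whose mask contains their centroid (spots outside
#' every cell are dropped); the compartment is nuclear iff the centroid lies
#' in the nucleus mask — a 2-D projection convention that overestimates
#' nuclear localization, so compartment fractions are semi-quantitative.
#'
#' @param field List with numeric matrices `dapi`, `mrna`, `upa` of identical
#'   shape.
#' @param pixel_size_nm Pixel size (default 104).
#' @param expand_um Cell expansion radius in um (default 3).
#' @param spot_radius,min_area Passed to [detect_spots()].
#' @param min_overlap Co-localization threshold (default 0.3).
#' @param nucleus_diameter Accepted nucleus diameter range in px,
#'   `c(min, max)`.
#' @return List with `cells` (per-cell tibble: counts per channel and
#'   compartment plus co-localization counts) and `spots` (per-spot tibble
#'   with channel, cell, compartment, co-localization tag).
#' @export
quantify_fish_field <- function(field, pixel_size_nm = 104, expand_um = 3,
                                spot_radius = 4L, min_area = 3L,
                                min_overlap = 0.3,
                                nucleus_diameter = c(10, 80)) {
  stopifnot(all(c("dapi", "mrna", "upa") %in% names(field)))
  stopifnot(all(dim(field$mrna) == dim(field$dapi)),
            all(dim(field$upa) == dim(field$dapi)))
  nuclei <- segment_nuclei(field$dapi, nucleus_diameter[1], nucleus_diameter[2])
  ex <- expand_cells(nuclei, expand_um, pixel_size_nm)
  mrna <- detect_spots(field$mrna, spot_radius, min_area)
  upa <- detect_spots(field$upa, spot_radius, min_area)
  upa_tagged <- colocalize(upa, mrna, min_overlap)
  locate <- function(spots, channel, coloc = NULL) {
    if (nrow(spots) == 0) {
      return(tibble::tibble(channel = character(), spot_id = integer(),
                            area = integer(), row = numeric(), col = numeric(),
                            cell_id = integer(), compartment = character(),
                            colocalized = logical()))
    }
    ri <- pmin(pmax(round(spots$row), 1), nrow(nuclei))
    ci <- pmin(pmax(round(spots$col), 1), ncol(nuclei))
    at <- cbind(ri, ci)
    tibble::tibble(
      channel = channel,
      spot_id = spots$spot_id, area = spots$area,
      row = spots$row, col = spots$col,
      cell_id = ex$cells[at],
      compartment = dplyr::case_when(
        ex$cells[at] == 0L ~ "none",
        nuclei[at] > 0L ~ "nuclear",
        TRUE ~ "cytoplasmic"
      ),
      colocalized = if (is.null(coloc)) NA else coloc
    )
  }
  spot_tbl <- dplyr::bind_rows(
    locate(mrna$spots, "mrna"),
    locate(upa_tagged, "upa", upa_tagged$colocalized)
  )
  n_cells <- max(nuclei)
  count_in <- function(f) {
    if (nrow(spot_tbl) == 0) return(integer(n_cells))
    sel <- spot_tbl[f(spot_tbl) & spot_tbl$cell_id > 0, ]
    tabulate(sel$cell_id, n_cells)
  }
  cells <- tibble::tibble(
    cell_id = seq_len(n_cells),
    nucleus_area = as.integer(tabulate(nuclei[nuclei > 0], n_cells)),
    n_mrna = count_in(function(s) s$channel == "mrna"),
    n_mrna_nuclear = count_in(function(s) s$channel == "mrna" &
                                s$compartment == "nuclear"),
    n_upa = count_in(function(s) s$channel == "upa"),
    n_upa_nuclear = count_in(function(s) s$channel == "upa" &
                               s$compartment == "nuclear"),
    n_coloc = count_in(function(s) s$channel == "upa" &
                         !is.na(s$colocalized) & s$colocalized),
    n_coloc_nuclear = count_in(function(s) s$channel == "upa" &
                                 !is.na(s$colocalized) & s$colocalized &
                                 s$compartment == "nuclear")
  )
  list(cells = cells, spots = spot_tbl)
}

#' Culture-level summary of per-cell speckle counts
#'
#' Aggregates per-cell counts (possibly from several fields of one culture)
#' into the culture-level quantities: number of cells, percentage of cells
#' with at least one speckle per channel, spots-per-cell summaries, the
#' pooled and per-cell-median co-localization percentages (both are reported
#' because the published convention is ambiguous), nuclear percentages per
#' spot category, and the ratio of UPA-only events to co-localization events
#' (undefined when no co-localization events exist).
#'
#' @param cells Per-cell tibble from [quantify_fish_field()] (rows from
#'   multiple fields may be bound together).
#' @return Object of class `culture_summary`; `tidy()` gives a one-row
#'   tibble.
#' @export
summarize_culture <- function(cells) {
  stopifnot(nrow(cells) > 0)
  tot_upa <- sum(cells$n_upa)
  tot_coloc <- sum(cells$n_coloc)
  tot_mrna <- sum(cells$n_mrna)
  per_cell_coloc <- ifelse(cells$n_upa > 0,
                           100 * cells$n_coloc / cells$n_upa, NA_real_)
  structure(
    list(
      n_cells = nrow(cells),
      pct_cells_with_mrna = 100 * mean(cells$n_mrna > 0),
      pct_cells_with_upa = 100 * mean(cells$n_upa > 0),
      mrna_per_cell = summary(cells$n_mrna),
      upa_per_cell = summary(cells$n_upa),
      pct_upa_colocalized = if (tot_upa > 0) 100 * tot_coloc / tot_upa
        else NA_real_,
      pct_upa_colocalized_cell_median = median(per_cell_coloc, na.rm = TRUE),
      ratio_upa_only_to_coloc = ratio_upa_only_to_coloc(
        tot_upa - tot_coloc, tot_coloc
      ),
      pct_nuclear_mrna = if (tot_mrna > 0)
        100 * sum(cells$n_mrna_nuclear) / tot_mrna else NA_real_,
      pct_nuclear_upa = if (tot_upa > 0)
        100 * sum(cells$n_upa_nuclear) / tot_upa else NA_real_,
      pct_nuclear_coloc = if (tot_coloc > 0)
        100 * sum(cells$n_coloc_nuclear) / tot_coloc else NA_real_
    ),
    class = "culture_summary"
  )
}

#' Ratio of UPA-only events to co-localization events
#'
#' The abundance of short upstream transcripts relative to the 5'-extended
#' full-length isoform, from pooled speckle counts: UPA speckles not
#' co-localizing with mRNA speckles divided by co-localizing ones. `NA` when
#' there are no co-localization events.
#'
#' @param n_upa_only Count of UPA-only speckles.
#' @param n_coloc Count of co-localization events.
#' @return Non-negative scalar or `NA`.
#' @export
ratio_upa_only_to_coloc <- function(n_upa_only, n_coloc) {
  ifelse(n_coloc > 0, n_upa_only / n_coloc, NA_real_)
}

#' @export
print.culture_summary <- function(x, ...) {
  cat("<culture_summary> ", x$n_cells, " cells; ",
      round(x$pct_cells_with_mrna, 1), "% mRNA+, ",
      round(x$pct_cells_with_upa, 1), "% UPA+; ",
      round(x$pct_upa_colocalized, 1), "% UPA co-localized\n", sep = "")
  invisible(x)
}

#' @export
tidy.culture_summary <- function(x, ...) {
  tibble::tibble(
    n_cells = x$n_cells,
    pct_cells_with_mrna = x$pct_cells_with_mrna,
    pct_cells_with_upa = x$pct_cells_with_upa,
    pct_upa_colocalized = x$pct_upa_colocalized,
    pct_upa_colocalized_cell_median = x$pct_upa_colocalized_cell_median,
    ratio_upa_only_to_coloc = x$ratio_upa_only_to_coloc,
    pct_nuclear_mrna = x$pct_nuclear_mrna,
    pct_nuclear_upa = x$pct_nuclear_upa,
    pct_nuclear_coloc = x$pct_nuclear_coloc
  )
}
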