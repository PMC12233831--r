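#' Plot per-replicate abundance ratios
#'
#' Column plot of the relative-abundance ratios per replicate with the
#' cross-replicate median annotated, mirroring the usual presentation of
#' promoter-output quantification.
#'
#' @param object An [abundance_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.abundance_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$per_replicate,
    dplyr::all_of(c("ratio_canonical_novel", "ratio_canonical_longfoxp3",
                    "ratio_canonical_short")),
    names_to = "ratio", values_to = "value"
  )
  long$ratio <- dplyr::recode(long$ratio,
    ratio_canonical_novel = "canonical : novel canonical",
    ratio_canonical_longfoxp3 = "canonical : longFOXP3",
    ratio_canonical_short = "canonical : short upstream")
  meds <- dplyr::summarise(dplyr::group_by(long, .data$ratio),
                           med = median(.data$value, na.rm = TRUE))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ratio, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$replicate_id), size = 2) +
    ggplot2::geom_text(data = meds, size = 3, vjust = -1,
                       ggplot2::aes(y = max(long$value, na.rm = TRUE),
                                    label = round(.data$med, 1))) +
    ggplot2::labs(x = NULL, y = "ratio (reads)", colour = "replicate") +
    ggplot2::theme_minimal()
}

#' Plot the cleavage-site offset histogram
#'
#' @param offsets Tibble from [cleavage_offsets()].
#' @param window Half-width passed to [cleavage_histogram()].
#' @return A ggplot object.
#' @export
plot_cleavage_offsets <- function(offsets, window = 10L) {
  h <- cleavage_histogram(offsets, window)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "3' end offset from PAS (nt, transcription direction)",
                  y = "reads") +
    ggplot2::theme_minimal()
}

#' Plot poly(A) tail length distributions by class
#'
#' @param classified Output of [classify_reads()] (excluded reads dropped).
#' @param group Grouping column (default `"class"`).
#' @return A ggplot object.
#' @export
plot_polya <- function(classified, group = "class") {
  d <- dplyr::filter(classified, .data$class != "excluded",
                     !is.na(.data$polya_len))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$polya_len,
                                  colour = .data[[group]])) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "poly(A) tail length (nt)", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot a culture summary
#'
#' Bar chart of the headline culture-level percentages.
#'
#' @param object A [summarize_culture()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.culture_summary <- function(object, ...) {
  d <- tibble::tibble(
    quantity = c("cells with mRNA spots", "cells with UPA spots",
                 "UPA spots co-localized", "nuclear mRNA spots",
                 "nuclear UPA spots"),
    pct = c(object$pct_cells_with_mrna, object$pct_cells_with_upa,
            object$pct_upa_colocalized, object$pct_nuclear_mrna,
            object$pct_nuclear_upa)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$quantity, y = .data$pct)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of cells / spots") +
    ggplot2::theme_minimal()
}
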