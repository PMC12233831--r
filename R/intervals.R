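#' Genomic interval conventions
#'
#' All internal coordinates are 0-based, half-open: an interval `[start, end)`
#' contains position `p` iff `start <= p < end`. BED input is native in this
#' convention; GTF features and human-readable spans such as
#' `"chrX:49264670-49264735"` are 1-based inclusive and are converted on
#' ingestion with [parse_span()].
#'
#' `tx_pos()` maps a genomic position to a "transcription coordinate" that
#' increases in the direction of transcription, so upstream/downstream logic
#' is strand-free: on the plus strand it is the identity, on the minus strand
#' it is the negation.
#'
#' @param pos Integer vector of genomic positions (0-based).
#' @param strand `"+"` or `"-"`.
#' @return `tx_pos()`: numeric vector of transcription coordinates.
#' @examples
#' tx_pos(100, "-") < tx_pos(50, "-") # 100 is upstream of 50 on minus strand
#' @export
tx_pos <- function(pos, strand) {
  stopifnot(all(strand %in% c("+", "-")))
  sgn <- rep_len(ifelse(strand == "+", 1L, -1L), length(pos))
  pos * sgn
}

#' Parse a 1-based inclusive genomic span
#'
#' Converts strings such as `"chrX:49,264,670-49,264,735"` (1-based,
#' inclusive, the convention of genome browsers and of printed coordinates)
#' to the package's 0-based half-open representation.
#'
#' @param x Character vector of spans (`chrom:start-end`, commas allowed, the
#'   dash may be an en-dash).
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open).
#' @examples
#' parse_span("chrX:49264670-49264735")
#' @export
parse_span <- function(x) {
  x <- gsub(",", "", x)
  x <- gsub("–", "-", x)
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("cannot parse span(s): ", paste(x[bad], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    chrom = vapply(m, `[[`, "", 2L),
    start = as.integer(vapply(m, `[[`, "", 3L)) - 1L,
    end = as.integer(vapply(m, `[[`, "", 4L))
  )
}

#' Format a 0-based half-open interval as a 1-based inclusive span
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open bounds.
#' @return Character vector `chrom:start-end` in 1-based inclusive form.
#' @export
format_span <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, as.integer(start) + 1L, as.integer(end))
}

#' Reflect coordinates for mirror-symmetry checks
#'
#' Maps position `p` to `C - 1 - p` and interval `[s, e)` to `[C - e, C - s)`,
#' so that half-open membership is preserved exactly when the strand is also
#' flipped. Used by property tests: every piece of coordinate logic in the
#' package must be invariant under this reflection.
#'
#' @param pos Position vector.
#' @param start,end Interval bounds (0-based half-open).
#' @param C Reflection constant.
#' @return Reflected positions, or a list with reflected `start`/`end`.
#' @export
reflect_pos <- function(pos, C) C - 1L - as.integer(pos)

#' @rdname reflect_pos
#' @export
reflect_interval <- function(start, end, C) {
  list(start = C - as.integer(end), end = C - as.integer(start))
}

# half-open membership, vectorized over pos
point_in <- function(pos, start, end) pos >= start & pos < end

# fraction of [s1,e1) covered by [s2,e2)
overlap_frac <- function(s1, e1, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  ov / pmax(1, e1 - s1)
}
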