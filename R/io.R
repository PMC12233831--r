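#' Read and write the long-read TSV interchange format
#'
#' Tab-separated with columns `read_id`, `strand`, `blocks`
#' (`start-end;start-end`, 0-based half-open), `polya_len`, `replicate_id`
#' (extra columns such as truth labels round-trip unchanged).
#'
#' @param path File path.
#' @param reads Read tibble (see [drs_reads]).
#' @return `read_drs_tsv()`: the read tibble; writers return `path`
#'   invisibly.
#' @export
read_drs_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    read_id = "c", strand = "c", blocks = "c",
                    polya_len = "d", replicate_id = "c",
                    .default = readr::col_guess()
                  ))
}

#' @rdname read_drs_tsv
#' @export
write_drs_tsv <- function(reads, path) {
  readr::write_tsv(reads, path)
  invisible(path)
}

#' Read primary alignments from a BAM file as a read tibble
#'
#' Requires the Bioconductor BAM stack (Rsamtools/GenomicAlignments).
#' Primary alignments only (flags 0 and 16); aligned blocks come from the
#' CIGAR (M/D merge across mismatches, N opens a new block), converted to the
#' package's 0-based half-open convention.
#'
#' @param path BAM file (an index is created if absent).
#' @param replicate_id Replicate label to attach.
#' @return Read tibble (see [drs_reads]); `polya_len` is `NA` (tail estimates
#'   come from the basecaller, not the BAM).
#' @export
read_drs_bam <- function(path, replicate_id = "rep1") {
  if (!requireNamespace("GenomicAlignments", quietly = TRUE) ||
      !requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("reading BAM requires the Rsamtools/GenomicAlignments packages",
         call. = FALSE)
  }
  if (!file.exists(paste0(path, ".bai"))) Rsamtools::indexBam(path)
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  ga <- GenomicAlignments::readGAlignments(
    path, param = Rsamtools::ScanBamParam(flag = flags, what = "qname")
  )
  grl <- GenomicAlignments::grglist(ga)
  blocks <- vapply(as.list(IRanges::ranges(grl)), function(r) {
    paste(sprintf("%d-%d", BiocGenerics::start(r) - 1L, BiocGenerics::end(r)),
          collapse = ";")
  }, "")
  tibble::tibble(
    read_id = S4Vectors::mcols(ga)$qname,
    strand = as.character(BiocGenerics::strand(ga)),
    blocks = blocks,
    polya_len = NA_real_,
    replicate_id = replicate_id
  )
}

#' Read and write bedGraph coverage
#'
#' Four-column bedGraph (`chrom start end value`, 0-based half-open), the
#' standard exchange format for per-base coverage. Track lines are ignored on
#' input; runs of equal coverage are collapsed on output.
#'
#' @param path File path.
#' @param chrom Restrict to one chromosome (default: the first seen).
#' @param track A [coverage_track()].
#' @return `read_bedgraph()`: a [coverage_track()].
#' @export
read_bedgraph <- function(path, chrom = NULL) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tb <- tibble::tibble(
    chrom = vapply(parts, `[[`, "", 1L),
    start = as.integer(vapply(parts, `[[`, "", 2L)),
    end = as.integer(vapply(parts, `[[`, "", 3L)),
    value = as.numeric(vapply(parts, `[[`, "", 4L))
  )
  if (is.null(chrom)) chrom <- tb$chrom[1]
  tb <- tb[tb$chrom == chrom, ]
  tb <- tb[order(tb$start), ]
  lo <- min(tb$start)
  hi <- max(tb$end)
  counts <- numeric(hi - lo)
  for (k in seq_len(nrow(tb))) {
    counts[(tb$start[k] - lo + 1L):(tb$end[k] - lo)] <- tb$value[k]
  }
  coverage_track(chrom, lo, counts)
}

#' @rdname read_bedgraph
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  v <- track$counts
  r <- rle(v)
  ends <- track$start + cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  readr::write_lines(
    sprintf("%s\t%d\t%d\t%s", track$chrom, starts[keep], ends[keep],
            format(r$values[keep], trim = TRUE, scientific = FALSE)),
    path
  )
  invisible(path)
}

#' Read and write CAGE peaks as BED6+1
#'
#' BED columns: chrom, start, end (cluster, 0-based half-open), name
#' (`promoter_id:peak_number`), score, strand, then summit (0-based) and
#' optional sigma.
#'
#' @param path File path.
#' @param peaks CAGE-peak tibble (as in [locus_annotation()]).
#' @param chrom,strand Chromosome/strand written out.
#' @return `read_cage_bed()`: a CAGE-peak tibble.
#' @export
read_cage_bed <- function(path) {
  tb <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  nm <- strsplit(tb$X4, ":", fixed = TRUE)
  tibble::tibble(
    promoter_id = vapply(nm, `[[`, "", 1L),
    peak_number = as.integer(vapply(nm, `[[`, "", 2L)),
    start = as.integer(tb$X2),
    end = as.integer(tb$X3),
    summit = as.integer(tb$X7),
    score = as.numeric(tb$X5),
    sigma = if (ncol(tb) >= 8) as.numeric(tb$X8) else NA_real_
  )
}

#' @rdname read_cage_bed
#' @export
write_cage_bed <- function(peaks, path, chrom, strand) {
  readr::write_lines(
    sprintf("%s\t%d\t%d\t%s:%d\t%s\t%s\t%d\t%s",
            chrom, peaks$start, peaks$end, peaks$promoter_id,
            peaks$peak_number, format(peaks$score, trim = TRUE),
            strand, peaks$summit, format(peaks$sigma, trim = TRUE)),
    path
  )
  invisible(path)
}

#' Read and write a locus annotation as JSON
#'
#' Lossless round-trip of the full [locus_annotation()] (exons, PAS and
#' 3'-UTR threshold, CAGE peaks with sigmas, neighbour promoter, allowed
#' splice patterns, alternative first exons).
#'
#' @param ann A [locus_annotation()].
#' @param path File path.
#' @return `read_locus_json()`: the annotation; the writer returns `path`.
#' @export
write_locus_json <- function(ann, path) {
  stopifnot(inherits(ann, "locus_annotation"))
  jsonlite::write_json(
    list(
      chrom = ann$chrom, strand = ann$strand, exons = ann$exons,
      pas_position = ann$pas_position, utr3_min_nt = ann$utr3_min_nt,
      cage_peaks = ann$cage_peaks,
      neighbor_promoter = ann$neighbor_promoter,
      allowed_splice_patterns = ann$allowed_splice_patterns,
      alt_first_exons = ann$alt_first_exons,
      cds_exons = ann$cds_exons,
      chrom_length = ann$chrom_length
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_locus_json
#' @export
read_locus_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  locus_annotation(
    chrom = x$chrom, strand = x$strand,
    exons = tibble::as_tibble(x$exons),
    pas_position = x$pas_position,
    cage_peaks = tibble::as_tibble(x$cage_peaks),
    neighbor_promoter = x$neighbor_promoter,
    allowed_splice_patterns = lapply(x$allowed_splice_patterns, as.integer),
    alt_first_exons = tibble::as_tibble(x$alt_first_exons),
    cds_exons = x$cds_exons,
    utr3_min_nt = x$utr3_min_nt,
    chrom_length = x$chrom_length
  )
}

#' Write transcript sequences as FASTA
#'
#' @param transcripts Named character vector of sequences.
#' @param path File path.
#' @return `read_transcripts_fasta()`: named character vector.
#' @export
write_transcripts_fasta <- function(transcripts, path) {
  set <- Biostrings::DNAStringSet(chartr("U", "T", unlist(transcripts)))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname write_transcripts_fasta
#' @export
read_transcripts_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  setNames(as.character(set), names(set))
}

#' Read and write images as plain-text PGM (P2)
#'
#' The text-only interchange format for image matrices: intensities are
#' scaled to `maxval` grey levels (lossy quantization; images are primarily
#' in-memory numeric matrices).
#'
#' @param img Numeric matrix.
#' @param path File path.
#' @param maxval Grey levels (default 65535).
#' @return `read_pgm()`: numeric matrix scaled back to `[0, 1]` times the
#'   recorded scale.
#' @export
write_pgm <- function(img, path, maxval = 65535L) {
  lo <- min(img)
  hi <- max(img)
  scaled <- if (hi > lo) round((img - lo) / (hi - lo) * maxval) else
    matrix(0L, nrow(img), ncol(img))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("# lo=%.8g hi=%.8g", lo, hi),
               sprintf("%d %d", ncol(img), nrow(img)),
               sprintf("%d", maxval)), con)
  write(t(scaled), file = con, ncolumns = ncol(img))
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  stopifnot(lines[1] == "P2")
  meta <- lines[startsWith(lines, "#")][1]
  body <- lines[!startsWith(lines, "#")][-1]
  dims <- as.integer(strsplit(body[1], " ")[[1]])
  maxval <- as.numeric(body[2])
  vals <- as.numeric(unlist(strsplit(paste(body[-(1:2)], collapse = " "),
                                     "\\s+")))
  vals <- vals[!is.na(vals)]
  m <- matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE)
  if (!is.na(meta)) {
    nums <- as.numeric(regmatches(meta,
      gregexpr("-?[0-9.]+(e[+-]?[0-9]+)?", meta))[[1]])
    m <- m / maxval * (nums[2] - nums[1]) + nums[1]
  }
  m
}

#' Materialize a complete synthetic study directory
#'
#' One call producing every input the pipeline consumes: the locus annotation
#' (JSON), CAGE peaks (BED6+1), transcript sequences (FASTA), long reads with
#' truth labels (TSV), short-read coverage (bedGraph), RNA-FISH fields (PGM
#' per channel plus truth CSVs), and a speckle-presence table (CSV).
#' Deterministic per seed.
#'
#' @param dir Output directory (created).
#' @param config A [sim_config()].
#' @param n_reads,replicates Passed to [simulate_drs_reads()].
#' @param n_fields Passed to [simulate_fish_images()].
#' @return `dir`, invisibly.
#' @export
simulate_study <- function(dir, config, n_reads = 2000L, replicates = 4L,
                           n_fields = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  locus <- simulate_locus(config)
  ann <- locus$annotation
  write_locus_json(ann, file.path(dir, "locus.json"))
  write_cage_bed(ann$cage_peaks, file.path(dir, "cage_peaks.bed"),
                 ann$chrom, ann$strand)
  write_transcripts_fasta(locus$transcripts,
                          file.path(dir, "transcripts.fasta"))
  reads <- simulate_drs_reads(config, locus, n_reads, replicates)
  write_drs_tsv(reads, file.path(dir, "drs_reads.tsv"))
  ngs <- simulate_ngs_coverage(config, locus)
  write_bedgraph(ngs$track, file.path(dir, "ngs_coverage.bedgraph"))
  fields <- simulate_fish_images(config, n_fields)
  for (k in seq_along(fields)) {
    for (ch in c("dapi", "mrna", "upa")) {
      write_pgm(fields[[k]][[ch]],
                file.path(dir, sprintf("field%02d_%s.pgm", k, ch)))
    }
    readr::write_csv(fields[[k]]$cell_truth,
                     file.path(dir, sprintf("field%02d_cell_truth.csv", k)))
    readr::write_csv(fields[[k]]$spot_truth,
                     file.path(dir, sprintf("field%02d_spot_truth.csv", k)))
  }
  presence <- simulate_presence_table(config)
  readr::write_csv(presence, file.path(dir, "presence.csv"))
  jsonlite::write_json(
    list(seed = config$seed, n_reads = n_reads, replicates = replicates,
         n_fields = n_fields,
         package_version = as.character(utils::packageVersion("foxlocus"))),
    file.path(dir, "provenance.json"), auto_unbox = TRUE
  )
  invisible(dir)
}
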