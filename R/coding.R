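#' Find open reading frames with AUG/CUG starts
#'
#' Scans a transcript sequence for ORFs meeting the microprotein-prediction
#' criteria: a start codon from `starts` (default AUG and CUG, the canonical
#' and the strongest near-cognate initiator), terminated by the first in-frame
#' stop, with a minimum total length (stop included) of `min_len_nt`. ORFs
#' lacking an in-frame stop are not reported.
#'
#' Offsets are 1-based positions within the sequence (R/Biostrings
#' convention).
#'
#' @param seq Transcript sequence (character, `Biostrings::RNAString` or
#'   `DNAString`; T and U are equivalent on input).
#' @param starts Character vector of start codons (RNA alphabet).
#' @param min_len_nt Minimum ORF length in nt including the stop codon
#'   (default 150, i.e. 49 codons); must be >= 6 and divisible by 3.
#' @param region Optional `c(start, end)` 1-based inclusive window: only start
#'   codons inside it are considered.
#' @return Tibble, one row per ORF in 5'-to-3' start order: `start_offset`,
#'   `start_codon`, `length_nt`, `length_aa`, `stop_offset` (first base of the
#'   stop codon), `kozak_score`.
#' @export
find_orfs <- function(seq, starts = c("AUG", "CUG"), min_len_nt = 150L,
                      region = NULL) {
  stopifnot(min_len_nt >= 6, min_len_nt %% 3 == 0)
  s <- normalize_rna(seq)
  n <- nchar(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  codon_at <- function(p) paste0(ch[p], ch[p + 1L], ch[p + 2L])
  if (n < 3) {
    return(empty_orf_tbl())
  }
  pos <- seq_len(n - 2L)
  cods <- paste0(ch[pos], ch[pos + 1L], ch[pos + 2L])
  start_pos <- pos[cods %in% starts]
  if (!is.null(region)) {
    start_pos <- start_pos[start_pos >= region[1] & start_pos <= region[2]]
  }
  stop_pos <- pos[cods %in% c("UAA", "UAG", "UGA")]
  if (length(start_pos) == 0) return(empty_orf_tbl())
  rows <- purrr::map_dfr(start_pos, function(p) {
    frame_stops <- stop_pos[stop_pos > p & (stop_pos - p) %% 3L == 0L]
    if (length(frame_stops) == 0) return(NULL)
    st <- frame_stops[1]
    len <- st + 3L - p
    if (len < min_len_nt) return(NULL)
    tibble::tibble(
      start_offset = p, start_codon = codon_at(p),
      length_nt = len, length_aa = len %/% 3L - 1L, stop_offset = st,
      kozak_score = kozak_score(s, p)
    )
  })
  if (nrow(rows) == 0) empty_orf_tbl() else rows
}

empty_orf_tbl <- function() {
  tibble::tibble(start_offset = integer(), start_codon = character(),
                 length_nt = integer(), length_aa = integer(),
                 stop_offset = integer(), kozak_score = numeric())
}

normalize_rna <- function(seq) {
  s <- toupper(as.character(seq))
  s <- chartr("T", "U", s)
  if (grepl("[^ACGUN]", s)) {
    stop("sequence contains characters outside the A/C/G/U(/N) alphabet",
         call. = FALSE)
  }
  s
}

# Kozak position-weight model: flanking positions -6..-1 and +4 relative to
# the start codon. The vertebrate consensus context gccRccAUGG scores 1.0;
# positions -3 (purine) and +4 (G) dominate. N (and out-of-sequence padding)
# contributes 0.
kozak_weights <- local({
  w <- list(
    "-6" = c(A = 0.33, C = 0.33, G = 1.00, U = 0.33, N = 0),
    "-5" = c(A = 0.33, C = 1.00, G = 0.33, U = 0.33, N = 0),
    "-4" = c(A = 0.33, C = 1.00, G = 0.33, U = 0.33, N = 0),
    "-3" = c(A = 1.00, C = 0.25, G = 1.00, U = 0.25, N = 0),
    "-2" = c(A = 0.33, C = 1.00, G = 0.33, U = 0.33, N = 0),
    "-1" = c(A = 0.33, C = 1.00, G = 0.33, U = 0.33, N = 0),
    "+4" = c(A = 0.20, C = 0.20, G = 1.00, U = 0.20, N = 0)
  )
  imp <- c("-6" = 1, "-5" = 1, "-4" = 1, "-3" = 3, "-2" = 1, "-1" = 1,
           "+4" = 3)
  list(w = w, imp = imp / sum(imp))
})

#' Kozak context score of a putative start codon
#'
#' Position-weight similarity of the 10-nt initiation context (6 nt upstream,
#' the codon, 1 nt downstream) to the vertebrate Kozak consensus
#' `gccRccAUGG`, normalized so the consensus context scores 1.0 and an
#' all-unknown context 0.0. Only the flanking positions (-6..-1, +4) are
#' scored, so AUG and CUG starts are directly comparable; positions outside
#' the sequence are padded with N and contribute 0. Deterministic; the score
#' depends on nothing outside the 10-base window.
#'
#' @param seq Transcript sequence.
#' @param start_offset 1-based offset of the start codon's first base.
#' @return Score in `[0, 1]`.
#' @examples
#' kozak_score("GCCGCCAUGG", 7) # consensus context -> 1
#' @export
kozak_score <- function(seq, start_offset) {
  s <- normalize_rna(seq)
  n <- nchar(s)
  get_base <- function(p) {
    if (p < 1 || p > n) "N" else substr(s, p, p)
  }
  rel <- c(-6, -5, -4, -3, -2, -1, 4)
  labs <- c("-6", "-5", "-4", "-3", "-2", "-1", "+4")
  score <- 0
  for (k in seq_along(rel)) {
    b <- get_base(start_offset + rel[k] + if (rel[k] > 0) -1L else 0L)
    score <- score + kozak_weights$imp[[labs[k]]] * kozak_weights$w[[labs[k]]][[b]]
  }
  unname(score)
}

# Expasy average residue masses (Da); protein mass = sum + one water.
aa_avg_mass <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
water_mass <- 18.01524

#' Molecular weight of a protein sequence
#'
#' Average (not monoisotopic) residue masses plus one water, in kDa —
#' matching the kDa scale of SDS-PAGE comparisons.
#'
#' @param aa_sequence One-letter amino-acid string (standard 20 letters).
#' @return Molecular weight in kDa (full precision; round to 1 dp for
#'   reporting).
#' @examples
#' protein_mw("GG") # 0.1321 kDa
#' @export
protein_mw <- function(aa_sequence) {
  aa <- strsplit(toupper(aa_sequence), "", fixed = TRUE)[[1]]
  bad <- setdiff(aa, names(aa_avg_mass))
  if (length(bad) > 0) {
    stop("unknown amino-acid letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  (sum(aa_avg_mass[aa]) + water_mass) / 1000
}

#' Translate an ORF to protein
#'
#' Standard genetic code; the initiator codon (including near-cognate CUG)
#' is translated as methionine, the convention for alternative initiation.
#'
#' @param seq Transcript sequence.
#' @param start_offset 1-based start of the ORF.
#' @param length_nt ORF length in nt including the stop codon.
#' @return Amino-acid string (stop not included).
#' @export
translate_orf <- function(seq, start_offset, length_nt) {
  s <- normalize_rna(seq)
  cds <- substr(s, start_offset, start_offset + length_nt - 4L)
  aa <- as.character(Biostrings::translate(
    Biostrings::RNAString(cds), no.init.codon = TRUE
  ))
  substr(aa, 1, 1) <- "M"
  aa
}

#' Enumerate proteoforms and upstream ORFs of a transcript
#'
#' Categorizes the qualifying ORFs of a transcript relative to an annotated
#' main start: the main proteoform; N-terminally extended proteoforms (an
#' upstream AUG/CUG in frame with the main start and sharing its stop, with no
#' intervening in-frame stop); and upstream ORFs (start codon in the 5' UTR,
#' wholly or partly upstream of the main start — uORFs overlapping the main
#' ORF are included as long as their start lies in the UTR).
#'
#' @inheritParams find_orfs
#' @param main_start 1-based offset of the annotated main start codon (must be
#'   one of `starts`).
#' @return Tibble as [find_orfs()] plus `category`
#'   (`main_proteoform`/`n_extended_proteoform`/`uORF`), `protein` and
#'   `mw_kda`. ORFs starting inside the CDS or 3' UTR are not reported.
#' @export
enumerate_proteoforms <- function(seq, main_start, starts = c("AUG", "CUG"),
                                  min_len_nt = 150L) {
  s <- normalize_rna(seq)
  main_codon <- substr(s, main_start, main_start + 2L)
  if (!main_codon %in% starts) {
    stop("main start at offset ", main_start, " is ", main_codon,
         ", not one of ", paste(starts, collapse = "/"), call. = FALSE)
  }
  orfs <- find_orfs(s, starts = starts, min_len_nt = min_len_nt)
  main <- orfs[orfs$start_offset == main_start, ]
  stopifnot(nrow(main) == 1)
  orfs$category <- dplyr::case_when(
    orfs$start_offset == main_start ~ "main_proteoform",
    orfs$start_offset < main_start &
      (main_start - orfs$start_offset) %% 3L == 0L &
      orfs$stop_offset == main$stop_offset ~ "n_extended_proteoform",
    orfs$start_offset < main_start ~ "uORF",
    TRUE ~ "downstream"
  )
  orfs <- orfs[orfs$category != "downstream", ]
  orfs$protein <- purrr::map2_chr(orfs$start_offset, orfs$length_nt,
                                  function(p, l) translate_orf(s, p, l))
  orfs$mw_kda <- vapply(orfs$protein, protein_mw, 1.0, USE.NAMES = FALSE)
  orfs
}

#' Coding-potential report for a set of transcripts
#'
#' Applies [enumerate_proteoforms()] to each transcript (e.g. the full-length
#' and delta-2 splice variants of a 5'-extended isoform) and returns a tidy
#' table mirroring the usual summary columns: variant, start codon, Kozak
#' score, length in aa, molecular weight in kDa.
#'
#' @param transcripts Named character vector (or `RNAStringSet`) of transcript
#'   sequences.
#' @param main_starts Named integer vector of 1-based main-start offsets,
#'   aligned with `transcripts`.
#' @inheritParams find_orfs
#' @return Tibble with one row per (transcript, ORF).
#' @export
coding_potential_report <- function(transcripts, main_starts,
                                    starts = c("AUG", "CUG"),
                                    min_len_nt = 150L) {
  txs <- vapply(as.list(transcripts), as.character, "")
  purrr::imap_dfr(txs, function(s, nm) {
    out <- enumerate_proteoforms(s, main_starts[[nm]], starts, min_len_nt)
    dplyr::bind_cols(tibble::tibble(variant = nm), out)
  })
}
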