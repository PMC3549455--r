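# Default significance gate for best_frame_alignment(): raw local-alignment
# score at the 99th percentile of 1,000 null pairs (uniform-random 300-nt
# query vs unrelated 200-residue protein, best of 6 frames, BLOSUM62,
# gap 11/1). Scores below it are reported as "no confident frame".
DEFAULT_MIN_FRAME_SCORE <- 42

#' Best translated-frame local alignment of a nucleotide query
#'
#' Translates the query in all six frames (0-2 forward, 3-5 on the reverse
#' complement) and aligns each translation to a reference protein by local
#' affine-gap alignment (BLOSUM62, gap open 11 / extend 1 by default,
#' mirroring BLASTX defaults). The maximum-scoring frame is returned; ties
#' are broken by the lowest frame index, then the leftmost query start.
#' This emulates BLASTX-style reading-frame identification for cDNA/EST
#' sequences.
#'
#' @param nucleotides Query nucleotide string (length >= 3).
#' @param reference_protein Reference amino-acid string (non-empty).
#' @param gap_open,gap_extend Affine gap penalties (non-negative).
#' @param substitution_matrix Name of a matrix shipped with Biostrings
#'   (default `"BLOSUM62"`), or a matrix.
#' @param min_score Scores below this are flagged `confident = FALSE`
#'   (a "no confident frame" result, not an error). The default is
#'   calibrated on a seeded null simulation; see the package vignette.
#' @return One-row tibble: `frame` (0-5), `strand`, `frame_offset` (0-2 on
#'   the read strand), `score`, `identity` (percent over aligned columns),
#'   `query_aa_start`/`query_aa_end` and `ref_start`/`ref_end` (0-based
#'   half-open, on the frame's translation and the reference respectively),
#'   `confident`.
#' @export
best_frame_alignment <- function(nucleotides, reference_protein,
                                 gap_open = 11, gap_extend = 1,
                                 substitution_matrix = "BLOSUM62",
                                 min_score = DEFAULT_MIN_FRAME_SCORE) {
  stopifnot(nchar(nucleotides) >= 3L, nchar(reference_protein) >= 1L,
            gap_open >= 0, gap_extend >= 0)
  fwd <- toupper(nucleotides)
  rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  ref <- Biostrings::AAString(toupper(reference_protein))

  rows <- purrr::map(0:5, function(fr) {
    strand <- if (fr <= 2L) "+" else "-"
    off <- fr %% 3L
    aa <- translate_dna(if (strand == "+") fwd else rev, off)
    if (nchar(aa) == 0L) return(NULL)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(aa), ref, type = "local",
      substitutionMatrix = substitution_matrix,
      gapOpening = gap_open, gapExtension = gap_extend
    )
    pat <- Biostrings::pattern(aln)
    sub <- Biostrings::subject(aln)
    tibble::tibble(
      frame = fr, strand = strand, frame_offset = off,
      score = Biostrings::score(aln),
      identity = Biostrings::pid(aln, type = "PID1"),
      query_aa_start = Biostrings::start(pat) - 1L,
      query_aa_end = Biostrings::end(pat),
      ref_start = Biostrings::start(sub) - 1L,
      ref_end = Biostrings::end(sub)
    )
  })
  res <- dplyr::bind_rows(rows)
  best <- res |>
    dplyr::arrange(dplyr::desc(.data$score), .data$frame, .data$query_aa_start) |>
    dplyr::slice(1)
  best$confident <- best$score >= min_score
  best
}

#' Map a frame alignment to a nucleotide coding span
#'
#' Converts the aligned amino-acid span of a confident frame alignment into
#' a 0-based half-open nucleotide interval on the input's forward strand
#' (start = frame_offset + 3 x aa_start on the read strand; reverse-strand
#' spans are mapped back to forward coordinates).
#'
#' @param nucleotides The query nucleotide string given to
#'   [best_frame_alignment()].
#' @param frame_alignment The one-row tibble it returned (`confident` must
#'   be `TRUE`).
#' @return One-row tibble: `start`, `end` (0-based half-open, forward
#'   coordinates), `strand`, `frame_offset`, `score`, `identity`.
#' @export
call_orf <- function(nucleotides, frame_alignment) {
  fa <- frame_alignment
  stopifnot(nrow(fa) == 1L)
  if (!isTRUE(fa$confident)) {
    stop("call_orf(): alignment is not confident; no ORF is called", call. = FALSE)
  }
  L <- nchar(nucleotides)
  s_read <- fa$frame_offset + 3L * fa$query_aa_start
  e_read <- fa$frame_offset + 3L * fa$query_aa_end
  if (fa$strand == "+") {
    start <- s_read; end <- e_read
  } else {
    start <- L - e_read; end <- L - s_read
  }
  if (start < 0L || end > L || (end - start) %% 3L != 0L) {
    stop("call_orf(): internal span arithmetic violated its invariant", call. = FALSE)
  }
  tibble::tibble(
    start = start, end = end, strand = fa$strand,
    frame_offset = fa$frame_offset,
    score = fa$score, identity = fa$identity
  )
}

#' Filter ORF calls by alignment significance
#'
#' Keeps calls meeting both a raw-score and an identity threshold, in input
#' order. When an external hit table carrying E-values is supplied (columns
#' `query`, `evalue`, matched against a `gene_id` column of `calls`), an
#' E-value ceiling is applied instead, supporting externally computed
#' BLASTX-style gates such as E < 2e-35.
#'
#' @param calls Tibble of ORF calls (as from [call_orf()], typically with a
#'   `gene_id` column).
#' @param min_score,min_identity Thresholds (>= 0).
#' @param hits Optional tibble with `query` and `evalue` columns.
#' @param max_evalue E-value ceiling used when `hits` is supplied.
#' @return The retained subset of `calls`, order preserved.
#' @export
filter_orf_calls <- function(calls, min_score = DEFAULT_MIN_FRAME_SCORE,
                             min_identity = 0, hits = NULL, max_evalue = NULL) {
  stopifnot(min_score >= 0, min_identity >= 0)
  if (nrow(calls) == 0L) return(calls)
  if (!is.null(hits) && !is.null(max_evalue)) {
    ok <- hits$query[hits$evalue < max_evalue]
    return(dplyr::filter(calls, .data$gene_id %in% ok))
  }
  dplyr::filter(calls, .data$score >= min_score, .data$identity >= min_identity)
}
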