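#' Merge overlapping coding spans
#'
#' Coding spans are 0-based half-open intervals (BED convention) on a
#' contig; overlapping or adjacent-duplicate spans are merged before
#' masking. Strand is ignored (GC is strand-symmetric).
#'
#' @param spans Tibble with `start`, `end` columns (0-based half-open).
#' @return Tibble of merged disjoint spans, sorted by `start`.
#' @export
merge_spans <- function(spans) {
  if (nrow(spans) == 0L) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  stopifnot(all(spans$end > spans$start), all(spans$start >= 0))
  ir <- IRanges::reduce(IRanges::IRanges(start = spans$start + 1L, end = spans$end))
  tibble::tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Non-coding GC profile of an annotated contig
#'
#' Computes the GC-content of the contig outside its (merged) coding
#' spans — the non-coding complement of exons within a genomic region
#' consisting of exons, introns and flanking sequence. Non-ACGT bases are
#' excluded from the GC denominator.
#'
#' @param nucleotides Contig sequence (single string).
#' @param coding_spans Tibble with `start`, `end` (0-based half-open;
#'   within bounds). May be empty, in which case the profile covers the
#'   whole contig.
#' @return One-row tibble: `gc_noncoding` (percent, `NA` when the contig
#'   is fully coding — undefined, distinct from 0), `noncoding_length`
#'   (bases) and `coding_fraction`.
#' @export
noncoding_profile <- function(nucleotides, coding_spans) {
  L <- nchar(nucleotides)
  merged <- merge_spans(coding_spans)
  stopifnot(all(merged$end <= L))
  coding_len <- sum(merged$end - merged$start)
  noncoding_len <- L - coding_len
  if (noncoding_len == 0L) {
    return(tibble::tibble(gc_noncoding = NA_real_, noncoding_length = 0L,
                          coding_fraction = 1))
  }
  mask <- rep(TRUE, L)
  for (i in seq_len(nrow(merged))) {
    mask[(merged$start[i] + 1L):merged$end[i]] <- FALSE
  }
  chars <- strsplit(toupper(nucleotides), "", fixed = TRUE)[[1]]
  nc <- paste(chars[mask], collapse = "")
  tibble::tibble(
    gc_noncoding = gc_content(nc),
    noncoding_length = noncoding_len,
    coding_fraction = coding_len / L
  )
}

#' Pair per-gene GC3 with non-coding GC and correlate
#'
#' Joins a per-gene GC3 table with per-contig non-coding GC profiles on a
#' shared id, drops incomplete pairs, and reports the Spearman rank
#' correlation — the coupling between coding third-position composition
#' and the composition of the surrounding non-coding DNA.
#'
#' @param gc3_tbl Tibble with `gene_id` and `gc3`.
#' @param noncoding_tbl Tibble with `gene_id` and `gc_noncoding`.
#' @return List with `pairs` (tibble: `gene_id`, `gc3`, `gc_noncoding`)
#'   and `correlation` (one-row tibble from [spearman_rank()]).
#' @export
pair_gc3_noncoding <- function(gc3_tbl, noncoding_tbl) {
  pairs <- dplyr::inner_join(
    dplyr::select(gc3_tbl, "gene_id", "gc3"),
    dplyr::select(noncoding_tbl, "gene_id", "gc_noncoding"),
    by = "gene_id"
  ) |>
    dplyr::filter(!is.na(.data$gc3), !is.na(.data$gc_noncoding))
  if (nrow(pairs) == 0L) {
    stop("pair_gc3_noncoding(): no complete pairs", call. = FALSE)
  }
  list(pairs = pairs,
       correlation = spearman_rank(pairs$gc3, pairs$gc_noncoding))
}
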