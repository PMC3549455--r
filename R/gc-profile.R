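#' GC-content of a nucleotide sequence
#'
#' Percent G+C over the A/C/G/T bases only; any other (ambiguity) characters
#' are excluded from both numerator and denominator.
#'
#' @param nucleotides Character vector of nucleotide strings.
#' @return Numeric vector of percentages in \[0, 100\]; `NA` where a string
#'   contains no A/C/G/T base at all (undefined, distinct from 0).
#' @examples
#' gc_content(c("ATGC", "GGGG", "ANNT"))
#' @export
gc_content <- function(nucleotides) {
  vapply(nucleotides, function(s) {
    s <- toupper(s)
    counts <- table(strsplit(s, "", fixed = TRUE)[[1]])
    gc <- sum(counts[names(counts) %in% c("G", "C")])
    at <- sum(counts[names(counts) %in% c("A", "T")])
    if (gc + at == 0L) return(NA_real_)
    100 * gc / (gc + at)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Codon-position GC profile of a framed coding sequence
#'
#' Computes GC3 (percent of counted codons whose third base is G or C), GC4
#' (the same restricted to fourfold-degenerate codons) and overall
#' GC-content for the in-frame portion of a sequence. Stop codons are
#' excluded from the GC3 denominator; any codon containing a non-ACGT base
#' is excluded from both GC3 and GC4. A trailing partial codon is dropped.
#'
#' @param nucleotides A single nucleotide string (the coding region,
#'   already restricted to its span if one was inferred).
#' @param frame_offset 0, 1 or 2.
#' @param code A [genetic_code()].
#' @return One-row tibble: `gc3`, `gc4`, `gc_overall` (percent; `NA` when
#'   the respective denominator is zero), `n_codons` (counted codons for
#'   GC3) and `n_fourfold` (fourfold-degenerate codons counted for GC4).
#' @examples
#' gc_profile("ATGGCG")   # gc3 = 100
#' gc_profile("ATGTAA")   # stop excluded: gc3 over 1 codon
#' @export
gc_profile <- function(nucleotides, frame_offset = 0L, code = genetic_code()) {
  codons <- split_codons(nucleotides, frame_offset)
  clean <- codons[grepl("^[ACGT]{3}$", codons)]
  aa <- unname(code[clean])
  counted <- clean[aa != "*"]
  third_gc <- substr(counted, 3, 3) %in% c("G", "C")
  ff <- counted[counted %in% fourfold_codons(code)]
  ff_gc <- substr(ff, 3, 3) %in% c("G", "C")
  tibble::tibble(
    gc3 = if (length(counted)) 100 * mean(third_gc) else NA_real_,
    gc4 = if (length(ff)) 100 * mean(ff_gc) else NA_real_,
    gc_overall = gc_content(nucleotides),
    n_codons = length(counted),
    n_fourfold = length(ff)
  )
}

#' GC3 of a framed coding sequence
#'
#' Convenience scalar accessor over [gc_profile()].
#' @inheritParams gc_profile
#' @return GC3 percent, or `NA` when no codon could be counted.
#' @export
gc3 <- function(nucleotides, frame_offset = 0L, code = genetic_code()) {
  gc_profile(nucleotides, frame_offset, code)$gc3
}

#' GC4 of a framed coding sequence
#'
#' @inheritParams gc_profile
#' @return GC4 percent over fourfold-degenerate codons, or `NA` when the
#'   sequence contains none.
#' @export
gc4 <- function(nucleotides, frame_offset = 0L, code = genetic_code()) {
  gc_profile(nucleotides, frame_offset, code)$gc4
}

#' Classify genes as GC-rich or GC-poor
#'
#' The conventional cutoff places the boundary value in the rich class:
#' GC-rich means GC3 >= 50, GC-poor means GC3 < 50.
#'
#' @param gc3_value Numeric vector of GC3 percentages.
#' @param cutoff Boundary, default 50.
#' @return Factor with levels `GC-rich`, `GC-poor`; refuses undefined
#'   (`NA`) inputs with an error.
#' @examples
#' classify_gc(c(50, 49.99, 0))
#' @export
classify_gc <- function(gc3_value, cutoff = 50) {
  if (anyNA(gc3_value)) {
    stop("classify_gc(): undefined GC3 values cannot be classified", call. = FALSE)
  }
  stopifnot(all(gc3_value >= 0 & gc3_value <= 100))
  factor(ifelse(gc3_value >= cutoff, "GC-rich", "GC-poor"),
         levels = c("GC-rich", "GC-poor"))
}
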