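#' Genetic code table
#'
#' Returns a codon-to-amino-acid lookup as a named character vector of length
#' 64 (names are codons over ACGT, values are one-letter amino acids with
#' `"*"` for stop). Variant codes are selected by NCBI translation-table
#' identifier; the default is the standard code.
#'
#' @param table_id NCBI translation-table id as a string (default `"1"`,
#'   the standard code).
#' @return A named character vector of length 64 with class `genetic_code`
#'   and a `table_id` attribute.
#' @examples
#' code <- genetic_code()
#' code[["ATG"]]
#' @export
genetic_code <- function(table_id = "1") {
  code <- Biostrings::getGeneticCode(table_id)
  stopifnot(length(code) == 64L)
  structure(code, table_id = table_id, class = "genetic_code")
}

#' Translate a nucleotide sequence in a given frame
#'
#' Reads complete codons from `frame_offset` onward; any codon containing a
#' base outside ACGT yields the unknown residue `"X"`; a trailing partial
#' codon is dropped. Stop codons appear as `"*"`. Case-insensitive.
#'
#' @param nucleotides A single nucleotide string.
#' @param frame_offset 0, 1 or 2: number of leading bases skipped.
#' @param code A [genetic_code()].
#' @return A single amino-acid string (empty for sequences shorter than one
#'   codon).
#' @examples
#' translate_dna("ATGAAA")        # "MK"
#' translate_dna("AATGAAA", 1)    # "MK"
#' translate_dna("ATGNAA")        # "MX"
#' @export
translate_dna <- function(nucleotides, frame_offset = 0L, code = genetic_code()) {
  stopifnot(length(nucleotides) == 1L, frame_offset %in% 0:2)
  codons <- split_codons(nucleotides, frame_offset)
  if (length(codons) == 0L) return("")
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Complete codons (uppercased) from frame_offset; trailing partial dropped.
split_codons <- function(nucleotides, frame_offset = 0L) {
  s <- toupper(nucleotides)
  n <- nchar(s)
  if (n - frame_offset < 3L) return(character(0))
  starts <- seq.int(frame_offset + 1L, by = 3L, length.out = (n - frame_offset) %/% 3L)
  substring(s, starts, starts + 2L)
}

#' Fourfold-degenerate codons of a genetic code
#'
#' A codon is fourfold degenerate (at its third position) when all four
#' third-position variants encode the same amino acid, so any base at the
#' third site is synonymous. For the standard code this is a set of 32
#' codons (the families GCN, CGN, GGN, CTN, CCN, TCN, ACN, GTN) — third
#' positions of the 6-fold families CTN, CGN and TCN count, i.e. degeneracy
#' is assessed per site, not per family.
#'
#' @param code A [genetic_code()].
#' @return Sorted character vector of codons.
#' @export
fourfold_codons <- function(code = genetic_code()) {
  bases <- c("A", "C", "G", "T")
  codons <- names(code)
  keep <- vapply(codons, function(cd) {
    variants <- paste0(substr(cd, 1, 2), bases)
    aa <- unname(code[variants])
    length(unique(aa)) == 1L && aa[1] != "*"
  }, logical(1))
  sort(codons[keep])
}
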