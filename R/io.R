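#' Read and write FASTA files
#'
#' Thin wrappers over Biostrings giving named character vectors, the
#' representation the rest of the package works with. Multi-record,
#' line-wrapped and case-insensitive input is supported.
#'
#' @param path File path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @param sequences Named character vector.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(sequences), path, width = 70L)
  invisible(path)
}

#' Read and write BED-like coding spans
#'
#' Three-or-more-column tab-separated spans in BED convention: 0-based,
#' half-open, columns `gene_id` (the BED name field is stored per row as
#' the sequence/contig id), `start`, `end`.
#'
#' @param path File path.
#' @return Tibble: `contig_id`, `start`, `end`, and `gene_id` when a
#'   fourth column is present.
#' @export
read_bed <- function(path) {
  tbl <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  names(tbl)[1:3] <- c("contig_id", "start", "end")
  if (ncol(tbl) >= 4L) names(tbl)[4] <- "gene_id"
  tbl
}

#' @rdname read_bed
#' @param spans Tibble with `contig_id`, `start`, `end` and optionally
#'   `gene_id`.
#' @export
write_bed <- function(spans, path) {
  cols <- intersect(c("contig_id", "start", "end", "gene_id"), names(spans))
  readr::write_tsv(spans[cols], path, col_names = FALSE)
  invisible(path)
}

#' Read a gene table
#'
#' Tab-separated with a header; expected columns include `gene_id`,
#' `species`, `chromosome` and optionally `gc3` and `ortholog_id`.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_gene_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
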