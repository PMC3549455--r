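#' Functional-category over-representation between two gene lists
#'
#' FatiGO-style comparison: for each annotation term carried by enough
#' genes, a 2x2 table (in list A with/without the term vs in list B
#' with/without) is tested with Fisher's exact test; Benjamini-Hochberg q
#' values are computed across all tested terms, and the direction records
#' which list is over-represented. Terms are taken as given (no ontology
#' propagation).
#'
#' @param list_a,list_b Disjoint character vectors of gene ids (both
#'   non-empty).
#' @param annotations Tibble with `gene_id`, `term` (and optionally
#'   `namespace`, `level`, carried through).
#' @param min_term_size Minimum genes (in the union of the two lists)
#'   carrying a term for it to be tested (default 5).
#' @return Tibble sorted by `p`: `term`, `a`, `b`, `c`, `d` (the 2x2
#'   counts), `p`, `q`, `direction` (`"A"` or `"B"`), plus any `namespace`
#'   and `level` columns present in `annotations`.
#' @export
over_representation <- function(list_a, list_b, annotations, min_term_size = 5L) {
  stopifnot(min_term_size >= 1L)
  if (length(list_a) == 0L || length(list_b) == 0L) {
    stop("over_representation(): both gene lists must be non-empty", call. = FALSE)
  }
  if (length(intersect(list_a, list_b)) > 0L) {
    stop("over_representation(): gene lists must be disjoint", call. = FALSE)
  }
  universe <- c(list_a, list_b)
  ann <- dplyr::filter(annotations, .data$gene_id %in% universe)
  term_genes <- split(ann$gene_id, ann$term)
  term_genes <- lapply(term_genes, unique)
  term_genes <- term_genes[lengths(term_genes) >= min_term_size]
  if (length(term_genes) == 0L) {
    return(tibble::tibble(term = character(), a = integer(), b = integer(),
                          c = integer(), d = integer(), p = numeric(),
                          q = numeric(), direction = character()))
  }
  na <- length(list_a); nb <- length(list_b)
  out <- purrr::imap_dfr(term_genes, function(genes, term) {
    a <- sum(list_a %in% genes)
    c <- sum(list_b %in% genes)
    tab <- matrix(c(a, c, na - a, nb - c), nrow = 2)
    tibble::tibble(
      term = term, a = a, b = na - a, c = c, d = nb - c,
      p = fisher_exact_2x2(tab)$p_two_sided,
      direction = ifelse(a / na >= c / nb, "A", "B")
    )
  })
  out$q <- stats::p.adjust(out$p, method = "BH")
  meta_cols <- intersect(c("namespace", "level"), names(annotations))
  if (length(meta_cols) > 0L) {
    meta <- dplyr::distinct(ann, .data$term, .keep_all = TRUE) |>
      dplyr::select("term", dplyr::all_of(meta_cols))
    out <- dplyr::left_join(out, meta, by = "term")
  }
  dplyr::arrange(out, .data$p) |>
    dplyr::relocate("q", .after = "p")
}

#' Chromosome concentration of a term's genes
#'
#' Checks whether a term's over-representation could be driven by a gene
#' cluster: the fraction of the term's located genes sitting on the single
#' most-populated chromosome, flagged when it reaches a threshold. This
#' formalizes the diagnosis that, e.g., a histone-family cluster on one
#' chromosome explains a chromatin-term signal.
#'
#' @param term_genes Character vector of the term's gene ids.
#' @param gene_records Tibble with `gene_id` and `chromosome` (unknown
#'   locations as `NA` or `"Un"`).
#' @param threshold Flagging threshold on the fraction (default 0.5).
#' @return One-row tibble: `top_chromosome`, `n_located`,
#'   `fraction_on_top`, `flagged`.
#' @export
chromosome_concentration <- function(term_genes, gene_records, threshold = 0.5) {
  located <- gene_records |>
    dplyr::filter(.data$gene_id %in% term_genes,
                  !is.na(.data$chromosome), .data$chromosome != "Un")
  if (nrow(located) == 0L) {
    stop("chromosome_concentration(): no genes with a known chromosome",
         call. = FALSE)
  }
  counts <- sort(table(located$chromosome), decreasing = TRUE)
  frac <- as.numeric(counts[1]) / nrow(located)
  tibble::tibble(
    top_chromosome = names(counts)[1],
    n_located = nrow(located),
    fraction_on_top = frac,
    flagged = frac >= threshold
  )
}

#' Per-term GC summary against the cohort
#'
#' Mean GC of the genes carrying a term, compared with the mean over the
#' whole cohort.
#'
#' @param term_genes Character vector of the term's gene ids.
#' @param gene_gc Tibble with `gene_id` and `gc` (any GC measure: GC3 or
#'   whole-gene GC).
#' @return One-row tibble: `term_mean`, `cohort_mean`, `difference`, `n`.
#' @export
category_gc_summary <- function(term_genes, gene_gc) {
  cohort <- gene_gc$gc[!is.na(gene_gc$gc)]
  term_vals <- gene_gc$gc[gene_gc$gene_id %in% term_genes & !is.na(gene_gc$gc)]
  if (length(term_vals) == 0L) {
    stop("category_gc_summary(): no GC value for any gene of the term",
         call. = FALSE)
  }
  tibble::tibble(
    term_mean = mean(term_vals),
    cohort_mean = mean(cohort),
    difference = mean(term_vals) - mean(cohort),
    n = length(term_vals)
  )
}
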