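#' Species karyotype rule
#'
#' A karyotype rule assigns chromosome labels to a size class
#' (macrochromosome vs microchromosome). Rules are data, not code: each
#' species carries its own label sets, an "unknown location" sentinel and an
#' optional set of labels excluded from analysis (e.g. chromosomes absent
#' from a genome assembly).
#'
#' @param species_id Species identifier string.
#' @param macro_labels,micro_labels Disjoint character vectors of
#'   chromosome labels.
#' @param unknown_label Sentinel for unplaced genes (default `"Un"`).
#' @param excluded_labels Labels documented as excluded from analysis.
#' @return A `karyotype` list object.
#' @seealso [default_karyotypes()] for the shipped snake and chicken rules.
#' @export
karyotype <- function(species_id, macro_labels, micro_labels,
                      unknown_label = "Un", excluded_labels = character()) {
  macro_labels <- as.character(macro_labels)
  micro_labels <- as.character(micro_labels)
  if (length(intersect(macro_labels, micro_labels)) > 0L) {
    stop("karyotype(): macro and micro label sets must be disjoint", call. = FALSE)
  }
  structure(
    list(species_id = species_id, macro_labels = macro_labels,
         micro_labels = micro_labels, unknown_label = unknown_label,
         excluded_labels = as.character(excluded_labels)),
    class = "karyotype"
  )
}

#' Shipped karyotype rules
#'
#' Default rules for the Japanese four-striped rat snake (macrochromosomes
#' 1-7, Z and W; ten microchromosome pairs labelled 8-17) and chicken
#' (macrochromosomes 1-8, Z and W; microchromosomes 9-28; chromosomes
#' 29-31 and 33-38 are absent from the assembly and 32 carries no assigned
#' genes, so those labels are recorded as excluded).
#'
#' @return Named list of [karyotype()] objects (`snake`, `chicken`).
#' @export
default_karyotypes <- function() {
  list(
    snake = karyotype("snake",
                      macro_labels = c(as.character(1:7), "Z", "W"),
                      micro_labels = as.character(8:17)),
    chicken = karyotype("chicken",
                        macro_labels = c(as.character(1:8), "Z", "W"),
                        micro_labels = as.character(9:28),
                        excluded_labels = as.character(c(29:32, 33:38)))
  )
}

# Strip arm suffixes so "4p"/"2q31" match their chromosome label.
normalize_chromosome_label <- function(labels) {
  sub("^([0-9]+|[A-Za-z]+)[pq].*$", "\\1", as.character(labels))
}

#' Classify chromosome labels by size class
#'
#' Deterministic, total classification: labels in the macro set map to
#' `macro`, labels in the micro set to `micro`, the sentinel and anything
#' else to `unknown`. Arm suffixes ("4p", "2q") are stripped before lookup.
#'
#' @param kar A [karyotype()].
#' @param labels Character vector of chromosome labels.
#' @return Factor with levels `macro`, `micro`, `unknown`.
#' @examples
#' classify_chromosome(default_karyotypes()$chicken, c("9", "Z", "Un"))
#' @export
classify_chromosome <- function(kar, labels) {
  stopifnot(inherits(kar, "karyotype"))
  lab <- normalize_chromosome_label(labels)
  cls <- dplyr::case_when(
    lab %in% kar$macro_labels ~ "macro",
    lab %in% kar$micro_labels ~ "micro",
    .default = "unknown"
  )
  factor(cls, levels = c("macro", "micro", "unknown"))
}

#' Assign ortholog pairs to the four chromosome-class categories
#'
#' Orthologs shared between two species are grouped by the size classes of
#' the chromosomes carrying them: group 1 = macro in both, 2 = micro in
#' both, 3 = macro in species A / micro in species B, 4 = micro in A /
#' macro in B. A pair with an unknown location on either side is excluded.
#'
#' @param class_a,class_b Size-class vectors (as from
#'   [classify_chromosome()]) for species A and B.
#' @return Factor with levels `"1"`-`"4"` and `"excluded"`.
#' @export
assign_pair_group <- function(class_a, class_b) {
  a <- as.character(class_a); b <- as.character(class_b)
  grp <- dplyr::case_when(
    a == "unknown" | b == "unknown" ~ "excluded",
    a == "macro" & b == "macro" ~ "1",
    a == "micro" & b == "micro" ~ "2",
    a == "macro" & b == "micro" ~ "3",
    a == "micro" & b == "macro" ~ "4"
  )
  factor(grp, levels = c("1", "2", "3", "4", "excluded"))
}

#' Contingency table of GC class by chromosome size class
#'
#' Cross-tabulates GC-rich/GC-poor genes (via [classify_gc()]) against
#' macro/micro chromosome class, with row and column margins — the layout
#' of a classic karyotype-by-composition summary table. Records with a
#' missing GC3 are skipped with a warning and their count is attached as
#' the `n_skipped` attribute.
#'
#' @param records Tibble with columns `size_class` (`macro`/`micro`) and
#'   `gc3`.
#' @param cutoff GC-rich boundary passed to [classify_gc()].
#' @return Tibble with rows `macro`, `micro`, `total` and columns
#'   `size_class`, `gc_rich`, `gc_poor`, `total`.
#' @export
tabulate_gc_by_class <- function(records, cutoff = 50) {
  n_skipped <- 0L
  if (nrow(records) > 0L) {
    n_skipped <- sum(is.na(records$gc3))
    if (n_skipped > 0L) {
      warning(sprintf("tabulate_gc_by_class(): skipped %d record(s) with missing gc3",
                      n_skipped), call. = FALSE)
      records <- dplyr::filter(records, !is.na(.data$gc3))
    }
  }
  cells <- function(cls) {
    sub <- records[as.character(records$size_class) == cls, , drop = FALSE]
    if (nrow(sub) == 0L) return(c(rich = 0L, poor = 0L))
    gc_cls <- classify_gc(sub$gc3, cutoff)
    c(rich = sum(gc_cls == "GC-rich"), poor = sum(gc_cls == "GC-poor"))
  }
  ma <- cells("macro"); mi <- cells("micro")
  out <- tibble::tibble(
    size_class = c("macro", "micro", "total"),
    gc_rich = unname(c(ma["rich"], mi["rich"], ma["rich"] + mi["rich"])),
    gc_poor = unname(c(ma["poor"], mi["poor"], ma["poor"] + mi["poor"]))
  )
  out$total <- out$gc_rich + out$gc_poor
  attr(out, "n_skipped") <- n_skipped
  out
}
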