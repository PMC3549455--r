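#' Per-gene GC profiles, with optional reading-frame inference
#'
#' The entry point of the analysis: computes GC3/GC4 profiles for a set of
#' nucleotide sequences. Without reference proteins the inputs are treated
#' as framed coding sequences (frame 0). With references, the reading
#' frame and coding span of each sequence are first inferred by six-frame
#' translated local alignment ([best_frame_alignment()]) against the
#' reference of the same name (or a single shared reference), and profiles
#' are computed on the called span; sequences without a confident frame
#' are reported with `NA` profiles.
#'
#' @param sequences Named character vector of nucleotide sequences, or a
#'   path to a FASTA file.
#' @param proteins Optional named character vector (or FASTA path) of
#'   reference proteins.
#' @param min_score Significance gate for frame inference.
#' @param code A [genetic_code()].
#' @return Tibble: `gene_id`, `frame`, `strand`, `start`, `end` (0-based
#'   half-open coding span), `score`, `identity`, `gc3`, `gc4`,
#'   `gc_overall`, `n_codons`, `n_fourfold`.
#' @export
profile_genes <- function(sequences, proteins = NULL,
                          min_score = DEFAULT_MIN_FRAME_SCORE,
                          code = genetic_code()) {
  if (is.character(sequences) && length(sequences) == 1L && file.exists(sequences)) {
    sequences <- read_fasta(sequences)
  }
  if (!is.null(proteins) && is.character(proteins) && length(proteins) == 1L &&
      file.exists(proteins)) {
    proteins <- read_fasta(proteins)
  }
  if (length(sequences) == 0L) {
    return(tibble::tibble(gene_id = character(), frame = integer(),
                          strand = character(), start = integer(),
                          end = integer(), score = numeric(),
                          identity = numeric(), gc3 = numeric(),
                          gc4 = numeric(), gc_overall = numeric(),
                          n_codons = integer(), n_fourfold = integer()))
  }
  ids <- names(sequences)
  if (is.null(ids)) ids <- sprintf("seq%04d", seq_along(sequences))
  purrr::map_dfr(seq_along(sequences), function(i) {
    nt <- toupper(sequences[[i]])
    if (is.null(proteins)) {
      prof <- gc_profile(nt, 0L, code)
      return(dplyr::bind_cols(
        tibble::tibble(gene_id = ids[i], frame = 0L, strand = "+",
                       start = 0L, end = 3L * (nchar(nt) %/% 3L),
                       score = NA_real_, identity = NA_real_),
        prof))
    }
    ref <- if (ids[i] %in% names(proteins)) proteins[[ids[i]]]
           else if (length(proteins) == 1L) proteins[[1L]]
           else NA_character_
    empty_prof <- tibble::tibble(gc3 = NA_real_, gc4 = NA_real_,
                                 gc_overall = NA_real_, n_codons = 0L,
                                 n_fourfold = 0L)
    if (is.na(ref)) {
      return(dplyr::bind_cols(
        tibble::tibble(gene_id = ids[i], frame = NA_integer_, strand = NA_character_,
                       start = NA_integer_, end = NA_integer_,
                       score = NA_real_, identity = NA_real_),
        empty_prof))
    }
    fa <- best_frame_alignment(nt, ref, min_score = min_score)
    if (!fa$confident) {
      return(dplyr::bind_cols(
        tibble::tibble(gene_id = ids[i], frame = fa$frame, strand = fa$strand,
                       start = NA_integer_, end = NA_integer_,
                       score = fa$score, identity = fa$identity),
        empty_prof))
    }
    orf <- call_orf(nt, fa)
    cds <- substr(nt, orf$start + 1L, orf$end)
    if (orf$strand == "-") {
      cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    }
    dplyr::bind_cols(
      tibble::tibble(gene_id = ids[i], frame = fa$frame, strand = orf$strand,
                     start = orf$start, end = orf$end,
                     score = fa$score, identity = fa$identity),
      gc_profile(cds, 0L, code))
  })
}

#' Intra-genomic GC3 heterogeneity analysis
#'
#' The chromosome-class comparison of a per-gene GC3 table: the
#' GC-rich/GC-poor by macro/micro contingency table with margins,
#' per-class descriptive statistics, a Mann-Whitney U test of the class
#' difference, and the one- vs two-Gaussian bimodality comparison of the
#' pooled distribution. With fewer than two classes the comparison steps
#' are skipped with a warning.
#'
#' @param genes Tibble with `gc3` and `size_class` (and anything else,
#'   carried along).
#' @param cutoff GC-rich boundary (default 50).
#' @param bin_width Histogram bin width for the mixture comparison.
#' @return Object of class `gc_heterogeneity`: list with `contingency`,
#'   `class_stats`, `u_test` (`NULL` when skipped), `mixture` (a
#'   `mixture_comparison`, `NULL` when fewer than 30 values), `n`.
#' @export
heterogeneity_analysis <- function(genes, cutoff = 50, bin_width = 5) {
  genes <- dplyr::filter(genes, !is.na(.data$gc3))
  classes <- intersect(c("macro", "micro"), unique(as.character(genes$size_class)))
  class_stats <- purrr::map_dfr(classes, function(cls) {
    dplyr::bind_cols(tibble::tibble(size_class = cls),
                     describe(genes$gc3[genes$size_class == cls]))
  })
  u_test <- NULL
  contingency <- tabulate_gc_by_class(genes, cutoff)
  if (length(classes) == 2L) {
    u_test <- mann_whitney_u(genes$gc3[genes$size_class == "macro"],
                             genes$gc3[genes$size_class == "micro"])
  } else {
    warning("heterogeneity_analysis(): fewer than 2 size classes; ",
            "class comparison skipped", call. = FALSE)
  }
  mixture <- if (nrow(genes) >= 30L) {
    fit_mixture_and_compare(genes$gc3, bin_width = bin_width)
  } else NULL
  structure(list(contingency = contingency, class_stats = class_stats,
                 u_test = u_test, mixture = mixture, n = nrow(genes)),
            class = "gc_heterogeneity")
}

#' @export
print.gc_heterogeneity <- function(x, ...) {
  cat(sprintf("GC3 heterogeneity analysis of %d genes\n\n", x$n))
  print(x$contingency)
  cat("\nPer-class GC3:\n"); print(x$class_stats)
  if (!is.null(x$u_test)) {
    cat(sprintf("\nMann-Whitney U = %g, p = %.3g\n",
                x$u_test$statistic, x$u_test$p_two_sided))
  }
  if (!is.null(x$mixture)) print(x$mixture)
  invisible(x)
}

#' Cross-species ortholog GC3 comparison
#'
#' Computes the Spearman correlation of GC3 between every pair of species
#' sharing at least 3 orthologs (pairs with a missing value dropped per
#' species pair). When the table carries a `pair_group` column (the
#' four-category chromosome-class grouping of [assign_pair_group()]),
#' group-wise summaries and tests are added: per group and species
#' descriptive statistics, a between-species Mann-Whitney U test within
#' each group, and a Kruskal-Wallis + Dunn comparison across groups within
#' each species. Groups with fewer than `min_group_n` orthologs are
#' reported but flagged as not statistically compared.
#'
#' @param orthologs Long tibble: `ortholog_id`, `species`, `gc3`, and
#'   optionally `pair_group`.
#' @param min_group_n Minimum group size for testing (default 5).
#' @return Object of class `cross_species`: list with `correlations`
#'   (tibble: `species_a`, `species_b`, `rho`, `p`, `n`),
#'   `group_stats`, `group_tests` (between-species, per group),
#'   `within_species` (named list of Kruskal-Wallis + Dunn results), each
#'   `NULL` without grouping.
#' @export
cross_species_analysis <- function(orthologs, min_group_n = 5L) {
  species <- unique(orthologs$species)
  if (length(species) < 2L) {
    stop("cross_species_analysis(): need at least 2 species", call. = FALSE)
  }
  wide <- orthologs |>
    dplyr::select("ortholog_id", "species", "gc3") |>
    tidyr::pivot_wider(names_from = "species", values_from = "gc3")
  combos <- utils::combn(species, 2)
  correlations <- purrr::map_dfr(seq_len(ncol(combos)), function(i) {
    sa <- combos[1, i]; sb <- combos[2, i]
    ok <- !(is.na(wide[[sa]]) | is.na(wide[[sb]]))
    if (sum(ok) < 3L) {
      stop(sprintf("cross_species_analysis(): fewer than 3 shared orthologs for %s-%s",
                   sa, sb), call. = FALSE)
    }
    cr <- spearman_rank(wide[[sa]][ok], wide[[sb]][ok])
    tibble::tibble(species_a = sa, species_b = sb, rho = cr$rho,
                   p = cr$p_two_sided, n = cr$n)
  })
  group_stats <- group_tests <- within_species <- NULL
  if ("pair_group" %in% names(orthologs)) {
    grp_tbl <- dplyr::filter(orthologs, !is.na(.data$pair_group),
                             .data$pair_group != "excluded")
    group_stats <- grp_tbl |>
      dplyr::group_by(.data$pair_group, .data$species) |>
      dplyr::summarise(describe(.data$gc3), .groups = "drop") |>
      dplyr::mutate(tested = .data$n >= min_group_n)
    groups <- sort(unique(as.character(grp_tbl$pair_group)))
    group_tests <- purrr::map_dfr(groups, function(g) {
      sub <- dplyr::filter(grp_tbl, .data$pair_group == g)
      counts <- table(sub$species)
      if (any(counts < min_group_n) || length(counts) < 2L) {
        return(tibble::tibble(pair_group = g, species_a = NA_character_,
                              species_b = NA_character_, statistic = NA_real_,
                              p = NA_real_, tested = FALSE))
      }
      sp <- names(counts)[1:2]
      ut <- mann_whitney_u(sub$gc3[sub$species == sp[1]],
                           sub$gc3[sub$species == sp[2]])
      tibble::tibble(pair_group = g, species_a = sp[1], species_b = sp[2],
                     statistic = ut$statistic, p = ut$p_two_sided,
                     tested = TRUE)
    })
    tested_groups <- group_tests$pair_group[group_tests$tested]
    if (length(tested_groups) >= 2L) {
      within_species <- purrr::map(stats::setNames(nm = species), function(sp) {
        sub <- dplyr::filter(grp_tbl, .data$species == sp,
                             .data$pair_group %in% tested_groups)
        kruskal_wallis_dunn(split(sub$gc3, as.character(sub$pair_group)))
      })
    }
  }
  structure(list(correlations = correlations, group_stats = group_stats,
                 group_tests = group_tests, within_species = within_species),
            class = "cross_species")
}

#' @export
print.cross_species <- function(x, ...) {
  cat("Cross-species GC3 correlations:\n"); print(x$correlations)
  if (!is.null(x$group_stats)) {
    cat("\nChromosome-class group summaries:\n"); print(x$group_stats)
  }
  invisible(x)
}

#' Non-coding GC analysis of annotated contigs
#'
#' Computes per-contig non-coding GC ([noncoding_profile()]), pairs it
#' with per-gene GC3, reports their Spearman correlation, and — when a
#' `size_class` column is available — per-class descriptive statistics of
#' non-coding GC and a Mann-Whitney class comparison.
#'
#' @param contigs Named character vector of contig sequences (or FASTA
#'   path); names are gene/contig ids.
#' @param spans Tibble with `contig_id`, `start`, `end` (0-based
#'   half-open coding spans).
#' @param gene_table Tibble with `gene_id`, `gc3` and optionally
#'   `size_class` (ids match contig names).
#' @return Object of class `noncoding_gc`: list with `profiles`, `pairs`,
#'   `correlation`, `class_stats`, `u_test`.
#' @export
noncoding_analysis <- function(contigs, spans, gene_table) {
  if (is.character(contigs) && length(contigs) == 1L && file.exists(contigs)) {
    contigs <- read_fasta(contigs)
  }
  profiles <- purrr::map_dfr(names(contigs), function(id) {
    sp <- dplyr::filter(spans, .data$contig_id == id)
    dplyr::bind_cols(tibble::tibble(gene_id = id),
                     noncoding_profile(contigs[[id]], sp))
  })
  paired <- pair_gc3_noncoding(gene_table, profiles)
  class_stats <- u_test <- NULL
  if ("size_class" %in% names(gene_table)) {
    prof_cls <- dplyr::inner_join(
      profiles, dplyr::select(gene_table, "gene_id", "size_class"),
      by = "gene_id") |>
      dplyr::filter(!is.na(.data$gc_noncoding),
                    as.character(.data$size_class) %in% c("macro", "micro"))
    class_stats <- prof_cls |>
      dplyr::group_by(size_class = as.character(.data$size_class)) |>
      dplyr::summarise(describe(.data$gc_noncoding), .groups = "drop")
    if (length(unique(prof_cls$size_class)) == 2L) {
      u_test <- mann_whitney_u(
        prof_cls$gc_noncoding[prof_cls$size_class == "macro"],
        prof_cls$gc_noncoding[prof_cls$size_class == "micro"])
    }
  }
  structure(list(profiles = profiles, pairs = paired$pairs,
                 correlation = paired$correlation,
                 class_stats = class_stats, u_test = u_test),
            class = "noncoding_gc")
}

#' @export
print.noncoding_gc <- function(x, ...) {
  cat(sprintf("Non-coding GC analysis: %d paired genes\n", nrow(x$pairs)))
  cat(sprintf("GC3 ~ non-coding GC Spearman rho = %.3f (p = %.3g, n = %d)\n",
              x$correlation$rho, x$correlation$p_two_sided, x$correlation$n))
  if (!is.null(x$class_stats)) { cat("\nPer-class non-coding GC:\n"); print(x$class_stats) }
  invisible(x)
}

#' Category over-representation analysis with diagnostics
#'
#' Runs [over_representation()] between two gene lists and, for every term
#' at or below a q-value threshold, attaches the chromosome-concentration
#' diagnostic and the per-term GC summary when location/GC tables are
#' supplied.
#'
#' @param list_a,list_b Disjoint gene-id vectors.
#' @param annotations Tibble with `gene_id`, `term` (optional `namespace`,
#'   `level`).
#' @param gene_records Optional tibble with `gene_id`, `chromosome` for
#'   the concentration check.
#' @param gene_gc Optional tibble with `gene_id`, `gc` for the GC summary.
#' @param min_term_size,q_threshold,concentration_threshold Tuning
#'   parameters (defaults 5, 0.05, 0.5).
#' @return Object of class `enrichment`: list with `results` (the
#'   over-representation table, extended with `fraction_on_top`,
#'   `concentration_flagged`, `term_mean_gc`, `gc_difference` where
#'   available) and the input thresholds.
#' @export
enrichment_analysis <- function(list_a, list_b, annotations,
                                gene_records = NULL, gene_gc = NULL,
                                min_term_size = 5L, q_threshold = 0.05,
                                concentration_threshold = 0.5) {
  res <- over_representation(list_a, list_b, annotations, min_term_size)
  res$fraction_on_top <- NA_real_
  res$concentration_flagged <- NA
  res$term_mean_gc <- NA_real_
  res$gc_difference <- NA_real_
  sig <- which(res$q <= q_threshold)
  ann_terms <- split(annotations$gene_id, annotations$term)
  for (i in sig) {
    genes <- unique(ann_terms[[res$term[i]]])
    if (!is.null(gene_records)) {
      cc <- try(chromosome_concentration(genes, gene_records,
                                         concentration_threshold), silent = TRUE)
      if (!inherits(cc, "try-error")) {
        res$fraction_on_top[i] <- cc$fraction_on_top
        res$concentration_flagged[i] <- cc$flagged
      }
    }
    if (!is.null(gene_gc)) {
      gs <- try(category_gc_summary(genes, gene_gc), silent = TRUE)
      if (!inherits(gs, "try-error")) {
        res$term_mean_gc[i] <- gs$term_mean
        res$gc_difference[i] <- gs$difference
      }
    }
  }
  structure(list(results = res, min_term_size = min_term_size,
                 q_threshold = q_threshold,
                 concentration_threshold = concentration_threshold),
            class = "enrichment")
}

#' @export
print.enrichment <- function(x, ...) {
  cat(sprintf("Over-representation: %d terms tested, %d at q <= %g\n",
              nrow(x$results), sum(x$results$q <= x$q_threshold),
              x$q_threshold))
  print(utils::head(x$results, 10))
  invisible(x)
}

#' Simulate a complete synthetic study
#'
#' Writes every input format the analysis functions consume, generated
#' from a [landscape_config()] under one seed: a gene table
#' (`genes.tsv`), an ortholog table (`orthologs.tsv`), EST reads with
#' their reference proteins and planted spans (`ests.fasta`,
#' `proteins.fasta`, `est_truth.tsv`), annotated contigs with coding
#' spans and a per-contig truth table (`contigs.fasta`,
#' `coding_spans.bed`, `contig_truth.tsv`), and an enrichment input set
#' (`list_a.txt`, `list_b.txt`, `annotations.tsv`). Identical seeds give
#' identical files.
#'
#' @param config A [landscape_config()].
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_ests Number of EST constructs (default 5).
#' @param n_contigs Number of annotated contigs (default 40; capped at the
#'   configured non-coding cohort size).
#' @return Invisible list of the generated objects and file paths.
#' @export
simulate_study <- function(config = landscape_config(), dir = tempfile("study"),
                           seed = 1L, n_ests = 5L, n_contigs = 40L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)

  genes <- sample_gc3_landscape(config, seed)
  readr::write_tsv(genes, p("genes.tsv"))

  orthologs <- sample_ortholog_pairs(config, seed + 1L)
  readr::write_tsv(orthologs, p("orthologs.tsv"))

  # EST constructs with ground truth
  est <- with_seed(seed + 2L, {
    purrr::map(seq_len(n_ests), function(i) {
      prot <- paste(sample(setdiff(unique(unname(genetic_code())), "*"),
                           120L, replace = TRUE), collapse = "")
      cds <- synthesize_cds(prot, target_gc3 = stats::runif(1, 35, 65),
                            seed = sample.int(1e6, 1))
      e <- synthesize_est(cds, utr5_len = 80L, utr3_len = 60L,
                          strand = sample(c("+", "-"), 1),
                          seed = sample.int(1e6, 1))
      list(id = sprintf("est%03d", i), protein = prot, est = e)
    })
  })
  write_fasta(stats::setNames(purrr::map_chr(est, ~ .x$est$sequence),
                              purrr::map_chr(est, "id")), p("ests.fasta"))
  write_fasta(stats::setNames(purrr::map_chr(est, "protein"),
                              purrr::map_chr(est, "id")), p("proteins.fasta"))
  est_truth <- purrr::map_dfr(est, ~ tibble::tibble(
    gene_id = .x$id, start = .x$est$start, end = .x$est$end,
    strand = .x$est$strand))
  readr::write_tsv(est_truth, p("est_truth.tsv"))

  # Annotated contigs: per-class GC3 / non-coding GC pairs via the copula
  nc <- config$noncoding
  n_total <- min(n_contigs, nc$macro$n + nc$micro$n)
  n_ma <- round(n_total * nc$macro$n / (nc$macro$n + nc$micro$n))
  n_mi <- n_total - n_ma
  contig_truth <- with_seed(seed + 3L, {
    dplyr::bind_rows(
      dplyr::mutate(sample_coupled_gaussians(
        n_ma, config$macro$mean, config$macro$sd,
        nc$macro$mean, nc$macro$sd, config$noncoding_rho),
        size_class = "macro"),
      dplyr::mutate(sample_coupled_gaussians(
        n_mi, config$micro$mean, config$micro$sd,
        nc$micro$mean, nc$micro$sd, config$noncoding_rho),
        size_class = "micro")
    ) |>
      dplyr::rename(gc3_target = "x", noncoding_gc_target = "y") |>
      dplyr::mutate(gene_id = sprintf("contig%03d", dplyr::row_number()))
  })
  contig_objs <- with_seed(seed + 4L, {
    purrr::map(seq_len(nrow(contig_truth)), function(i) {
      prot <- paste(sample(setdiff(unique(unname(genetic_code())), "*"),
                           150L, replace = TRUE), collapse = "")
      cds <- synthesize_cds(prot, contig_truth$gc3_target[i],
                            seed = sample.int(1e6, 1))
      ct <- synthesize_contig(cds, intergenic_gc = contig_truth$noncoding_gc_target[i],
                              intron_gc = contig_truth$noncoding_gc_target[i],
                              layout = list(flank = 2000L, intron_length = 400L,
                                            n_introns = 2L),
                              seed = sample.int(1e6, 1))
      ct
    })
  })
  write_fasta(stats::setNames(purrr::map_chr(contig_objs, "sequence"),
                              contig_truth$gene_id), p("contigs.fasta"))
  spans <- purrr::map2_dfr(contig_objs, contig_truth$gene_id, function(ct, id) {
    dplyr::mutate(ct$spans, contig_id = id)
  })
  write_bed(spans, p("coding_spans.bed"))
  readr::write_tsv(contig_truth, p("contig_truth.tsv"))

  enr <- plant_enrichment(seed = seed + 5L)
  writeLines(enr$list_a, p("list_a.txt"))
  writeLines(enr$list_b, p("list_b.txt"))
  readr::write_tsv(enr$annotations, p("annotations.tsv"))

  invisible(list(
    dir = dir, genes = genes, orthologs = orthologs,
    est_truth = est_truth, contig_truth = contig_truth, spans = spans,
    enrichment = enr,
    paths = stats::setNames(
      file.path(dir, c("genes.tsv", "orthologs.tsv", "ests.fasta",
                       "proteins.fasta", "est_truth.tsv", "contigs.fasta",
                       "coding_spans.bed", "contig_truth.tsv", "list_a.txt",
                       "list_b.txt", "annotations.tsv")),
      c("genes", "orthologs", "ests", "proteins", "est_truth", "contigs",
        "coding_spans", "contig_truth", "list_a", "list_b", "annotations"))
  ))
}
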