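# Run code with a local RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Synthetic-cohort configuration
#'
#' Parameters of the seeded generators that emulate the statistical
#' structure of a sauropsid cDNA-mapping study: a two-class GC3 landscape
#' (macrochromosomal genes lower-GC than microchromosomal ones), a
#' four-category snake-chicken ortholog cohort coupled at a target rank
#' correlation, and non-coding GC distributions coupled to GC3. All
#' Gaussian means/SDs are percentages; class and group counts are gene
#' counts. See the methods vignette for the provenance of each default.
#'
#' @param macro,micro Lists `list(mean =, sd =, n =)` for the snake GC3
#'   landscape (defaults 41.5/8.6 with n = 144 and 56.4/10.5 with n = 39).
#' @param groups Per-category snake/chicken Gaussians and counts for the
#'   ortholog cohort (defaults: group 1 macro/macro n = 85, snake
#'   39.1/8.0 vs chicken 47.1/10.9; group 2 micro/micro n = 35, 57.4/9.8
#'   vs 54.9/13.7; group 3 macro/micro n = 49, 43.9/8.7 vs 55.7/12.8;
#'   group 4 micro/macro n = 3).
#' @param ortholog_rho Target Spearman correlation of ortholog GC3 within
#'   each group (default 0.51, the snake-chicken level).
#' @param noncoding Non-coding GC Gaussians per class (macro 36.8/3.5
#'   n = 139; micro 42.5/4.0 n = 37).
#' @param noncoding_rho Target Spearman correlation between GC3 and
#'   non-coding GC (default 0.73).
#' @param sister_rho Target Spearman correlation of GC3 between two close
#'   snake species (default 0.90).
#' @return A `landscape_config` list.
#' @export
landscape_config <- function(
    macro = list(mean = 41.5, sd = 8.6, n = 144L),
    micro = list(mean = 56.4, sd = 10.5, n = 39L),
    groups = list(
      `1` = list(n = 85L, snake = c(39.1, 8.0), chicken = c(47.1, 10.9)),
      `2` = list(n = 35L, snake = c(57.4, 9.8), chicken = c(54.9, 13.7)),
      `3` = list(n = 49L, snake = c(43.9, 8.7), chicken = c(55.7, 12.8)),
      `4` = list(n = 3L,  snake = c(56.4, 10.5), chicken = c(47.1, 10.9))
    ),
    ortholog_rho = 0.51,
    noncoding = list(macro = list(mean = 36.8, sd = 3.5, n = 139L),
                     micro = list(mean = 42.5, sd = 4.0, n = 37L)),
    noncoding_rho = 0.73,
    sister_rho = 0.90) {
  cfg <- list(macro = macro, micro = micro, groups = groups,
              ortholog_rho = ortholog_rho, noncoding = noncoding,
              noncoding_rho = noncoding_rho, sister_rho = sister_rho)
  stopifnot(macro$sd > 0, micro$sd > 0, macro$n >= 0, micro$n >= 0,
            abs(ortholog_rho) < 1, abs(noncoding_rho) < 1, abs(sister_rho) < 1)
  structure(cfg, class = "landscape_config")
}

# Gaussian draws clamped (truncated) to the percent scale.
rnorm_pct <- function(n, mean, sd) pmin(pmax(stats::rnorm(n, mean, sd), 0), 100)

#' Sample coupled Gaussian pairs at a target Spearman correlation
#'
#' Draws pairs from a Gaussian copula whose latent Pearson correlation
#' `2 sin(pi rho_s / 6)` yields the requested Spearman correlation, with
#' Gaussian marginals clamped to \[0, 100\].
#'
#' @param n Number of pairs.
#' @param mean1,sd1,mean2,sd2 Marginal parameters (percent scale).
#' @param rho_s Target Spearman correlation in (-1, 1).
#' @return Tibble with columns `x`, `y`.
#' @export
sample_coupled_gaussians <- function(n, mean1, sd1, mean2, sd2, rho_s) {
  stopifnot(abs(rho_s) < 1, sd1 > 0, sd2 > 0)
  r <- 2 * sin(pi * rho_s / 6)
  z1 <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
  tibble::tibble(x = pmin(pmax(mean1 + sd1 * z1, 0), 100),
                 y = pmin(pmax(mean2 + sd2 * z2, 0), 100))
}

#' Sample a two-class GC3 landscape
#'
#' Generates a cohort of gene records with chromosome labels, size classes
#' and GC3 values drawn from the per-class Gaussians of the configuration
#' (clamped to \[0, 100\]). Macro genes receive labels from the snake
#' macrochromosome set (1-7, Z, W), micro genes from 8-17, uniformly.
#'
#' @param config A [landscape_config()].
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return Tibble: `gene_id`, `species`, `chromosome`, `size_class`,
#'   `gc3`.
#' @export
sample_gc3_landscape <- function(config = landscape_config(), seed = 1L) {
  kar <- default_karyotypes()$snake
  with_seed(seed, {
    n_ma <- config$macro$n; n_mi <- config$micro$n
    tibble::tibble(
      gene_id = sprintf("gene%04d", seq_len(n_ma + n_mi)),
      species = "snake",
      chromosome = c(sample(kar$macro_labels, n_ma, replace = TRUE),
                     sample(kar$micro_labels, n_mi, replace = TRUE)),
      size_class = factor(rep(c("macro", "micro"), c(n_ma, n_mi)),
                          levels = c("macro", "micro", "unknown")),
      gc3 = c(rnorm_pct(n_ma, config$macro$mean, config$macro$sd),
              rnorm_pct(n_mi, config$micro$mean, config$micro$sd))
    )
  })
}

#' Sample a four-category snake-chicken ortholog cohort
#'
#' For each chromosome-class category, draws per-species GC3 from the
#' configured Gaussians coupled by a Gaussian copula at the configured
#' Spearman correlation, and assigns chromosome labels consistent with the
#' category (e.g. group 3 = snake macro, chicken micro).
#'
#' @param config A [landscape_config()].
#' @param seed Integer seed.
#' @return Long tibble: `ortholog_id`, `pair_group`, `species`,
#'   `chromosome`, `size_class`, `gc3` (two rows per ortholog).
#' @export
sample_ortholog_pairs <- function(config = landscape_config(), seed = 1L) {
  kars <- default_karyotypes()
  class_of <- list(`1` = c("macro", "macro"), `2` = c("micro", "micro"),
                   `3` = c("macro", "micro"), `4` = c("micro", "macro"))
  labels_for <- function(kar, cls, n) {
    pool <- if (cls == "macro") kar$macro_labels else kar$micro_labels
    sample(pool, n, replace = TRUE)
  }
  with_seed(seed, {
    offset <- 0L
    purrr::imap_dfr(config$groups, function(g, gname) {
      if (g$n == 0L) return(NULL)
      cls <- class_of[[gname]]
      xy <- sample_coupled_gaussians(g$n, g$snake[1], g$snake[2],
                                     g$chicken[1], g$chicken[2],
                                     config$ortholog_rho)
      ids <- sprintf("og%04d", offset + seq_len(g$n))
      offset <<- offset + g$n
      tibble::tibble(
        ortholog_id = rep(ids, 2),
        pair_group = gname,
        species = rep(c("snake", "chicken"), each = g$n),
        chromosome = c(labels_for(kars$snake, cls[1], g$n),
                       labels_for(kars$chicken, cls[2], g$n)),
        size_class = rep(cls, each = g$n),
        gc3 = c(xy$x, xy$y)
      )
    })
  })
}

# Split the codons of a genetic code by amino acid and third-base class.
codon_choices <- function(code = genetic_code()) {
  codons <- names(code)[code != "*"]
  aa <- unname(code[codons])
  third_gc <- substr(codons, 3, 3) %in% c("G", "C")
  list(gc = split(codons[third_gc], aa[third_gc]),
       at = split(codons[!third_gc], aa[!third_gc]))
}

#' Synthesize a CDS with a target GC3
#'
#' Back-translates a protein choosing synonymous codons so that the
#' realized GC3 is as close to the target as codon granularity allows: the
#' number of G/C-ending codons is fixed at `round(target/100 * n)` and the
#' sites receiving them are drawn at random among the residues with
#' synonymous third-base freedom (all except Met and Trp, which force
#' G-ending codons). Within the chosen third-base class the codon is drawn
#' uniformly.
#'
#' @param protein Amino-acid string over the 20 standard residues.
#' @param target_gc3 Target GC3 percent; must be feasible for the protein
#'   (at least the fraction forced by Met/Trp).
#' @param seed Integer seed.
#' @param code A [genetic_code()].
#' @return Nucleotide string; `translate_dna()` of it reproduces `protein`
#'   exactly.
#' @export
synthesize_cds <- function(protein, target_gc3, seed = 1L, code = genetic_code()) {
  aa <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  stopifnot(length(aa) >= 1L)
  choices <- codon_choices(code)
  if (!all(aa %in% union(names(choices$gc), names(choices$at)))) {
    stop("synthesize_cds(): protein contains a non-standard residue", call. = FALSE)
  }
  n <- length(aa)
  has_at <- aa %in% names(choices$at)
  forced_gc <- !has_at                      # Met, Trp: only G/C-ending codons
  n_forced <- sum(forced_gc)
  k_target <- round(target_gc3 / 100 * n)
  k_free <- k_target - n_forced
  n_free <- n - n_forced
  if (k_free < 0L || k_free > n_free) {
    stop(sprintf(
      "synthesize_cds(): target GC3 %.1f infeasible; feasible range is [%.1f, 100] for this protein",
      target_gc3, 100 * n_forced / n), call. = FALSE)
  }
  with_seed(seed, {
    gc_sites <- forced_gc
    free_idx <- which(!forced_gc)
    if (k_free > 0L) gc_sites[sample(free_idx, k_free)] <- TRUE
    codons <- vapply(seq_len(n), function(i) {
      pool <- if (gc_sites[i]) choices$gc[[aa[i]]] else choices$at[[aa[i]]]
      if (length(pool) == 1L) pool else sample(pool, 1L)
    }, character(1))
    paste(codons, collapse = "")
  })
}

# Random nucleotide string at a given GC percent (per-base draws).
random_dna <- function(n, gc_pct) {
  if (n == 0L) return("")
  is_gc <- stats::runif(n) < gc_pct / 100
  base <- ifelse(is_gc, sample(c("G", "C"), n, replace = TRUE),
                 sample(c("A", "T"), n, replace = TRUE))
  paste(base, collapse = "")
}

# Substitute bases at a given per-base rate.
mutate_dna <- function(s, rate) {
  if (rate == 0 || nchar(s) == 0L) return(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Synthesize an EST-like read around a CDS
#'
#' Wraps a CDS in untranslated flanks of chosen length and GC-content,
#' optionally applies single-pass sequencing errors (substitutions only),
#' and reports the planted coding span as ground truth. With
#' `strand = "-"` the whole construct is reverse-complemented and the span
#' is reported in forward coordinates of the returned sequence.
#'
#' @param cds Coding nucleotide string.
#' @param utr5_len,utr3_len Flank lengths (>= 0).
#' @param utr_gc Flank GC percent (default 40).
#' @param error_rate Per-base substitution probability in \[0, 0.05\].
#' @param strand `"+"` or `"-"`.
#' @param seed Integer seed.
#' @return List: `sequence`, `start`, `end` (0-based half-open planted
#'   span), `strand`.
#' @export
synthesize_est <- function(cds, utr5_len = 0L, utr3_len = 0L, utr_gc = 40,
                           error_rate = 0, strand = "+", seed = 1L) {
  stopifnot(utr5_len >= 0L, utr3_len >= 0L,
            error_rate >= 0, error_rate <= 0.05, strand %in% c("+", "-"))
  with_seed(seed, {
    seq <- paste0(random_dna(utr5_len, utr_gc), toupper(cds),
                  random_dna(utr3_len, utr_gc))
    seq <- mutate_dna(seq, error_rate)
    start <- utr5_len
    end <- utr5_len + nchar(cds)
    if (strand == "-") {
      L <- nchar(seq)
      seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
      sp <- c(L - end, L - start)
      start <- sp[1]; end <- sp[2]
    }
    list(sequence = seq, start = start, end = end, strand = strand)
  })
}

#' Synthesize an annotated genomic contig
#'
#' Lays out one or more CDSs on a contig with flanking sequence and
#' optional introns, all non-coding DNA drawn per-base at configured
#' GC-contents, and returns the ground-truth coding spans (0-based
#' half-open, exon-level).
#'
#' @param cds_list Character vector of coding sequences (may be empty for
#'   a pure non-coding contig).
#' @param intergenic_gc,intron_gc Non-coding GC percentages.
#' @param layout List: `flank` (length of leading/trailing/intergenic
#'   segments), `intron_length`, `n_introns` (per CDS).
#' @param seed Integer seed.
#' @return List: `sequence`, `spans` (tibble `start`, `end`, `gene_id`).
#' @export
synthesize_contig <- function(cds_list, intergenic_gc = 40, intron_gc = 40,
                              layout = list(flank = 1000L, intron_length = 0L,
                                            n_introns = 0L),
                              seed = 1L) {
  stopifnot(layout$flank >= 0L, layout$intron_length >= 0L, layout$n_introns >= 0L)
  with_seed(seed, {
    pieces <- character(0)
    spans <- list()
    pos <- 0L
    add <- function(s) {
      pieces[[length(pieces) + 1L]] <<- s
      pos <<- pos + nchar(s)
    }
    add(random_dna(layout$flank, intergenic_gc))
    for (gi in seq_along(cds_list)) {
      cds <- toupper(cds_list[[gi]])
      n_in <- layout$n_introns
      # split the CDS into n_introns + 1 exon chunks at codon boundaries
      n_cod <- nchar(cds) %/% 3L
      cuts <- if (n_in > 0L && n_cod > n_in) {
        sort(sample(seq_len(n_cod - 1L), n_in)) * 3L
      } else integer(0)
      bounds <- c(0L, cuts, nchar(cds))
      for (ei in seq_len(length(bounds) - 1L)) {
        exon <- substr(cds, bounds[ei] + 1L, bounds[ei + 1L])
        spans[[length(spans) + 1L]] <- tibble::tibble(
          start = pos, end = pos + nchar(exon),
          gene_id = sprintf("gene%03d", gi))
        add(exon)
        if (ei < length(bounds) - 1L) {
          add(random_dna(layout$intron_length, intron_gc))
        }
      }
      add(random_dna(layout$flank, intergenic_gc))
    }
    list(sequence = paste(pieces, collapse = ""),
         spans = if (length(spans)) dplyr::bind_rows(spans)
                 else tibble::tibble(start = integer(), end = integer(),
                                     gene_id = character()))
  })
}

#' Plant a single enriched annotation term
#'
#' Builds two disjoint gene lists and a term annotation table in which one
#' planted term is carried at `base_rate * relative_risk` in list A versus
#' `base_rate` in list B, while every other term is carried at `base_rate`
#' in both lists (the global null).
#'
#' @param n_genes Genes per list.
#' @param n_terms Total number of terms (the planted one plus nulls).
#' @param planted_term Id of the enriched term (default `"T001"`).
#' @param relative_risk Carriage-rate ratio A:B for the planted term
#'   (>= 1).
#' @param base_rate Null per-gene carriage probability (default 0.2).
#' @param seed Integer seed.
#' @return List: `list_a`, `list_b`, `annotations` (tibble `gene_id`,
#'   `term`), `planted_term`.
#' @export
plant_enrichment <- function(n_genes = 100L, n_terms = 51L,
                             planted_term = "T001", relative_risk = 3,
                             base_rate = 0.2, seed = 1L) {
  stopifnot(relative_risk >= 1, base_rate > 0, base_rate * relative_risk <= 1)
  with_seed(seed, {
    list_a <- sprintf("A%04d", seq_len(n_genes))
    list_b <- sprintf("B%04d", seq_len(n_genes))
    terms <- unique(c(planted_term, sprintf("T%03d", seq_len(n_terms) + 1L)))[seq_len(n_terms)]
    ann <- purrr::map_dfr(terms, function(tm) {
      rate_a <- if (tm == planted_term) base_rate * relative_risk else base_rate
      carriers <- c(list_a[stats::runif(n_genes) < rate_a],
                    list_b[stats::runif(n_genes) < base_rate])
      if (length(carriers) == 0L) return(NULL)
      tibble::tibble(gene_id = carriers, term = tm)
    })
    list(list_a = list_a, list_b = list_b, annotations = ann,
         planted_term = planted_term)
  })
}
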