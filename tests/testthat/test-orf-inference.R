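test_that("a planted exact coding region is recovered with identity 100", {
  prot <- random_protein(50)
  cds <- synthesize_cds(prot, 50, seed = 3)
  est <- synthesize_est(cds, utr5_len = 45, utr3_len = 30, seed = 4)
  fa <- best_frame_alignment(est$sequence, prot)
  expect_true(fa$confident)
  expect_equal(fa$strand, "+")
  expect_equal(fa$identity, 100)
  expect_equal(fa$ref_start, 0L)
  expect_equal(fa$ref_end, 50L)
  orf <- call_orf(est$sequence, fa)
  expect_equal(orf$start, est$start)
  expect_equal(orf$end, est$end)
})

test_that("the same construct on the reverse strand scores identically", {
  prot <- random_protein(50)
  cds <- synthesize_cds(prot, 50, seed = 7)
  fwd <- synthesize_est(cds, 45, 30, strand = "+", seed = 8)
  rev <- synthesize_est(cds, 45, 30, strand = "-", seed = 8)
  fa_f <- best_frame_alignment(fwd$sequence, prot)
  fa_r <- best_frame_alignment(rev$sequence, prot)
  expect_true(fa_r$frame %in% 3:5)
  expect_equal(fa_r$score, fa_f$score)
  orf_r <- call_orf(rev$sequence, fa_r)
  expect_equal(orf_r$start, rev$start)
  expect_equal(orf_r$end, rev$end)
  expect_equal(orf_r$strand, "-")
})

test_that("span arithmetic maps amino-acid spans to nucleotide spans", {
  fa0 <- tibble::tibble(frame = 0L, strand = "+", frame_offset = 0L,
                        score = 100, identity = 100,
                        query_aa_start = 10L, query_aa_end = 60L,
                        ref_start = 0L, ref_end = 50L, confident = TRUE)
  orf <- call_orf(strrep("A", 200), fa0)
  expect_equal(c(orf$start, orf$end), c(30L, 180L))
  fa1 <- dplyr::mutate(fa0, frame = 1L, frame_offset = 1L,
                       query_aa_start = 0L, query_aa_end = 20L)
  orf1 <- call_orf(strrep("A", 100), fa1)
  expect_equal(c(orf1$start, orf1$end), c(1L, 61L))
  expect_error(call_orf(strrep("A", 200), dplyr::mutate(fa0, confident = FALSE)),
               "not confident")
})

test_that("alignment scores match a quadratic-time local-alignment oracle", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  set.seed(42)
  for (i in 1:12) {
    p1 <- random_protein(sample(10:50, 1))
    p2 <- random_protein(sample(10:50, 1))
    got <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(p1), Biostrings::AAString(p2), type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1))
    expect_equal(got, oracle_sw_score(p1, p2, BLOSUM62))
  }
})

test_that("reverse-complementing the query permutes frames, not the score", {
  prot <- random_protein(40)
  cds <- synthesize_cds(prot, 45, seed = 12)
  est <- synthesize_est(cds, 20, 20, seed = 13)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(est$sequence)))
  fa <- best_frame_alignment(est$sequence, prot)
  fa_rc <- best_frame_alignment(rc, prot)
  expect_equal(fa_rc$score, fa$score)
  expect_equal(fa_rc$strand, setdiff(c("+", "-"), fa$strand))
})

test_that("the called span's translation reproduces the aligned residues", {
  prot <- random_protein(60)
  cds <- synthesize_cds(prot, 55, seed = 21)
  est <- synthesize_est(cds, 33, 12, seed = 22)
  fa <- best_frame_alignment(est$sequence, prot)
  orf <- call_orf(est$sequence, fa)
  span <- substr(est$sequence, orf$start + 1, orf$end)
  expect_equal(translate_dna(span), prot)
})

test_that("random sequences score below the calibrated default threshold", {
  set.seed(99)
  n_null <- 40
  scores <- replicate(n_null, {
    nt <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    best_frame_alignment(nt, random_protein(200), min_score = 0)$score
  })
  expect_gte(mean(scores < 42), 0.95)
})

test_that("similarity filtering keeps confident calls, in order", {
  calls <- tibble::tibble(gene_id = c("g1", "g2"), score = c(40, 400),
                          identity = c(90, 95))
  expect_equal(filter_orf_calls(calls, min_score = 100)$gene_id, "g2")
  expect_equal(nrow(filter_orf_calls(calls[0, ], min_score = 100)), 0L)
  hits <- tibble::tibble(query = c("g1", "g2"), evalue = c(1e-50, 1e-10))
  kept <- filter_orf_calls(calls, hits = hits, max_evalue = 2e-35)
  expect_equal(kept$gene_id, "g1")
})
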