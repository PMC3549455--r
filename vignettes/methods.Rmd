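---
title: "Methods: chromosome-class GC heterogeneity from coding sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromosome-class GC heterogeneity from coding sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyogc)
```

## The scientific problem

Sauropsid karyotypes (birds, snakes, lizards, turtles) typically divide into
a few large macrochromosomes and many tiny microchromosomes. In chicken,
microchromosomes are GC-richer than macrochromosomes, and the GC-content at
third codon positions (GC~3~) of a gene tracks the GC level of the isochore
it sits in. `karyogc` implements the analysis chain used to ask whether a
genome shows this chromosome-size-dependent GC heterogeneity when all one
has is cDNA/EST sequence plus a cytogenetic or assembly-based gene-location
table:

1. infer each EST's reading frame by six-frame translated local alignment
   against a reference protein, and compute GC~3~ (all third codon
   positions) and GC~4~ (third positions of fourfold-degenerate codons
   only, where every base is synonymous);
2. classify genes by the size class of their chromosome (macro vs micro)
   under per-species karyotype rules;
3. compare the two classes (rank tests, a GC-rich/GC-poor contingency
   table) and assess bimodality of the pooled GC~3~ distribution by
   comparing a one-Gaussian and a two-Gaussian histogram fit;
4. couple GC~3~ to the GC of surrounding non-coding DNA, and compare
   ortholog GC~3~ across species, including the four-way grouping of
   ortholog pairs by (macro, micro) class in each species;
5. test functional-category over-representation between macro- and
   microchromosomal gene lists, with diagnostics for signals driven by a
   gene cluster on a single chromosome.

Every stage can be exercised without external data through seeded
generators that emulate the statistical structure of such a study.

## GC~3~ and GC~4~

`gc_profile()` reads complete codons from the declared frame. Codons
containing a non-ACGT base are excluded from both denominators, and stop
codons are excluded from the GC~3~ denominator: profiles are meant for
deduced protein-coding regions, where a stop either terminates the CDS or
flags a frame problem, and ambiguity codes carry no composition
information. GC~4~ uses *site-level* degeneracy: the third position of a
codon counts if all four third-base variants encode the same amino acid, so
the CTN, CGN and TCN members of the six-fold families are included (32
codons under the standard code). Degeneracy is derived from the code table
at run time, so alternative translation tables work unchanged.

Percentages are carried at full floating precision; the GC-rich/GC-poor
split places the boundary value in the rich class (GC~3~ ≥ 50 is rich).

## Reading-frame inference

`best_frame_alignment()` translates the query in all six frames and aligns
each translation to the reference protein with local affine-gap alignment
(BLOSUM62, gap open 11, extend 1 — the classic translated-search defaults).
The best frame's aligned span maps back to nucleotide coordinates as
`start = frame_offset + 3 × aa_start` (reverse-strand hits are reported in
forward coordinates with a strand flag). Coordinates are 0-based and
half-open throughout, matching BED.

E-values are *not* recomputed; the confidence gate is a raw-score
threshold. The default (42) is the 99th percentile of a seeded null
simulation: 1,000 pairs of a uniform-random 300-nt query against an
unrelated 200-residue protein, scoring the best of six frames. When an
external hit table with E-values is available, `filter_orf_calls()` applies
an E-value ceiling instead (e.g. the classic `2e-35` similarity gate).
There is no frameshift correction: an indel sequencing error truncates the
called span at the best local alignment, which biases spans short but never
shifts the frame of what is retained.

## Karyotype rules

Karyotype rules are data, not code. The shipped defaults encode a colubrid
snake (macro = chromosomes 1–7, Z, W; ten microchromosome pairs) and
chicken (macro = 1–8, Z, W; micro = 9–28, with 29–31/33–38 absent from the
assembly and 32 gene-less, recorded as excluded labels). Arm suffixes
("4p", "2q31") are stripped before lookup. Ortholog pairs fall into four
categories — macro/macro, micro/micro, macro/micro, micro/macro — with
pairs lacking a location on either side excluded.

## The statistics engine

All tests are implemented from first principles so their behaviour is fully
specified; base R equivalents are used as independent cross-checks in the
test suite only.

* **Mann–Whitney U**: exact by full enumeration of group labelings when the
  combined n is ≤ 16 (ties handled exactly as a permutation test); above
  that, the normal approximation with tie correction and a continuity
  correction.
* **Spearman**: average ranks, product-moment on ranks, t-approximate
  p-value with n − 2 df.
* **Fisher's exact test**: two-sided p as the sum of hypergeometric
  probabilities ≤ the observed table's probability (relative tolerance
  1e−7), plus the sample odds ratio.
* **Kruskal–Wallis + Dunn**: tie-corrected H with a chi-square reference;
  Dunn z on pooled ranks, Bonferroni-adjusted (the convention of the
  graphical-statistics packages that popularized "Dunn's post test").
* **Descriptives**: mean, sample SD (n − 1), SEM.

## The bimodality comparison

`fit_mixture_and_compare()` emulates curve-comparison on a frequency
distribution: values are binned (default width 5 over [0, 100]), and a
single Gaussian versus a sum of two Gaussians is fitted to (bin centre,
count) by Levenberg–Marquardt least squares. The fits are compared by the
extra sum-of-squares F test, `F = ((SS₁−SS₂)/(df₁−df₂))/(SS₂/df₂)` with
`df = n_bins − n_params`, and by AICc on the least-squares surface,
`n ln(SS/n) + 2K + 2K(K+1)/(n−K−1)` with `K = n_params + 1`; the
two-Gaussian Akaike weight is `1/(1 + exp(ΔAICc/2))`.

Two numerical choices matter and are deliberate:

* **Poisson weighting** (default `weighted = TRUE`, weights
  `1/max(count, 1)`). Histogram counts are heteroscedastic; unweighted
  fitting lets the high-count central bins dominate the residual surface,
  and in simulation the F test then rejects a true single Gaussian more
  than half the time. Weighting restores much of the calibration while
  keeping the binned-curve character of the procedure.
* **A component-SD floor of half the bin width.** A Gaussian narrower than
  a bin is unresolvable on binned data; without the floor the second
  component collapses onto a single bin and harvests its entire residual,
  which is pure overfitting.

The two-component fit is multi-started (split of the one-Gaussian solution
at ±1 SD and ±0.5 SD, plus a degenerate start at the one-Gaussian solution
itself), so SS₂ ≤ SS₁ and F ≥ 0 by construction.

**Known limitation.** For weakly separated mixtures this procedure sits
near its information limit. At the default study scale (183 values from a
0.79/0.21 mixture with means 15 points apart and SDs ≈ 9–10, Ashman
D ≈ 1.6), simulation shows the two-Gaussian model is favoured by Akaike
weight in only about half of replicates, and on true single-Gaussian data
the F test keeps its nominal level in only ~65–72% of replicates rather
than ≥ 95%: the residual miscalibration comes from structurally empty bins
(they deflate the denominator variance estimate) and from the nonlinearity
of the fit. No coherent setting of the unstated knobs (bin width,
weighting, restricting to occupied bins) fixes both properties at once —
narrowing the fit to occupied bins calibrates F but makes the AICc
small-sample penalty prohibitive. The histogram procedure is therefore best
read as a descriptive model comparison, not a calibrated test;
`fit_mixture_em()` provides the likelihood-based alternative (EM on the raw
values, likelihood-ratio statistic and AICc on the likelihood scale), which
is the better tool when a defensible test of bimodality is the goal.

## Non-coding GC and its coupling to GC~3~

`noncoding_profile()` masks the (merged, strand-ignored) coding spans of an
annotated contig and computes GC over the complement — everything outside
annotated protein-coding spans, i.e. introns and flanks, and UTRs where
they are not annotated as coding. A fully coding contig yields an undefined
(not zero) profile. `pair_gc3_noncoding()` joins per-gene GC~3~ with these
profiles and reports their Spearman correlation. Gene-structure prediction
is out of scope: coding spans arrive as BED-like annotation, from the
synthetic generator or any external annotator.

## Over-representation analysis

`over_representation()` performs the two-list Fisher test per annotation
term (terms taken as given, no ontology propagation; default minimum term
size 5), reporting raw p and Benjamini–Hochberg q. Two diagnostics follow
the classic interpretive steps: `chromosome_concentration()` computes the
fraction of a term's located genes on its single most-populated chromosome
(flag threshold 0.5 by default — the qualitative "driven by one gene
cluster" attribution made quantitative), and `category_gc_summary()`
compares a term's mean GC with the cohort mean.

## The synthetic cohort

`landscape_config()` holds the generator parameters; the defaults *are* the
study conditions the package emulates:

* snake GC~3~ landscape: macro N(41.5, 8.6²) with n = 144, micro
  N(56.4, 10.5²) with n = 39 (truncated to [0, 100] by clamping — at these
  parameters truncation is negligible);
* snake–chicken ortholog categories with counts 85/35/49/3 and per-group
  Gaussians (39.1/8.0 vs 47.1/10.9; 57.4/9.8 vs 54.9/13.7; 43.9/8.7 vs
  55.7/12.8). The fourth group is too small for its moments to be reported
  anywhere, so it reuses the snake microchromosomal and the chicken
  group-1 parameters — a documented package choice;
* rank-correlation targets: 0.51 between ortholog GC~3~ of snake and
  chicken, 0.90 between sister snake species, 0.73 between GC~3~ and
  non-coding GC;
* non-coding GC: macro N(36.8, 3.5²) n = 139, micro N(42.5, 4.0²) n = 37.

Coupling uses a Gaussian copula with latent Pearson correlation
`2 sin(π ρ_s / 6)`, so the *rank* correlation hits the configured target —
rank-level recovery is what the closed-loop tests check.
`synthesize_cds()` back-translates a protein fixing the exact number of
G/C-ending codons at `round(target/100 × n)` (only Met and Trp lack
third-base freedom), so the achieved GC~3~ deviates from the target only by
rounding granularity; `synthesize_est()` adds UTR flanks, optional
substitution errors and strand; `synthesize_contig()` lays out exons,
introns and flanks with per-base composition at the configured GC;
`plant_enrichment()` builds two gene lists with one term enriched at a
configured relative risk. Identical seeds give byte-identical outputs, and
every generator emits its ground truth.

What the generators do *not* emulate: codon-usage bias beyond the
third-base GC target, autocorrelation of GC along chromosomes (isochore
structure within a contig), indel sequencing errors, incomplete or chimeric
ESTs, and correlated annotation terms. Passing closed-loop tests therefore
demonstrates that the pipeline recovers planted statistical structure, not
that real EST libraries are free of these complications.

## Problem sizes and reproducibility

The shipped tests and the acceptance script work at the study's own scale:
cohorts of 183 genes, 176-pair correlation recoveries, 200-replicate
simulation properties for the bimodality comparison and the reading-frame
closed loop, and 500-replicate power checks for the class comparison —
sizes chosen to match the emulated study while keeping a full run in
minutes on one CPU. All randomness flows through explicit seeds; rerunning
any generator or analysis with the same inputs and seed reproduces its
output exactly.
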