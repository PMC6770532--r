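---
title: "Methods: global sequence features, GA-RF selection, and the stacked ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: global sequence features, GA-RF selection, and the stacked ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

lncstack classifies transcripts as long non-coding RNA (lncRNA) or
protein-coding RNA from sequence alone. This vignette documents the model,
the numerical conventions, and the design choices in enough detail that every
number the package produces can be reproduced by hand or by an independent
implementation.

## The classification model

The pipeline has three stages:

1. **Feature extraction.** Each transcript is mapped to a fixed vector of
   260 global sequence features in six categories — codon-related (9),
   ORF-related (22), GC-related (7), CDS-related (3), transcript-related
   (213) and structure-related (6). `feature_schema()` fixes the names and
   order.
2. **Feature selection (GA-RF).** A genetic algorithm over binary feature
   masks, whose fitness is the stratified cross-validated AUC of a random
   forest restricted to the masked features, returns the ten best distinct
   masks ever evaluated.
3. **Stacked ensemble.** One random forest is trained per selected mask; the
   output layer is the arithmetic mean of the ten lncRNA probabilities.
   A transcript is called lncRNA when the averaged score is at least the
   threshold (default 0.5, ties toward lncRNA). lncRNA is the positive class
   throughout, so sensitivity is lncRNA recall.

## Sequence handling conventions

- Input sequences are uppercased and RNA is folded to DNA (`U` to `T`).
  Characters outside `{A,C,G,T}` become the sentinel `N`; sequences with
  more than 10% ambiguity are rejected outright. Windows containing `N` are
  skipped in k-mer and hexamer counting, and codons containing `N` are
  dropped in translation, so all downstream statistics stay well defined.
  This policy keeps real FASTA files usable without distorting frequencies.
- The default working range keeps transcripts strictly longer than 200 nt
  and strictly shorter than 3000 nt — both bounds excluded, matching the
  usual "longer than 200 nt" definition of lncRNA.
- Redundancy removal (e.g. CD-HIT clustering at 80% similarity) is a
  recommended *upstream* step for real data; it is deliberately not
  reimplemented here.

## ORF conventions

ORFs are scanned on the forward strand only (inputs are mRNA-sense
transcripts). Every `ATG` in every frame opens a candidate that runs to the
first in-frame stop codon; **the stop codon is included in the ORF length**,
so a transcript that is exactly one complete ORF has coverage 1.0. If no
in-frame stop follows, the candidate runs to the last complete codon and is
flagged incomplete. Ties are broken deterministically (first ORF: smallest
start, prefer stop-terminated, then longer; longest ORF: maximal length,
then smallest start, then stop-terminated). ORF integrity is coded +1/−1
rather than 1/0; any two distinct codes would serve a random forest equally,
but the convention is fixed so golden test values are unambiguous.

Every "frame score" in the schema is the **population variance** (divide by
3, not 2) of a per-frame statistic over the three forward frames: the three
frames are the entire population, not a sample.

## Feature-block details

- **Fickett TESTCODE score** uses the published 1982 lookup tables in the
  arrangement popularized by CPAT: four position parameters
  `max(c1,c2,c3)/(min(c1,c2,c3)+1)` and four composition fractions, each
  mapped through a piecewise threshold table and combined as a weighted sum.
  The whole transcript is read as frame-0 codons (complete codons only).
- **k-mers** (k = 1, 2, 3; lexicographic order A<C<G<T) are computed twice:
  over the transcript and over the longest-ORF subsequence (zeros when no
  ORF). Each k-group is normalized by the number of valid windows.
- **CTD** is represented by its distribution component only: for each base,
  the relative positions at which 0%, 25%, 50%, 75% and 100% of its
  occurrences have been seen (quantile index `ceil(m·f)`, the 0% descriptor
  being the first occurrence). The composition and transition components
  duplicate the k = 1 and k = 2 k-mer blocks, and the schema's fixed
  20-dimension budget for CTD forces the distribution-only reading.
- **Entropy density profiles (EDP)** map counts to
  `s_i = -p_i log p_i / H` with `H` the Shannon entropy (natural log; any
  base cancels). The profile sums to 1; a one-hot count vector (zero
  entropy) is returned as-is. The transcript-level EDP (20 dims) is over the
  amino-acid counts of the frame-0 translation with stop codons skipped; the
  ORF-level EDP (16 dims) is over the dinucleotide counts of the longest
  ORF.
- **Hexamer score** is the mean log-ratio of coding to noncoding background
  frequency over in-frame hexamers (step 3 from position 0), CPAT-style.
  Background tables are trained with a pseudocount (default 1) in every one
  of the 4096 cells, since unseen hexamers otherwise produce infinite
  log-ratios; coding training sequences are counted over their longest ORF
  (falling back to the raw sequence for ORF-less training records). An ORF
  shorter than one hexamer scores 0. Note that with a fixed pseudocount,
  duplicating a training set is only exactly frequency-neutral when the
  pseudocount is scaled with it.
- **SNR** sums the squared-modulus DFT of the four base-indicator channels
  and divides the power at the one-third-frequency bin `k* = round(N/3)` by
  the mean power over all non-DC bins. The 0/0 case (e.g. homopolymers) is
  defined as 0, and sequences shorter than 6 nt return 0.
- **Peptide features** are computed on the translation of the longest ORF:
  average-mass molecular weight (ExPASy masses + one water), theoretical pI
  (Henderson–Hasselbalch with the Bjellqvist pKa set, bisection on pH 0–14
  to 1e-3), Kyte–Doolittle GRAVY, and the Guruprasad instability index
  (DIWV dipeptide weights). `log10(pI/Mw)` guards the empty-peptide case
  with 0. The pI/Mw frame score is the population variance of
  `log10(pI/Mw)` over the per-frame longest ORFs, a missing frame
  contributing 0.
- **CDS features** substitute a transparent deterministic surrogate for an
  external CDS predictor: the CDS is the longest ORF and its score is
  `length · (1 + max(0, hexamer_score)) + 50·[stop] + 50·[ATG]` — monotone
  in the same signals (length, completeness, coding-like composition) while
  keeping the three-dimension contract. Externally computed calls (e.g.
  txCdsPredict output) can be read in and override the surrogate.

## GA-RF feature selection

Chromosomes are 260-bit masks, initialized i.i.d. Bernoulli(0.5). The
full-scale configuration mirrors the method's standard settings: population
500, up to 50 generations, tournament size 3, single-point crossover with
probability 0.5, per-individual mutation probability 0.2 with per-gene flip
probability 0.05, fitness = 10-fold stratified CV AUC of a 100-tree random
forest on the masked columns. Additional conventions fixed here:

- "Until the maximum fitness tends to be stable" is quantified as: stop when
  the best-ever fitness has not improved by more than 1e-4 for 5 consecutive
  generations.
- The returned "top 10" is a hall of fame over **all** chromosomes ever
  evaluated (unique by gene content), not just the final population.
- One stratified fold assignment, drawn from the run seed, is shared by all
  fitness evaluations, so chromosomes are compared on identical splits
  (common random numbers); fitness values are cached by chromosome. Both are
  performance conventions only — any cached value equals an independent
  `ga_fitness()` call with the same configuration.
- The all-zero chromosome is assigned fitness 0 by definition.
- `ga_desk_profile()` (population 60, 25 generations, 5 folds, 50 trees) is
  the scaled-down configuration used by the package's own tests and
  acceptance script; the full-scale profile is the default for real use.

## Evaluation

Accuracy, sensitivity, specificity, precision and F1 follow their standard
confusion-matrix forms; zero-denominator metrics are reported as `NA`
(undefined), never coerced to 0. AUC is the rank-based (Mann–Whitney)
statistic with midranks for ties, which the test suite checks against
brute-force pair counting and against pROC. Cross-validation uses seeded
stratified folds ("random split" in the source method; stratification
stabilizes fold AUCs and is declared here).

## The synthetic-data generator

Real training corpora (GENCODE-scale, tens of thousands of transcripts) are
out of scope; the generator provides labelled data with exactly the
statistical structure the classifier exploits:

- **Coding-like**: background 5' UTR + `ATG` + codons drawn from a
  Dirichlet-sharpened distribution over the 61 non-stop codons + stop +
  background 3' UTR. The ORF covers at least 60% of the transcript, and
  rejection sampling guarantees it is exactly the longest ORF (hence
  integrity +1 by construction). `codon_bias_strength` (default 0.75)
  interpolates the Dirichlet concentration; the per-dataset codon weights
  are drawn once from the seed so different datasets differ.
- **Noncoding-like**: an order-2 Markov chain whose transition rows are
  Dirichlet draws centred on the base distribution implied by `gc_target`
  (default 0.5, concentration 60, keeping realized GC within a few percent).
- **Null model**: at `codon_bias_strength = 0` the coding construction is
  disabled and "coding" sequences are drawn from the *same* background
  parameters as the noncoding set. This is deliberate: an enforced
  stop-free ORF scaffold alone separates the classes regardless of codon
  bias, so a meaningful null calibration (AUC ≈ 0.5) requires switching the
  scaffold off too.
- Lengths are uniform on [200, 3000] nt by default; every dataset is a
  deterministic function of its configuration and seed.

One protocol point matters for any use of the hexamer feature: the
background tables must be trained on sequences *disjoint* from those being
classified. A table trained on the classified sequences themselves lets the
hexamer score memorize finite-sample differences between its own training
classes — enough to push a null comparison of identically distributed
classes far above AUC 0.5. `synthetic_benchmark()` therefore generates a
same-parameter reference split for table training and keeps the final
cross-validation fold seed distinct from the GA's internal fitness folds.

What passing tests on these data do and do not show: the generator produces
the *signals* the method is built on (ORF structure, codon bias, GC
composition, periodicity) but none of the nuisance structure of real
transcriptomes — splice isoforms, sequence redundancy, biotype imbalance,
pseudogenes, or UTR-specific composition. Synthetic performance therefore
validates the machinery end to end, not the headline numbers attainable on
curated genome annotations.

## Problem sizes and numerical choices

The package's own test suite and acceptance script run at desk scale, chosen
as the smallest sizes at which every qualitative property is stable: GA
recovery uses 300 samples over 20 features (5 informative, effect size 1.2
on unit-variance noise); the end-to-end benchmark uses 500+500 transcripts
with the desk GA profile and a 10-member stack evaluated by 10-fold CV.
Random forests are `ranger` forests with library-default depth and
`mtry`, single-threaded, seeded per member/fold; every pipeline stage is
bit-reproducible given its seed, and model archives embed masks, seeds, the
schema hash and (optionally) the hexamer table so loaded models predict
identically.

Known limitations: only ATG-initiated forward-strand ORFs are considered;
no RNA secondary structure or conservation features; the CDS score is a
surrogate, not a reimplementation of an external CDS predictor; and the pI,
Mw and instability constants follow the ExPASy/Bjellqvist/Guruprasad
conventions — other constant sets would shift those six features slightly.
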