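---
title: "Mixture-model binning of metagenomic reads: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture-model binning of metagenomic reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A homology search of n metagenomic reads against a reference collection
yields hits in K candidate genomes (every genome with at least one hit is a
candidate). For read i and genome j we keep the best within-genome hit —
the one with the most identical bases — and record the pair
(x_ij, L_ij): identical matches and alignment length. The read's maximum
alignment length is m_i = max_j L_ij.

Two mechanisms generate the data. First, reads are drawn from genomes in
proportion to the mixture weights pi_1, ..., pi_K (pi_j ≥ 0, Σ pi_j = 1):
pi_j is the fraction of all reads generated by genome j, and pi_j = 0 means
genome j is not in the sample. Second, even a read truly from genome j
rarely matches it perfectly — sequencing errors, alignment errors and SNPs
are pooled into a single per-base mismatch probability p. A read aligned
with x identical and m − x mismatched bases therefore has component
probability pi_j (1−p)^x p^(m−x), and the likelihood of the whole table is

    L(pi, p) = prod_i sum_j pi_j (1−p)^(x_ij) p^(m_i − x_ij).

Modelling assumptions worth keeping in mind: reads are independent; a
single global p is shared by all genomes and positions; the exponent uses
the *read's* maximum alignment length m_i for every candidate, so a genome
that aligns only part of the read is penalised for the unaligned remainder
as if it were mismatched. That last convention is what makes the sparse
treatment coherent: an absent entry is x = 0 with weight pi_j p^(m_i),
astronomically small for real read lengths (0.02^35 ≈ 3.4e-60), so absent
entries are *truncated to exactly zero* in every sum. This is an
approximation to the full likelihood, not an exact identity; its error is
of order p^m relative to the retained terms.

## EM, in closed form

The complete-data likelihood (augmenting each read with its source genome)
is an exponential family, so EM has closed-form steps:

* E-step: z_ij = pi_j (1−p)^(x_ij) p^(m_i−x_ij) / Σ_k (same for k) over the
  read's stored entries.
* M-step: pi_j = Σ_i z_ij / n, and
  p = Σ_ij z_ij (m_i − x_ij) / Σ_ij z_ij m_i — a responsibility-weighted
  mismatch fraction, the unique maximiser of the expected complete-data
  log-likelihood in p. The suite verifies the fitted optimum against an
  exhaustive grid search over the (pi, p) space on small instances, and the
  sparse engine against an independent dense-matrix EM to 1e-10.

Iteration stops when every parameter moves less than epsilon between
iterations (`epsilon = 1e-6` by default, with `max_iter = 1000`); the
log-likelihood trace is stored and is non-decreasing, a property the tests
assert on random instances. Hitting the cap returns an unconverged fit with
a warning rather than an error, so long-running analyses can inspect and
resume rather than lose work.

## Tunable parameters

| parameter | default | meaning / why this default |
|---|---|---|
| `p0` | 0.05 | EM start for p. Any start in (0, 0.5) reached the same optimum on every instance we tested; 0.05 is a plausible raw error rate for short reads. |
| `pi0` | uniform 1/K | the natural uninformative start; EM's multiplicative updates keep every pi_j > 0 thereafter. |
| `epsilon` | 1e-6 | absolute per-parameter convergence tolerance; proportions are accurate to far below biological interest at this level. |
| `max_iter` | 1000 | generous for these closed-form updates; benchmark fits converge in a handful of iterations. |
| `B`, `alpha` | 1000, 0.05 | bootstrap replicates and family error rate; B can be lowered for exploration. |

Two conventions are reporting-side only and never alter the optimisation:
a genome is *called absent* when its fitted pi_j < 1/(10n) (EM from a
positive start cannot reach exact zero in finite iterations, but mass below
a tenth of a read is noise); and posterior ties in assignment go to the
genome with the larger fitted proportion, then to the smaller genome index
— deterministic, and consistent with the model's logic of borrowing
strength from abundance.

## Numerical choices

All component weights are computed in log space with per-read maximum
subtraction before exponentiation: (1−p)^x p^(m−x) underflows double
precision directly for realistic read lengths. The conventions 0·log 0 = 0
handle the edges p = 0 (error-free data) and pi_j = 0 exactly. A read whose
every stored weight is zero at the current parameters (possible only at
degenerate p of exactly 0 or 1) aborts with the read named, rather than
propagating NaNs. Within-genome hit collapsing breaks ties on identical
matches by the longer alignment, then first occurrence — deterministic and
favouring the longer equally-identical alignment.

## Assignment, roll-up and evaluation

Each matrix read goes to its maximum-posterior genome (hard assignment; the
0/1 assignment matrix's column sums are the per-genome counts). Reads with
no hits never enter the matrix; they are carried as an unassigned count so
that evaluation percentages use the full sequencing denominator. A read
assigned to a strain is credited to that strain's species, genus, and every
higher rank; unranked nodes (NCBI-style strains) are traversed
transparently. In truth-based evaluation, TP and FP at a rank are
percentages of *all* reads (so TP + FP < 100 when some reads lack hits,
exactly as in benchmark reporting); a read whose true genome has no
ancestor at a rank is excluded from that rank's tally (real lineages skip
ranks routinely), and a read whose assigned genome lacks the rank counts as
unassigned there, neither correct nor incorrect.

## Abundance

Read counts confound copy number with genome length: a long genome sheds
more reads per copy. Under uniform read sampling the expected read share is
proportional to (copies × length), so relative copy number is
a_j = (pi_j/l_j) / Σ_k (pi_k/l_k). Genomes missing from the length table
are dropped with a warning and the remainder renormalised — abundance is
only defined for genomes whose length is known.

## Bootstrap

Read-level resampling (rows of the scoring matrix, with replacement)
propagates all estimation uncertainty through the full EM refit. We use
percentile intervals — the simplest method consistent with resampling-based
confidence statements — at per-parameter level 1 − alpha/K, a Bonferroni
correction giving at least 1 − alpha simultaneous coverage of all K
proportions; p gets an uncorrected interval since the family claim concerns
the pi's. Genomes absent from a resample contribute pi = 0 to that
replicate, and replicates that hit the iteration cap are retained (dropping
them would bias the intervals) and counted. A 100-community Monte-Carlo
study in the acceptance suite (300 reads, K = 3, B = 200) observes 90%
simultaneous coverage at the nominal 95% family level — percentile
intervals are known to run slightly below nominal at modest n.

## What the generator emulates — and what it does not

`simulate_hits()` draws each read's source from pi_true, its alignment
length from a rounded Gaussian (mean 100 bp by default, floored at 35 bp),
and its identical-match count as Binomial(L, 1−p_true): exactly the
structure the mixture assumes. Homology is a synthetic stand-in: each
non-source genome cross-hits with a configurable probability
(Binomial(K−1, h) genomes per read, drawn uniformly), losing
Poisson(penalty) identical matches relative to the source hit. Defaults
h = 0.05, penalty = 5 give each read a secondary hit in roughly one in
twenty non-source genomes at visibly lower identity — enough ambiguity to
exercise the posterior machinery without overwhelming it. A read is a
no-hit read (in the truth table, absent from the hit file) with probability
~0.02–0.03, matching the benchmark fractions of reads without database
hits.

The presets encode the standard benchmark communities: 2 genomes
(25,926/124,074 read split, p = 0.027, and the published 4,641,652 /
2,478,101 bp chromosome lengths of the two organisms the design mirrors),
9 genomes (log-spaced proportions standing in for "diverse abundance",
whose exact benchmark values are not published in the accessible text),
11 and 100 genomes (equal proportions); all with 150,000 reads of mean
length 100 bp.

Because cross-hits are generated by this stylised model rather than by
aligning real sequences, passing recovery tests shows the estimator is
correct *under the model's assumptions* — it does not certify performance
against real inter-genome homology structure, conserved regions, horizontal
transfer, or database incompleteness. Synthetic lineages (species pairs
into genera, doubling upward to one kingdom) are likewise placeholders;
real NCBI taxonomy enters through the `nodes.dmp`/`names.dmp` adapter.

## Problem sizes in the shipped tests

Unit tests run on instances of tens of reads where hand or oracle
verification is exact. The acceptance suite fits the two-genome and
11-genome presets at full 150,000-read scale (a fit takes on the order of a
second), runs the 100 × B = 200 bootstrap coverage study at 300 reads per
community, and checks EM against the grid-search oracle at n ≤ 50, K ≤ 3 —
sizes chosen so the exhaustive oracle itself is trustworthy.

## Known limitations

* One global p: genomes with atypical divergence from their reference are
  mis-weighted relative to the rest.
* No indel/quality model: only match counts enter; alignment gaps are
  implicitly mismatches.
* K is fixed by the candidate set from the homology search; the model
  cannot discover genomes without hits (novel organisms need assembly-based
  approaches).
* Hard assignment discards posterior mass; counts near detection threshold
  should be read together with the bootstrap intervals.
* The zero-entry truncation, while numerically negligible, makes the
  fitted criterion an approximation to the full mixture likelihood.
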