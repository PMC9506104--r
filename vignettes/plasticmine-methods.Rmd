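---
title: "Mining collections for plastic-degrading enzyme homologs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining collections for plastic-degrading enzyme homologs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`plasticmine` implements a homology-mining survey: a curated catalog of
plastic-degrading gene products is searched against a species-labelled
collection of proteomes (or six-frame-translated genomes), and the
resulting HIT table is summarized into counts, genome-normalized
densities, percentage shares and summed-score degradation-potential
indicators, with distance-tree clusterization of the mined sequences
around their references. This vignette documents the statistical model,
the tunable parameters and the design decisions, including what the
synthetic benchmark does and does not establish about real data.

```{r setup}
library(plasticmine)
```

# The search model

## Local alignment

Every query–subject pair is scored with affine-gap Smith–Waterman
(Gotoh's algorithm), compiled in C++. A gap of length $k$ costs
$o + k\,e$ with opening cost $o = 11$ and extension cost $e = 1$ under
BLOSUM62 — the standard protein-search defaults. Only the optimal local
alignment per pair is reported; sub-optimal HSPs are not, because all
downstream statistics count *sequences*, not alignments. Percent identity
is the fraction of identical aligned columns over all alignment columns
(gaps included in the denominator).

The aligner is verified against an independently coded full-matrix
dynamic-programming oracle, written in plain R with quadratic-space
matrices, on hundreds of random sequence pairs; agreement is required to
be exact, not approximate.

## Karlin–Altschul statistics

Raw scores are normalized to bit scores
$S' = (\lambda S - \ln K)/\ln 2$ and converted to E-values
$E = m\,n\,2^{-S'}$, the expected number of chance alignments at or above
$S'$ in a search of query length $m$ against a database of $n$ residues.
Defaults $\lambda = 0.267$, $K = 0.041$, $H = 0.14$ are the standard
gapped estimates for BLOSUM62 with 11/1 penalties. A match is kept when
$E \le 0.05$ — the threshold is inclusive: a match is dropped only when
its significance exceeds 5%.

Inside `search_collection()` the lengths entering $E$ are BLAST-style
*effective* lengths: the expected span of a high-scoring alignment,
$\ell = \ln(K m n)/H$, is subtracted from the query and once per database
sequence (floored at $1/K$). Without this finite-size correction the
nominal E-values systematically overstate the chance-hit rate for
desk-scale sequences (decoys of 80–200 residues), and the decoy
calibration drifts outside the tolerance that Karlin–Altschul theory
justifies. The raw `e_value()` helper keeps the uncorrected formula, so
its documented linearity in database size holds exactly.

The calibration claim is tested by Monte-Carlo: decoy-only collections
are searched and the total number of reported hits is compared with the
theoretical expectation (queries × 0.05 per search); agreement within a
factor of 3 is required, the usual allowance for the Karlin–Altschul
approximation at finite lengths. The measured ratio is written by
`scripts/acceptance.R` at run time.

## Genome input

Nucleotide input is reduced to protein space by `extract_orfs()`: all six
frames are scanned, stop-free codon runs of at least `min_len` codons
(default 30) are translated with the standard code, and segments whose
nucleotides contain `N` are skipped. This approximates a
translated-genome search while keeping the engine single-alphabet.

# HIT statistics

**Unique reduction.** "Unique HIT" is defined at the subject-sequence
level: one row per distinct subject, keeping the best-scoring alignment
(ties: lower E-value, then first occurrence). The polymer, category and
enzyme-class annotations of all merged rows are *unioned*, so a subject
matched by a PE query and a PET query counts once overall but contributes
to both categories. This union-attribution rule is what makes per-category
counts and genus-level totals mutually consistent.

**Counts and normalization.** Counts are taken over any subset of
{category, plastic, species, enzyme class}; species present in the
collection manifest but without hits are emitted with zero counts.
Per-species counts are additionally divided by the species' genome count
— the divisor is the number of genomes searched, the only quantity that
varies across unevenly sampled species — giving per-genome densities.

**Shares.** Percentage shares are computed on the grand total and rounded
half-away-from-zero to integer percent (so 57.12/24.43/18.45 prints as
57/24/18, summing to 99; a ±1 rounding slack on the sum is inherent to
integer shares and asserted in the tests).

**Scores.** The degradation-potential score of a species for a group is
the sum of **raw** alignment scores (not bit scores) over its unique HITs
attributed to that group, hits in several groups contributing to each.
Raw-score sums keep the indicator on the familiar blast-score scale;
because every search in a run uses one scoring scheme, the choice of raw
vs bit scores only rescales the ranking, which is what the indicator is
used for. Ranking ties break lexicographically so output is deterministic.

# Clusterization

Distances between aligned sequences are p-distances over mutually gap-free
columns with the Kimura protein correction
$d = -\ln(1 - p - p^2/5)$, capped at 10 where the correction diverges
($p \gtrsim 0.85$); a pair with no comparable columns is an error in
user-facing calls and takes the cap inside bootstrap replicates, where
column resampling can legitimately produce such pairs. Unaligned input is
first aligned pairwise and the local identity converted to $p$.

Trees are built by canonical neighbor joining (`ape::nj`), with negative
branch-length estimates clamped to zero. NJ is exact on additive matrices,
and the suite verifies topology recovery on random additive matrices
generated from known trees. Maximum-likelihood inference (JTT + gamma) was
deliberately not reimplemented: the trees serve visual clade grouping and
nearest-reference extraction, for which distance-based clusterization is
sufficient and orders of magnitude lighter; this is a documented deviation
from ML-based practice. For the same reason a single default matrix
(BLOSUM62) is used throughout rather than Gonnet for the MSA stage; both
are configurable through `scoring_scheme()`.

The progressive MSA builds an NJ guide tree from pairwise distances,
midpoint-roots it, and merges profiles leaf-to-root by global
profile–profile alignment (column score = frequency-weighted substitution
score; affine gaps). Gap-removal always recovers the input sequences
exactly — an invariant the tests assert.

Bootstrap support resamples alignment columns with replacement
(default `n_reps = 50`), rebuilds the NJ tree per replicate, and reports
the percentage of replicates containing each internal bipartition of the
original tree; results are deterministic given the seed, and the caller's
RNG state is restored.

`subtree_near_reference()` implements an explicit convention: the subtree
spans the references plus each reference's $k$ nearest leaves by
path length (ties at the cutoff break by label order). A fixed-$k$ rule
was chosen over a similarity threshold because it is scale-free and
parameter-transparent; no published threshold exists for "highest
similarity" subtree membership.

# The synthetic benchmark

`generate_collection()` emulates the statistical structure the analysis
assumes: species differ only in how many homolog copies they carry and at
what identity, against an i.i.d. decoy background with Robinson–Robinson
residue frequencies. Defaults: 20 decoys per genome of 80–200 residues —
proteome-like length scale at a size where full Smith–Waterman over all
pairs stays interactive on one CPU.

Mutants substitute exactly `round((1 - identity) * L)` positions, drawn
without replacement, replacements drawn from BLOSUM62-positive exchange
partners. Substitution-only mutation (no indels) keeps realized identity
analytically exact, which the recovery tests rely on; an indel-aware mode
would weaken that control and is intentionally absent from this version.
Generation is fully deterministic for a fixed seed (per-sequence seeds are
derived from the master seed), to the point of byte-identical FASTA
output.

What passing the synthetic tests shows: the search recovers planted
homologs at ≥ 60% identity, false-positive rates follow the E-value
calibration, and the score ranking recovers planted abundance ratios
(4:2:1 across three species, ≥ 9 of 10 seeds). What it does not show:
robustness to domain shuffling, compositional bias, paralog interference
or real phylogenetic correlation between species — none of which the
generator models, by design.

# Problem sizes and runtime choices

The shipped tests and the acceptance script run at desk scale, chosen so
the full pipeline stays in the tens of seconds on a single CPU: catalogs
of 4–10 references (120–220 residues), collections of 2–3 species × 1–2
genomes with up to ~40 planted homologs plus 5–20 decoys per genome,
aligner-oracle comparisons on 200 pairs of ≤ 40 residues, NJ recovery on
50 matrices of 6–10 taxa, and 20-replicate decoy calibrations. These
sizes exercise every code path; the engines themselves are quadratic DP
and scale to realistic single-proteome searches, though the package makes
no claim to BLAST-scale throughput (heuristic seeding is an explicit
non-goal).

# Known limitations

* The search is exhaustive Smith–Waterman: suitable for catalog-scale
  query sets against desk-scale collections, not for thousand-genome
  screens.
* E-value calibration is asymptotic theory plus a finite-size correction;
  a factor-of-3 agreement band, not exactness, is the supported claim.
* NJ + bootstrap replaces ML inference; branch supports are
  distance-based and should be read as clustering stability, not
  phylogenetic posterior support.
* The category map covers the 15 recognised polymer codes; new polymers
  require extending `polymer_categories()`.
* Genome mode translates ORFs of ≥ `min_len` codons; very short exons or
  frameshifted genes are invisible to it.
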