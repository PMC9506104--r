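# plasticmine

`plasticmine` screens bacterial genome or proteome collections for homologs
of known plastic-degrading enzymes. It is aimed at comparative-genomics
studies that ask, for a genus or strain collection, *which species carry the
richest repertoire of candidate plastic-degrading genes, for which polymer
classes, and how do the mined sequences relate to the characterized
references?* — the kind of survey that has been applied to *Rhodococcus*
and other catabolically versatile actinobacteria.

The pipeline is self-contained: every stage, from the local-alignment
search to the tree clusterization, is implemented in the package, and a
deterministic synthetic-collection generator stands in for the real genome
downloads so the whole workflow can be exercised and tested offline.

## The method

**Catalog.** A curated set of reference gene products, each annotated with
the polymer(s) it degrades. Polymers map deterministically onto three
backbone categories: C−C backbone (PE), heteroatomic backbone (PET, PU) and
polyesters (PHB, PBAT, PLA, PCL, PBS, PBSA, PES, PPL, PHV, PHBV, PHPV,
Ecoflex). Duplicate sequences are collapsed (first kept, polymer
annotations unioned) before searching.

**Search.** Each reference is aligned against every subject protein with
affine-gap Smith–Waterman (BLOSUM62, gap open 11, extend 1). Raw scores
*S* are converted to bit scores *S′ = (λS − ln K)/ln 2* and E-values
*E = m·n·2^(−S′)* with the gapped Karlin–Altschul parameters
λ = 0.267, K = 0.041 and BLAST-style effective-length correction of the
search space. A match is reported as a HIT when *E* ≤ 0.05. Nucleotide
genomes are handled by six-frame ORF translation (`extract_orfs()`)
followed by the same protein search.

**HIT statistics.** HITs are reduced to unique subject sequences (best
score kept; annotations unioned), counted by category / polymer / species /
enzyme class, normalized by each species' genome count, and expressed as
integer-percent category shares. The degradation-potential score of a
species for a polymer group is the **sum of raw alignment scores** of its
unique HITs attributed to that group; species are ranked by this score.

**Clusterization.** Unique HITs of an enzyme class, together with their
references, are aligned by progressive MSA (NJ guide tree,
profile–profile alignment), placed in a neighbor-joining tree from
Kimura-corrected distances, bootstrap-supported (50 column resamples by
default), and the subtree of the *k* leaves nearest each reference is
extracted by path length.

## Worked example

A small synthetic demo ships with the package: an 8-entry catalog
(sequences are synthetic, as the filenames state) and a three-species
collection spec with multicopper-oxidase homologs planted at 4:2:1
abundance.

```r
library(plasticmine)

ct   <- read_catalog(
  system.file("extdata", "demo_catalog_synthetic.fasta", package = "plasticmine"),
  system.file("extdata", "demo_catalog_synthetic.tsv",   package = "plasticmine"))
spec <- read_synthetic_spec(
  system.file("extdata", "demo_spec.yaml", package = "plasticmine"))

coll <- run_simulate(spec, ct, "demo_sim")
res  <- run_mine(ct, coll, "demo_mine")
glance(res)
#> # A tibble: 1 x 6
#>   n_queries n_species n_subjects n_hits n_unique_hits e_threshold
#> 1         8         3         75     15            15        0.05

res$shares
#>   group            n share_pct
#> 1 CC_BACKBONE     13        87
#> 2 HETEROATOMIC     2        13
#> 3 POLYESTER        0         0

score_matrix_wide(res$scores_category)
#>   species      CC_BACKBONE HETEROATOMIC POLYESTER
#> 1 Species_high        5494         1231         0
#> 2 Species_mid         2755            0         0
#> 3 Species_low          695            0         0

rank_species(res$scores_category, "CC_BACKBONE")
#> [1] "Species_high" "Species_mid"  "Species_low"
```

All 15 planted homologs are recovered with no decoy false positives; the
summed-score ranking recovers the planted 4:2:1 abundance order. The
clusterization stage then groups the mined homologs around their
references:

```r
tre <- run_tree(res, coll, ct, "multicopper oxidase", "demo_tree",
                k = 3, n_boot = 50, seed = 1)
tre$subtree$tip.label
#> [1] "SYN_MCO_01" "SYN_MCO_02" "Species_high|g1|h001" ...
```

Each stage writes its artifacts (HIT table TSV, count tables with raw and
normalized columns, score matrices as TSV/JSON, rankings, Newick trees
with bootstrap labels, run-summary JSON) under the given output directory.
A thin command-line front end over the same functions is installed at
`system.file("cli", "plasticmine.R", package = "plasticmine")` with
`simulate`, `mine` and `tree` subcommands.

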