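# Independent reference implementations used as oracles. These are written
# as plain full-matrix / brute-force R code, deliberately separate from the
# package's compiled implementations.

# Full-matrix affine-gap Smith-Waterman score (Gotoh), quadratic space.
# Gap of length k costs open + k * ext, matching the package convention.
oracle_sw_score <- function(q, s, mat, open, ext) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  m <- length(qc); n <- length(sc)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0,
                     H[i - 1, j - 1] + mat[qc[i - 1], sc[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Brute-force six-frame ORF scan: for every frame of both strands, walk
# codons, translate, and collect stop-free runs of >= min_len codons that
# contain no N.
oracle_orfs <- function(genome, min_len) {
  code <- Biostrings::GENETIC_CODE
  rc <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  }
  prots <- character()
  for (s in c(toupper(genome), rc(toupper(genome)))) {
    for (f in 1:3) {
      aa <- character(); has_n <- logical()
      i <- f
      while (i + 2 <= nchar(s)) {
        cod <- substr(s, i, i + 2)
        aa <- c(aa, if (grepl("N", cod)) "?" else code[[cod]])
        i <- i + 3
      }
      run <- character()
      for (x in c(aa, "*")) {          # sentinel stop flushes the last run
        if (x == "*") {
          if (length(run) >= min_len && !any(run == "?"))
            prots <- c(prots, paste(run, collapse = ""))
          run <- character()
        } else run <- c(run, x)
      }
    }
  }
  sort(prots)
}

# Random protein of background composition.
random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- plasticmine::robinson_frequencies()
  paste(sample(names(f), n, replace = TRUE, prob = f), collapse = "")
}

# Random additive distance matrix from a random binary tree with strictly
# positive branch lengths; returns both the matrix and the generating tree.
random_additive_matrix <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, br = function(k) stats::runif(k, 0.2, 1.5))
  list(tree = ape::unroot(tr), d = ape::cophenetic.phylo(tr))
}

# Minimal annotated catalog used across tests.
tiny_catalog <- function(seed = 11) {
  set.seed(seed)
  make_catalog(
    accession = c("MCO1", "ALKB1", "CUT1", "PHBD1"),
    sequence = vapply(c(160, 180, 150, 170), random_protein, ""),
    organism = c("Pseudomonas sp.", "Rhodococcus ruber",
                 "Thermobifida fusca", "Ralstonia sp."),
    phylum = c("Proteobacteria", "Actinobacteria",
               "Actinobacteria", "Proteobacteria"),
    enzyme_class = c("multicopper oxidase", "alkane 1-monooxygenase",
                     "cutinase", "PHB-depolymerase"),
    polymers = list("PE", "PE", c("PET", "PU"), "PHB")
  )
}
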