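#' Robinson-Robinson background residue frequencies
#'
#' The standard amino-acid background composition used for random protein
#' models in local-alignment statistics.
#'
#' @return Named numeric vector over the 20 standard residues (sums to ~1).
#' @export
robinson_frequencies <- function() {
  c(A = 0.078047, R = 0.051269, N = 0.044873, D = 0.053640, C = 0.019246,
    Q = 0.042644, E = 0.062949, G = 0.073772, H = 0.021992, I = 0.051420,
    L = 0.090191, K = 0.057438, M = 0.022425, F = 0.038556, P = 0.052028,
    S = 0.071198, T = 0.058413, W = 0.013298, Y = 0.032165, V = 0.064409)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Mutate a protein to a controlled target identity
#'
#' Substitutes exactly `round((1 - target_identity) * L)` positions, chosen
#' uniformly without replacement; each replacement residue is drawn
#' uniformly from the BLOSUM62-positive exchange partners of the original
#' residue (falling back to a uniform draw over the other 19 residues when
#' none exists). No indels are introduced, so the realized global identity
#' is fixed by construction.
#'
#' @param ref Protein sequence string.
#' @param target_identity Target fraction of conserved positions, in
#'   (0.2, 1].
#' @param seed Integer RNG seed (global RNG state is restored afterwards).
#' @return The mutated protein string.
#' @export
mutate_sequence <- function(ref, target_identity, seed = 1L) {
  stopifnot(target_identity > 0.2, target_identity <= 1)
  chars <- strsplit(ref, "", fixed = TRUE)[[1]]
  L <- length(chars)
  n_sub <- round((1 - target_identity) * L)
  if (n_sub == 0) return(ref)
  b62 <- .builtin_matrix("BLOSUM62")
  aa <- aa_alphabet()
  partners <- lapply(setNames(aa, aa), function(a) {
    p <- aa[b62[a, aa] > 0 & aa != a]
    if (length(p) == 0) setdiff(aa, a) else p
  })
  .with_seed(seed, {
    pos <- sample.int(L, n_sub)
    for (i in pos) {
      cand <- partners[[chars[i]]]
      if (is.null(cand)) cand <- setdiff(aa, chars[i])  # e.g. X
      chars[i] <- cand[sample.int(length(cand), 1)]
    }
  })
  paste(chars, collapse = "")
}

#' Generate a random decoy protein
#'
#' I.i.d. residues drawn from the Robinson-Robinson background frequencies.
#'
#' @param length Decoy length (>= 30 residues).
#' @param seed Integer RNG seed (global RNG state is restored afterwards).
#' @return Protein sequence string.
#' @export
make_decoy <- function(length, seed = 1L) {
  stopifnot(length >= 30)
  f <- robinson_frequencies()
  .with_seed(seed,
    paste(sample(names(f), length, replace = TRUE, prob = f), collapse = ""))
}

#' Specification for a synthetic proteome collection
#'
#' Describes a multi-species collection in which each genome carries planted
#' homologs of catalog references at controlled sequence identity, against a
#' background of random decoys. Stands in for a real genome collection so
#' the whole pipeline is testable offline.
#'
#' @param species Tibble/data frame with columns `species` and `n_genomes`
#'   (>= 1).
#' @param planted Tibble/data frame with columns `species`, `accession`
#'   (catalog reference to plant), `copies_per_genome` (>= 0) and
#'   `target_identity` (in (0.2, 1]).
#' @param decoys_per_genome Number of decoy proteins per genome.
#' @param decoy_length_range Integer length range `c(min, max)` for decoys
#'   (min >= 30).
#' @param seed Integer master seed; fixes the collection byte-for-byte.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(species, planted,
                           decoys_per_genome = 20L,
                           decoy_length_range = c(80L, 200L),
                           seed = 1L) {
  species <- tibble::as_tibble(species)
  planted <- tibble::as_tibble(planted)
  stopifnot(all(c("species", "n_genomes") %in% names(species)),
            all(c("species", "accession", "copies_per_genome",
                  "target_identity") %in% names(planted)),
            all(species$n_genomes >= 1),
            all(planted$copies_per_genome >= 0),
            decoys_per_genome >= 0,
            length(decoy_length_range) == 2,
            decoy_length_range[1] >= 30,
            decoy_length_range[1] <= decoy_length_range[2])
  if (any(planted$target_identity <= 0.2 | planted$target_identity > 1))
    stop("target_identity must lie in (0.2, 1]")
  bad <- setdiff(planted$species, species$species)
  if (length(bad))
    stop("planted rows for unknown species: ", paste(bad, collapse = ", "))
  structure(list(species = species, planted = planted,
                 decoys_per_genome = as.integer(decoys_per_genome),
                 decoy_length_range = as.integer(decoy_length_range),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Read a synthetic-collection spec from a YAML config file
#'
#' Schema: top-level keys `seed`, `decoys_per_genome`, `decoy_length_range`
#' (2-element list) and `species` — a list of maps with `label`,
#' `n_genomes` and `planted`, itself a list of maps with `reference`,
#' `copies_per_genome`, `target_identity`.
#'
#' @param path Path to the YAML file.
#' @return A [synthetic_spec()] object.
#' @export
read_synthetic_spec <- function(path) {
  y <- yaml::read_yaml(path)
  sp <- tibble::tibble(
    species = vapply(y$species, `[[`, "", "label"),
    n_genomes = vapply(y$species, function(s)
      as.integer(s$n_genomes %||% 1L), 1L)
  )
  pl <- dplyr::bind_rows(lapply(y$species, function(s) {
    if (is.null(s$planted)) return(NULL)
    tibble::tibble(
      species = s$label,
      accession = vapply(s$planted, `[[`, "", "reference"),
      copies_per_genome = vapply(s$planted, function(p)
        as.integer(p$copies_per_genome %||% 1L), 1L),
      target_identity = vapply(s$planted, function(p)
        as.numeric(p$target_identity %||% 1), 1)
    )
  }))
  if (is.null(pl) || nrow(pl) == 0)
    pl <- tibble::tibble(species = character(), accession = character(),
                         copies_per_genome = integer(),
                         target_identity = double())
  synthetic_spec(sp, pl,
                 decoys_per_genome = y$decoys_per_genome %||% 20L,
                 decoy_length_range = unlist(y$decoy_length_range %||%
                                               c(80L, 200L)),
                 seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic proteome collection with ground truth
#'
#' Realizes a [synthetic_spec()] against a reference catalog: per species
#' and genome, the planted homologs are produced with [mutate_sequence()]
#' and the decoy background with [make_decoy()]. Fully deterministic for a
#' fixed spec seed (per-sequence seeds are derived from it), so repeated
#' calls give byte-identical collections.
#'
#' @param spec A [synthetic_spec()].
#' @param catalog Catalog tibble containing every planted accession.
#' @return List with `sequences` (tibble: `species`, `genome_index`,
#'   `subject_id`, `sequence`, `is_planted`, `source_reference`,
#'   `realized_identity`), `manifest` (`species`, `n_genomes`), `truth`
#'   (planted rows only) and the `spec`.
#' @export
generate_collection <- function(spec, catalog) {
  stopifnot(inherits(spec, "synthetic_spec"))
  miss <- setdiff(spec$planted$accession, catalog$accession)
  if (length(miss))
    stop("reference accession(s) absent from catalog: ",
         paste(miss, collapse = ", "))
  refseq <- setNames(catalog$sequence, catalog$accession)
  counter <- 0L
  next_seed <- function() {
    counter <<- counter + 1L
    (spec$seed %% 100000L) * 20011L + counter
  }
  rows <- list()
  for (si in seq_len(nrow(spec$species))) {
    sp <- spec$species$species[si]
    planted <- spec$planted[spec$planted$species == sp, ]
    for (g in seq_len(spec$species$n_genomes[si])) {
      p_idx <- 0L
      if (nrow(planted) > 0) {
        for (pi in seq_len(nrow(planted))) {
          acc <- planted$accession[pi]
          tgt <- planted$target_identity[pi]
          for (cp in seq_len(planted$copies_per_genome[pi])) {
            p_idx <- p_idx + 1L
            seq <- mutate_sequence(refseq[[acc]], tgt, seed = next_seed())
            L <- nchar(seq)
            real_id <- (L - round((1 - tgt) * L)) / L
            rows[[length(rows) + 1L]] <- tibble::tibble(
              species = sp, genome_index = g,
              subject_id = sprintf("%s|g%d|h%03d", sp, g, p_idx),
              sequence = seq, is_planted = TRUE,
              source_reference = acc, realized_identity = real_id
            )
          }
        }
      }
      if (spec$decoys_per_genome > 0) {
        for (di in seq_len(spec$decoys_per_genome)) {
          len_seed <- next_seed()
          len <- .with_seed(len_seed,
            sample(spec$decoy_length_range[1]:spec$decoy_length_range[2], 1))
          rows[[length(rows) + 1L]] <- tibble::tibble(
            species = sp, genome_index = g,
            subject_id = sprintf("%s|g%d|d%03d", sp, g, di),
            sequence = make_decoy(len, seed = next_seed()),
            is_planted = FALSE, source_reference = NA_character_,
            realized_identity = NA_real_
          )
        }
      }
    }
  }
  sequences <- dplyr::bind_rows(rows)
  list(
    sequences = sequences,
    manifest = tibble::tibble(species = spec$species$species,
                              n_genomes = spec$species$n_genomes),
    truth = sequences[sequences$is_planted,
                      c("species", "genome_index", "subject_id",
                        "source_reference", "realized_identity")],
    spec = spec
  )
}

#' Collapse a collection to the species -> proteome map used by search
#'
#' @param collection A collection from [generate_collection()] or
#'   [read_collection()].
#' @return Named list: species label -> named character vector of proteins.
#' @export
as_proteomes <- function(collection) {
  seqs <- collection$sequences
  split(setNames(seqs$sequence, seqs$subject_id), seqs$species)[
    collection$manifest$species]
}

#' Write a synthetic collection to disk
#'
#' One protein FASTA per genome (`<species>/genome_<i>.fasta`), plus
#' `manifest.tsv` (species, n_genomes) and `truth.tsv`. Output is
#' byte-deterministic for a fixed collection.
#'
#' @param collection A collection from [generate_collection()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_collection <- function(collection, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- collection$sequences
  for (sp in collection$manifest$species) {
    spdir <- file.path(dir, sp)
    dir.create(spdir, showWarnings = FALSE)
    sub <- seqs[seqs$species == sp, ]
    for (g in sort(unique(sub$genome_index))) {
      gsub_ <- sub[sub$genome_index == g, ]
      write_fasta(setNames(gsub_$sequence, gsub_$subject_id),
                  file.path(spdir, sprintf("genome_%03d.fasta", g)))
    }
  }
  write.table(as.data.frame(collection$manifest),
              file.path(dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(collection$truth),
              file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a collection directory written by [write_collection()]
#'
#' Also accepts hand-built directories: any `<species>/<genome>.fasta`
#' layout with a `manifest.tsv`.
#'
#' @param dir Collection directory.
#' @return List with `sequences`, `manifest` and (if present) `truth`.
#' @export
read_collection <- function(dir) {
  manifest <- tibble::as_tibble(
    read.table(file.path(dir, "manifest.tsv"), sep = "\t", header = TRUE,
               stringsAsFactors = FALSE))
  rows <- list()
  for (sp in manifest$species) {
    files <- sort(list.files(file.path(dir, sp), pattern = "\\.fasta$",
                             full.names = TRUE))
    for (g in seq_along(files)) {
      seqs <- read_fasta(files[g])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        species = sp, genome_index = g,
        subject_id = names(seqs), sequence = unname(seqs))
    }
  }
  out <- list(sequences = dplyr::bind_rows(rows), manifest = manifest)
  tf <- file.path(dir, "truth.tsv")
  if (file.exists(tf))
    out$truth <- tibble::as_tibble(
      read.table(tf, sep = "\t", header = TRUE, stringsAsFactors = FALSE))
  out
}
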