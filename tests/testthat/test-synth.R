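test_that("mutate_sequence hits the target identity exactly", {
  ref <- random_protein(100, seed = 31)
  expect_equal(mutate_sequence(ref, 1.0, seed = 1), ref)
  mut <- mutate_sequence(ref, 0.8, seed = 2)
  expect_equal(nchar(mut), 100)
  diffs <- sum(strsplit(ref, "")[[1]] != strsplit(mut, "")[[1]])
  expect_equal(diffs, 20)
  expect_error(mutate_sequence(ref, 0.1), "target_identity")
  expect_error(mutate_sequence(ref, 1.5), "target_identity")
})

test_that("mutants align to the reference near the target identity", {
  ref <- random_protein(150, seed = 32)
  for (seed in 1:20) {
    mut <- mutate_sequence(ref, 0.8, seed = seed)
    aln <- smith_waterman(ref, mut)
    expect_gte(aln$identity_pct, 75)
    expect_lte(aln$identity_pct, 85)
  }
})

test_that("decoys are deterministic with background composition", {
  expect_identical(make_decoy(80, seed = 5), make_decoy(80, seed = 5))
  expect_error(make_decoy(10), ">= 30")
  # composition over 1e5 residues within 1% per residue of the background
  big <- make_decoy(100000, seed = 6)
  freq <- table(strsplit(big, "")[[1]]) / 100000
  bg <- robinson_frequencies()
  expect_true(all(abs(freq[names(bg)] - bg) < 0.01))
})

test_that("generate_collection is reproducible and truth-complete", {
  ct <- tiny_catalog()
  spec <- synthetic_spec(
    species = tibble::tibble(species = c("A", "B"), n_genomes = c(2L, 1L)),
    planted = tibble::tibble(species = c("A", "B"),
                             accession = c("MCO1", "CUT1"),
                             copies_per_genome = c(2L, 1L),
                             target_identity = c(0.8, 0.9)),
    decoys_per_genome = 5L, seed = 77L)
  c1 <- generate_collection(spec, ct)
  c2 <- generate_collection(spec, ct)
  expect_identical(c1$sequences, c2$sequences)
  # manifest and truth shape
  expect_equal(c1$manifest$n_genomes, c(2L, 1L))
  expect_equal(nrow(c1$truth), 2 * 2 + 1)
  expect_true(all(abs(c1$truth$realized_identity -
                        c(rep(0.8, 4), 0.9)) <= 0.05))
  # every planted subject id exists exactly once in the sequence set
  expect_true(all(table(c1$truth$subject_id) == 1))
  expect_true(all(c1$truth$subject_id %in% c1$sequences$subject_id))
  # byte-identical FASTA output under a fixed seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_collection(c1, d1); write_collection(c2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_equal(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # collection round-trips through disk
  back <- read_collection(d1)
  expect_equal(back$sequences$sequence, c1$sequences$sequence)
  expect_equal(back$manifest, c1$manifest)
})

test_that("spec validation rejects bad parameters and unknown references", {
  ct <- tiny_catalog()
  sp <- tibble::tibble(species = "A", n_genomes = 1L)
  expect_error(synthetic_spec(sp, tibble::tibble(
    species = "A", accession = "MCO1", copies_per_genome = 1L,
    target_identity = 1.5)), "target_identity")
  ok <- synthetic_spec(sp, tibble::tibble(
    species = "A", accession = "NOPE", copies_per_genome = 1L,
    target_identity = 0.9))
  expect_error(generate_collection(ok, ct), "NOPE")
})

test_that("planted homologs at >= 0.6 identity are recovered by search", {
  ct <- tiny_catalog()
  spec <- synthetic_spec(
    species = tibble::tibble(species = c("A", "B"), n_genomes = 1L),
    planted = tibble::tibble(species = c("A", "A", "B"),
                             accession = c("MCO1", "CUT1", "ALKB1"),
                             copies_per_genome = c(3L, 2L, 3L),
                             target_identity = c(0.6, 0.7, 0.65)),
    decoys_per_genome = 10L, seed = 13L)
  coll <- generate_collection(spec, ct)
  hits <- search_collection(ct, as_proteomes(coll),
                            manifest = coll$manifest)
  recall <- mean(coll$truth$subject_id %in% hits$subject_id)
  expect_gte(recall, 0.95)
})

test_that("YAML spec files parse into equivalent specs", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 5",
    "decoys_per_genome: 7",
    "decoy_length_range: [60, 90]",
    "species:",
    "  - label: A",
    "    n_genomes: 2",
    "    planted:",
    "      - reference: MCO1",
    "        copies_per_genome: 2",
    "        target_identity: 0.85",
    "  - label: B",
    "    n_genomes: 1"
  ), path)
  spec <- read_synthetic_spec(path)
  expect_equal(spec$seed, 5L)
  expect_equal(spec$decoys_per_genome, 7L)
  expect_equal(spec$species$n_genomes, c(2L, 1L))
  expect_equal(spec$planted$accession, "MCO1")
  expect_equal(spec$planted$target_identity, 0.85)
})
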