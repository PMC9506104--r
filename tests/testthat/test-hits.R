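# Hand-built HIT rows for the statistical core (schema of search_collection)
hit_row <- function(gene_id, subject_id, species, score, evalue = 1e-6,
                    polymers = "PE", enzyme = "oxidase") {
  cats <- sort(unique(assign_category(polymers)))
  tibble::tibble(
    gene_id = gene_id,
    plastic_group = paste(cats, collapse = ","),
    plastic = paste(polymers, collapse = ","),
    plastic_enzyme = enzyme, species = species, subject_id = subject_id,
    score = as.integer(score), bit_score = score * 0.4,
    evalue = evalue, identity = 90,
    q_start = 0L, q_end = 10L, s_start = 0L, s_end = 10L,
    categories = list(cats), polymers = list(polymers)
  )
}

test_that("unique_hits keeps the best row per subject and unions labels", {
  tab <- dplyr::bind_rows(
    hit_row("Q1", "X", "A", 100, polymers = "PE"),
    hit_row("Q2", "X", "A", 250, polymers = "PE"),
    hit_row("Q3", "X", "A", 180, polymers = "PET", enzyme = "cutinase"),
    hit_row("Q4", "Y", "B", 50, polymers = "PHB", enzyme = "depolymerase")
  )
  u <- unique_hits(tab)
  expect_equal(nrow(u), 2)
  x <- u[u$subject_id == "X", ]
  expect_equal(x$score, 250L)
  expect_equal(x$gene_id, "Q2")
  expect_setequal(x$categories[[1]], c("CC_BACKBONE", "HETEROATOMIC"))
  expect_setequal(x$polymers[[1]], c("PE", "PET"))
  expect_setequal(x$enzyme_classes[[1]], c("oxidase", "cutinase"))
  # idempotence
  expect_equal(unique_hits(u)$score, u$score)
  expect_equal(unique_hits(u)$categories, u$categories)
  # ties on score break by lower E-value, then first occurrence
  tie <- dplyr::bind_rows(
    hit_row("Q1", "Z", "A", 100, evalue = 1e-3),
    hit_row("Q2", "Z", "A", 100, evalue = 1e-9),
    hit_row("Q3", "Z", "A", 100, evalue = 1e-9)
  )
  expect_equal(unique_hits(tie)$gene_id, "Q2")
})

test_that("unique_hits never increases the row count", {
  set.seed(9)
  for (i in 1:5) {
    n <- sample(5:25, 1)
    tab <- dplyr::bind_rows(lapply(seq_len(n), function(k)
      hit_row(paste0("Q", sample(3, 1)),
              paste0("S", sample(8, 1)), "A",
              sample(50:300, 1))))
    expect_lte(nrow(unique_hits(tab)), nrow(tab))
  }
})

test_that("grouped counts tally unions once per group value", {
  tab <- dplyr::bind_rows(
    hit_row("Q1", "X", "A", 100, polymers = "PE"),
    hit_row("Q2", "X", "A", 90, polymers = "PET"),
    hit_row("Q3", "Y", "A", 80, polymers = "PE"),
    hit_row("Q4", "Z", "B", 70, polymers = "PBAT")
  )
  u <- unique_hits(tab)
  by_cat <- count_hits(u, "category")
  expect_equal(by_cat$n[by_cat$category == "CC_BACKBONE"], 2L)   # X and Y
  expect_equal(by_cat$n[by_cat$category == "HETEROATOMIC"], 1L)  # X again
  expect_equal(by_cat$n[by_cat$category == "POLYESTER"], 1L)
  by_plastic <- count_hits(u, "plastic")
  expect_equal(by_plastic$n[by_plastic$plastic == "PE"], 2L)
  # marginalizing species x category equals counting by category alone
  man <- tibble::tibble(species = c("A", "B", "C"), n_genomes = 1L)
  byc_sp <- count_hits(u, c("species", "category"), manifest = man)
  marg <- byc_sp |> dplyr::group_by(category) |>
    dplyr::summarise(n = sum(n)) |> dplyr::arrange(category)
  expect_equal(marg$n, dplyr::arrange(by_cat, category)$n)
  # manifest species without hits appear with zero counts
  expect_true(all(byc_sp$n[byc_sp$species == "C"] == 0))
  expect_error(count_hits(u, "flavour"), "unknown grouping key")
})

test_that("empty tables give all-zero counts", {
  ct <- tiny_catalog()
  prot <- list(Sp_a = c(d1 = random_protein(60, seed = 5)))
  man <- tibble::tibble(species = "Sp_a", n_genomes = 2L)
  hits <- search_collection(ct, prot, e_threshold = 1e-30, manifest = man)
  u <- unique_hits(hits)
  cc <- count_hits(u, c("species", "category"), manifest = man)
  expect_equal(nrow(cc), 3)
  expect_true(all(cc$n == 0))
})

test_that("genome normalization divides counts by manifest genome counts", {
  counts <- tibble::tibble(species = c("A", "B"), n = c(100L, 30L))
  man <- tibble::tibble(species = c("A", "B"), n_genomes = c(10L, 1L))
  norm <- normalize_by_genomes(counts, man)
  expect_equal(norm$normalized, c(10, 30))
  # all-ones manifest leaves counts unchanged
  man1 <- tibble::tibble(species = c("A", "B"), n_genomes = 1L)
  expect_equal(normalize_by_genomes(counts, man1)$normalized,
               as.numeric(counts$n))
  # equal density at 3x genome count gives equal normalized values
  c2 <- tibble::tibble(species = c("A", "B"), n = c(30L, 90L))
  m2 <- tibble::tibble(species = c("A", "B"), n_genomes = c(1L, 3L))
  expect_equal(normalize_by_genomes(c2, m2)$normalized, c(30, 30))
  expect_error(normalize_by_genomes(counts,
                                    tibble::tibble(species = "A",
                                                   n_genomes = 1L)),
               "missing")
  m0 <- tibble::tibble(species = c("A", "B"), n_genomes = c(1L, 0L))
  expect_error(normalize_by_genomes(counts, m0), "zero genomes")
})

test_that("category shares reproduce integer percentages", {
  sh <- category_shares(c(POLYESTER = 16528, CC_BACKBONE = 7069,
                          HETEROATOMIC = 5340))
  expect_equal(sh$share_pct[match(c("POLYESTER", "CC_BACKBONE",
                                    "HETEROATOMIC"), sh$group)],
               c(57, 24, 18))
  sh2 <- category_shares(c(carboxylesterase = 7007,
                           `PLA-depolymerase` = 5302,
                           `PHB-depolymerase` = 4328))
  expect_equal(sh2$share_pct, c(42, 32, 26))
  expect_equal(category_shares(c(a = 0, b = 7))$share_pct, c(0, 100))
  expect_error(category_shares(c(a = 0, b = 0)), "zero")
  # shares sum to 100 within rounding for random count vectors
  set.seed(4)
  for (i in 1:20) {
    x <- stats::rpois(sample(2:6, 1), 500) + 1
    names(x) <- paste0("g", seq_along(x))
    expect_lte(abs(sum(category_shares(x)$share_pct) - 100), 1)
  }
})

test_that("species scores sum raw scores per group with union attribution", {
  tab <- dplyr::bind_rows(
    hit_row("Q1", "X1", "A", 100, polymers = "PE"),
    hit_row("Q2", "X2", "A", 200, polymers = "PE"),
    hit_row("Q3", "Y1", "B", 50, polymers = "PE"),
    hit_row("Q4", "X3", "A", 70, polymers = c("PE", "PET"))
  )
  u <- unique_hits(tab)
  sc <- species_score(u, "category")
  wide <- score_matrix_wide(sc)
  expect_equal(wide$CC_BACKBONE[wide$species == "A"], 370)
  expect_equal(wide$CC_BACKBONE[wide$species == "B"], 50)
  expect_equal(wide$HETEROATOMIC[wide$species == "A"], 70)  # X3 counts twice
  expect_true(all(sc$score >= 0))
  # additivity: column totals equal the summed unique-hit scores per group
  cc_total <- sum(sc$score[sc$group == "CC_BACKBONE"])
  manual <- sum(u$score[vapply(u$categories,
                               function(g) "CC_BACKBONE" %in% g,
                               logical(1))])
  expect_equal(cc_total, manual)
  # empty table gives an all-zero matrix over the manifest
  man <- tibble::tibble(species = c("A", "B"), n_genomes = 1L)
  empty <- unique_hits(tab[0, ])
  sc0 <- species_score(empty, "category", manifest = man)
  expect_equal(nrow(sc0), 6)
  expect_true(all(sc0$score == 0))
})

test_that("species ranking is by descending score with lexicographic ties", {
  sc <- structure(tibble::tibble(
    species = c("A", "B", "C"), group = "CC_BACKBONE",
    score = c(300, 50, 300)), class = c("plastic_scores", "tbl_df",
                                        "tbl", "data.frame"))
  expect_equal(rank_species(sc, "CC_BACKBONE"), c("A", "C", "B"))
  sc$score <- c(5, 5, 5)
  expect_equal(rank_species(sc, "CC_BACKBONE"), c("A", "B", "C"))
  expect_error(rank_species(sc, "POLYESTER"), "not present")
})
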