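#' Simulate a synthetic collection and write its artifacts
#'
#' Realizes a [synthetic_spec()] (or a YAML spec file) against a catalog and
#' writes the per-genome FASTAs, manifest and truth table, plus a
#' `simulate_summary.json` echoing all parameters and the seed.
#'
#' @param spec A [synthetic_spec()] or path to a YAML spec file.
#' @param catalog Catalog tibble.
#' @param out_dir Output directory.
#' @return The collection (see [generate_collection()]), invisibly.
#' @export
run_simulate <- function(spec, catalog, out_dir) {
  if (is.character(spec)) spec <- read_synthetic_spec(spec)
  collection <- generate_collection(spec, catalog)
  write_collection(collection, out_dir)
  summary <- list(
    seed = spec$seed,
    species = spec$species$species,
    n_genomes = spec$species$n_genomes,
    decoys_per_genome = spec$decoys_per_genome,
    decoy_length_range = spec$decoy_length_range,
    n_planted = nrow(collection$truth),
    n_sequences = nrow(collection$sequences)
  )
  jsonlite::write_json(summary, file.path(out_dir, "simulate_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(collection)
}

#' Mine a collection against a catalog and write every analysis artifact
#'
#' Runs the full statistical workflow: homology search, unique-hit
#' reduction, grouped counts (raw and genome-normalized where species are
#' involved), category shares, degradation-potential score matrices and
#' species rankings. All artifacts are TSV/JSON under `out_dir`; a
#' `run_summary.json` records inputs, parameters and totals. Deterministic:
#' rerunning with the same inputs reproduces every file byte-for-byte.
#'
#' @param catalog Catalog tibble (deduplicated internally).
#' @param collection A collection list (from [generate_collection()] /
#'   [read_collection()]) or a collection directory path.
#' @param out_dir Output directory.
#' @param scheme A [scoring_scheme()].
#' @param e_threshold E-value cutoff (default 0.05).
#' @return List with `hits`, `unique`, `counts` (named list of count
#'   tibbles), `scores_category`, `scores_enzyme`, `manifest`, invisibly.
#' @export
run_mine <- function(catalog, collection, out_dir,
                     scheme = scoring_scheme(), e_threshold = 0.05) {
  if (is.character(collection)) collection <- read_collection(collection)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  catalog <- dedup_catalog(catalog)
  proteomes <- as_proteomes(collection)
  hits <- search_collection(catalog, proteomes, scheme = scheme,
                            e_threshold = e_threshold,
                            manifest = collection$manifest)
  uh <- unique_hits(hits)
  write_hit_table(hits, file.path(out_dir, "hits.tsv"))
  write_hit_table(uh, file.path(out_dir, "unique_hits.tsv"))
  if (nrow(uh) > 0) {
    useqs <- collection$sequences$sequence[
      match(uh$subject_id, collection$sequences$subject_id)]
    write_fasta(setNames(useqs, uh$subject_id),
                file.path(out_dir, "unique_hits.fasta"))
  }

  counts <- list(
    category = count_hits(uh, "category"),
    plastic = count_hits(uh, "plastic"),
    species = count_hits(uh, "species"),
    enzyme_class = count_hits(uh, "enzyme_class"),
    species_category = count_hits(uh, c("species", "category"))
  )
  for (nm in names(counts)) {
    tab <- counts[[nm]]
    if ("species" %in% names(tab))
      tab <- normalize_by_genomes(tab, collection$manifest)
    counts[[nm]] <- tab
    write.table(as.data.frame(tab),
                file.path(out_dir, paste0("counts_by_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  shares <- category_shares(counts$category)
  write.table(as.data.frame(shares),
              file.path(out_dir, "category_shares.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  sc_cat <- species_score(uh, "category", manifest = collection$manifest)
  sc_enz <- species_score(uh, "enzyme_class",
                          manifest = collection$manifest)
  for (x in list(list(sc_cat, "category"), list(sc_enz, "enzyme"))) {
    wide <- score_matrix_wide(x[[1]])
    write.table(as.data.frame(wide),
                file.path(out_dir, paste0("scores_by_", x[[2]], ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(wide,
                         file.path(out_dir,
                                   paste0("scores_by_", x[[2]], ".json")),
                         digits = NA, pretty = TRUE)
  }
  rankings <- dplyr::bind_rows(lapply(unique(sc_cat$group), function(g)
    tibble::tibble(group = g, rank = seq_along(rank_species(sc_cat, g)),
                   species = rank_species(sc_cat, g))))
  write.table(as.data.frame(rankings),
              file.path(out_dir, "ranking_by_category.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(
    parameters = list(
      matrix = scheme$matrix_name, gap_open = scheme$gap_open,
      gap_extend = scheme$gap_extend, lambda = scheme$lambda,
      k_param = scheme$k_param, h_param = scheme$h_param,
      e_threshold = e_threshold),
    n_queries = nrow(catalog),
    n_species = nrow(collection$manifest),
    n_subjects = nrow(collection$sequences),
    n_hits = nrow(hits),
    n_unique_hits = nrow(uh)
  )
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res <- list(hits = hits, unique = uh, counts = counts, shares = shares,
              scores_category = sc_cat, scores_enzyme = sc_enz,
              manifest = collection$manifest, summary = summary)
  class(res) <- "plastic_mine"
  invisible(res)
}

#' Clusterize an enzyme class and extract the nearest-reference subtree
#'
#' Collects the unique HITs of one enzyme class together with the catalog
#' references of that class (or an explicit reference set), aligns them with
#' [progressive_msa()], builds the bootstrap-supported NJ tree and the
#' subtree of the `k` leaves nearest each reference, and writes the aligned
#' FASTA, both Newick files (bootstrap as internal node labels) and a
#' leaf-assignment TSV.
#'
#' @param mine A `plastic_mine` result from [run_mine()].
#' @param collection The mined collection (for subject sequences).
#' @param catalog The (deduplicated) catalog.
#' @param group Enzyme-class label to clusterize.
#' @param out_dir Output directory.
#' @param references Accessions to anchor the subtree; default: all catalog
#'   entries of `group`.
#' @param k Nearest leaves kept per reference (default 3).
#' @param n_boot Bootstrap replicates (default 50).
#' @param seed Bootstrap RNG seed.
#' @param scheme A [scoring_scheme()].
#' @return List with `alignment`, `tree`, `subtree`, invisibly.
#' @export
run_tree <- function(mine, collection, catalog, group, out_dir,
                     references = NULL, k = 3L, n_boot = 50L, seed = 1L,
                     scheme = scoring_scheme()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  catalog <- dedup_catalog(catalog)
  uh <- mine$unique
  sel <- vapply(uh$enzyme_classes, function(e) group %in% e, logical(1))
  hit_ids <- uh$subject_id[sel]
  if (is.null(references))
    references <- catalog$accession[catalog$enzyme_class == group]
  miss <- setdiff(references, catalog$accession)
  if (length(miss))
    stop("reference(s) absent from catalog: ", paste(miss, collapse = ", "))
  seqs <- c(
    setNames(catalog$sequence[match(references, catalog$accession)],
             references),
    setNames(collection$sequences$sequence[
      match(hit_ids, collection$sequences$subject_id)], hit_ids)
  )
  if (length(seqs) < 4)
    stop(sprintf(
      "group '%s' yields %d sequences; >= 4 are needed for clusterization",
      group, length(seqs)))
  aln <- progressive_msa(seqs, scheme)
  tree <- bootstrap_support(aln, n_reps = n_boot, seed = seed)
  sub <- subtree_near_reference(tree, references, k)
  write_fasta(aln, file.path(out_dir, paste0(group, "_aligned.fasta")))
  ape::write.tree(tree, file.path(out_dir, paste0(group, "_tree.nwk")))
  ape::write.tree(sub, file.path(out_dir, paste0(group, "_subtree.nwk")))
  D <- ape::cophenetic.phylo(tree)
  nearest_ref <- vapply(tree$tip.label, function(l) {
    if (l %in% references) return(l)
    references[which.min(D[l, references])]
  }, "")
  assign <- tibble::tibble(
    leaf = tree$tip.label,
    is_reference = tree$tip.label %in% references,
    in_subtree = tree$tip.label %in% sub$tip.label,
    nearest_reference = nearest_ref
  )
  write.table(as.data.frame(assign),
              file.path(out_dir, paste0(group, "_leaf_assignments.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(alignment = aln, tree = tree, subtree = sub,
                 assignments = assign))
}
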