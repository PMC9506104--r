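#' Search a proteome collection against a reference catalog
#'
#' Every (query, subject protein) pair is aligned with affine-gap
#' Smith-Waterman; the optimal local alignment becomes one annotated HIT row
#' when its E-value is within `e_threshold` (inclusive — matches are dropped
#' only when their significance exceeds the threshold). The database for
#' E-value purposes is the whole collection (all species pooled), with
#' BLAST-style effective-length correction of the search space. Only the
#' optimal alignment per pair is reported, never sub-optimal ones.
#'
#' @param catalog A (deduplicated) catalog tibble; see [dedup_catalog()].
#' @param proteomes Named list mapping species label to a named character
#'   vector of protein sequences (subject ids as names). A species with an
#'   empty proteome triggers a warning and contributes no rows.
#' @param scheme A [scoring_scheme()].
#' @param e_threshold Report a match when E-value <= this (default 0.05).
#' @param manifest Optional tibble (`species`, `n_genomes`) recorded as the
#'   `manifest` attribute of the result; defaults to one genome per species.
#' @return A HIT tibble with columns `gene_id`, `plastic_group`, `plastic`,
#'   `plastic_enzyme`, `species`, `subject_id`, `score`, `bit_score`,
#'   `evalue`, `identity`, spans `q_start`/`q_end`/`s_start`/`s_end`
#'   (0-based half-open) and list-columns `categories`/`polymers` carrying
#'   the query annotation. The collection manifest is attached as attribute
#'   `manifest`.
#' @export
search_collection <- function(catalog, proteomes, scheme = scoring_scheme(),
                              e_threshold = 0.05, manifest = NULL) {
  stopifnot(length(proteomes) > 0, !is.null(names(proteomes)))
  empty <- names(proteomes)[lengths(proteomes) == 0]
  if (length(empty))
    warning("empty proteome for species: ", paste(empty, collapse = ", "))
  if (is.null(manifest))
    manifest <- tibble::tibble(species = names(proteomes), n_genomes = 1L)

  mat <- scheme$matrix
  subj_tbl <- tibble::tibble(
    species = rep(names(proteomes), lengths(proteomes)),
    subject_id = unlist(lapply(proteomes, names), use.names = FALSE),
    sequence = unlist(proteomes, use.names = FALSE)
  )
  if (nrow(subj_tbl) > 0 && anyDuplicated(subj_tbl$subject_id))
    stop("subject ids must be unique across the collection")
  db_len <- sum(nchar(subj_tbl$sequence))
  n_db <- nrow(subj_tbl)
  subj_enc <- lapply(subj_tbl$sequence, encode_protein, mat = mat)

  rows <- vector("list", nrow(catalog))
  for (qi in seq_len(nrow(catalog))) {
    q <- catalog$sequence[qi]
    qenc <- encode_protein(q, mat, paste0("query ", catalog$accession[qi]))
    m <- nchar(q)
    eff <- effective_lengths(m, db_len, n_db, scheme)
    hits <- list()
    for (sj in seq_len(n_db)) {
      raw <- sw_score_cpp(qenc, subj_enc[[sj]], mat,
                          scheme$gap_open, scheme$gap_extend)
      if (raw == 0L) next
      bits <- bit_score(raw, scheme)
      ev <- e_value(bits, eff$m, eff$n)
      if (ev > e_threshold) next
      aln <- smith_waterman(q, subj_tbl$sequence[sj], scheme)
      hits[[length(hits) + 1L]] <- tibble::tibble(
        gene_id = catalog$accession[qi],
        plastic_group = paste(catalog$categories[[qi]], collapse = ","),
        plastic = paste(catalog$polymers[[qi]], collapse = ","),
        plastic_enzyme = catalog$enzyme_class[qi],
        species = subj_tbl$species[sj],
        subject_id = subj_tbl$subject_id[sj],
        score = aln$raw_score,
        bit_score = bits,
        evalue = ev,
        identity = aln$identity_pct,
        q_start = aln$q_start, q_end = aln$q_end,
        s_start = aln$s_start, s_end = aln$s_end,
        categories = catalog$categories[qi],
        polymers = catalog$polymers[qi]
      )
    }
    rows[[qi]] <- if (length(hits)) dplyr::bind_rows(hits) else NULL
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0)
    out <- tibble::tibble(
      gene_id = character(), plastic_group = character(),
      plastic = character(), plastic_enzyme = character(),
      species = character(), subject_id = character(),
      score = integer(), bit_score = double(), evalue = double(),
      identity = double(), q_start = integer(), q_end = integer(),
      s_start = integer(), s_end = integer(),
      categories = list(), polymers = list()
    )
  attr(out, "manifest") <- manifest
  attr(out, "e_threshold") <- e_threshold
  out
}

#' Write a HIT table TSV
#'
#' Exports the annotated HIT schema: `gene_id`, `plastic_group`, `plastic`,
#' `plastic_enzyme`, `species`, `subject_id`, `score`, `evalue`, `identity`.
#'
#' @param hits A HIT tibble from [search_collection()] or [unique_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  cols <- c("gene_id", "plastic_group", "plastic", "plastic_enzyme",
            "species", "subject_id", "score", "evalue", "identity")
  df <- as.data.frame(hits[, cols])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a HIT table TSV written by [write_hit_table()]
#'
#' List-columns `categories`/`polymers` are reconstituted from the
#' comma-joined `plastic_group`/`plastic` fields.
#'
#' @param path Path to the TSV.
#' @return A HIT tibble.
#' @export
read_hit_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   comment.char = "", stringsAsFactors = FALSE)
  out <- tibble::as_tibble(df)
  out$categories <- strsplit(out$plastic_group, ",", fixed = TRUE)
  out$polymers <- strsplit(out$plastic, ",", fixed = TRUE)
  out
}
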