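#' Polymer codes and their backbone categories
#'
#' The 15 recognised polymer codes, grouped into three backbone categories:
#' `CC_BACKBONE` (PE), `HETEROATOMIC` (PET, PU) and `POLYESTER` (PHB, PES,
#' PPL, PCL, PLA, PHV, PHBV, PHPV, PBS, PBSA, PBAT, Ecoflex).
#'
#' @return Named character vector mapping polymer code to category.
#' @export
polymer_categories <- function() {
  c(PE = "CC_BACKBONE",
    PET = "HETEROATOMIC", PU = "HETEROATOMIC",
    PHB = "POLYESTER", PES = "POLYESTER", PPL = "POLYESTER",
    PCL = "POLYESTER", PLA = "POLYESTER", PHV = "POLYESTER",
    PHBV = "POLYESTER", PHPV = "POLYESTER", PBS = "POLYESTER",
    PBSA = "POLYESTER", PBAT = "POLYESTER", Ecoflex = "POLYESTER")
}

#' The three polymer backbone categories
#' @return Character vector of category labels.
#' @export
category_levels <- function() c("CC_BACKBONE", "HETEROATOMIC", "POLYESTER")

#' Assign a polymer code to its backbone category
#'
#' @param polymer Character vector of polymer codes (case-sensitive except
#'   `Ecoflex`, matched case-insensitively).
#' @return Character vector of categories.
#' @examples
#' assign_category(c("PE", "PET", "PBAT"))
#' @export
assign_category <- function(polymer) {
  map <- polymer_categories()
  key <- ifelse(tolower(polymer) == "ecoflex", "Ecoflex", toupper(polymer))
  out <- unname(map[key])
  if (anyNA(out)) {
    bad <- unique(polymer[is.na(out)])
    stop(sprintf("unknown polymer code(s): %s. Valid codes: %s",
                 paste(bad, collapse = ", "),
                 paste(names(map), collapse = ", ")))
  }
  out
}

.catalog_tibble <- function(accession, sequence, organism, phylum,
                            enzyme_class, polymers) {
  categories <- purrr::map(polymers, ~ sort(unique(assign_category(.x))))
  tibble::tibble(
    accession = accession, sequence = sequence, organism = organism,
    phylum = phylum, enzyme_class = enzyme_class,
    polymers = polymers, categories = categories
  )
}

#' Build a reference catalog in code
#'
#' Constructor for a catalog tibble, mainly for tests and simulations; file
#' input goes through [read_catalog()].
#'
#' @param accession,sequence,organism,phylum,enzyme_class Character vectors,
#'   one element per entry.
#' @param polymers List of character vectors of polymer codes (or a single
#'   character vector recycled as one code per entry).
#' @return A catalog tibble with columns `accession`, `sequence`, `organism`,
#'   `phylum`, `enzyme_class`, list-columns `polymers` and `categories`.
#' @export
make_catalog <- function(accession, sequence, organism = "unknown",
                         phylum = "unknown", enzyme_class = "unknown",
                         polymers = list("PE")) {
  n <- length(accession)
  if (anyDuplicated(accession))
    stop("duplicate accession(s): ",
         paste(unique(accession[duplicated(accession)]), collapse = ", "))
  if (!is.list(polymers)) polymers <- as.list(polymers)
  organism <- rep_len(organism, n); phylum <- rep_len(phylum, n)
  enzyme_class <- rep_len(enzyme_class, n)
  polymers <- rep_len(polymers, n)
  for (i in seq_len(n))
    validate_protein(sequence[i], what = paste0("sequence of ", accession[i]))
  if (any(lengths(polymers) == 0)) stop("every entry needs >= 1 polymer code")
  .catalog_tibble(accession, sequence, organism, phylum, enzyme_class, polymers)
}

#' Load a reference catalog from FASTA + metadata TSV
#'
#' FASTA records and metadata rows must join 1:1 on accession (the first
#' header token). The metadata TSV is tab-separated with a header row and
#' columns `accession`, `organism`, `phylum`, `enzyme_class`, `polymers`
#' (comma-joined polymer codes) and optionally `category` (ignored; the
#' category is always recomputed from the polymer codes). Rows whose
#' `polymers` field contains an unknown code are rejected with a warning
#' naming the accession.
#'
#' @param fasta_path Protein FASTA of the reference gene products.
#' @param metadata_path Metadata TSV as described above.
#' @return A catalog tibble (see [make_catalog()]).
#' @export
read_catalog <- function(fasta_path, metadata_path) {
  seqs <- read_fasta(fasta_path)
  meta <- read.table(metadata_path, sep = "\t", header = TRUE,
                     quote = "", comment.char = "", stringsAsFactors = FALSE)
  need <- c("accession", "organism", "phylum", "enzyme_class", "polymers")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(names(seqs)))
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (anyDuplicated(meta$accession))
    stop("duplicate accession(s) in metadata: ",
         paste(unique(meta$accession[duplicated(meta$accession)]),
               collapse = ", "))
  no_meta <- setdiff(names(seqs), meta$accession)
  if (length(no_meta))
    stop("FASTA record(s) absent from metadata: ",
         paste(no_meta, collapse = ", "))
  no_seq <- setdiff(meta$accession, names(seqs))
  if (length(no_seq))
    stop("metadata row(s) with no FASTA record: ",
         paste(no_seq, collapse = ", "))

  meta <- meta[match(names(seqs), meta$accession), ]
  polys <- strsplit(meta$polymers, "\\s*,\\s*")
  ok <- vapply(polys, function(p)
    length(p) > 0 && !inherits(try(assign_category(p), silent = TRUE),
                               "try-error"), logical(1))
  if (any(!ok)) {
    warning("rejecting entr(ies) with unknown polymer codes: ",
            paste(meta$accession[!ok], collapse = ", "))
    meta <- meta[ok, ]; seqs <- seqs[ok]; polys <- polys[ok]
  }
  if (nrow(meta) == 0) stop("no valid catalog entries after validation")
  for (i in seq_len(nrow(meta)))
    validate_protein(seqs[[i]], what = paste0("sequence of ", meta$accession[i]))
  .catalog_tibble(meta$accession, unname(seqs), meta$organism, meta$phylum,
                  meta$enzyme_class, polys)
}

#' Collapse a catalog to unique amino-acid sequences
#'
#' Entries with byte-identical sequences are merged: the first entry by input
#' order is retained and the polymer annotations of the merged duplicates are
#' unioned (categories recomputed accordingly). Idempotent. Uniqueness is
#' exact sequence identity; near-identical sequences are not merged.
#'
#' @param catalog A catalog tibble.
#' @return The deduplicated catalog, with a `merged_accessions` list-column
#'   recording which accessions each retained entry absorbed.
#' @export
dedup_catalog <- function(catalog) {
  grp <- match(catalog$sequence, unique(catalog$sequence))
  keep <- !duplicated(grp)
  merged <- split(catalog$accession, grp)
  polys <- lapply(split(catalog$polymers, grp),
                  function(ps) sort(unique(unlist(ps))))
  out <- catalog[keep, ]
  ord <- as.character(grp[keep])
  out$polymers <- unname(polys[ord])
  out$categories <- purrr::map(out$polymers,
                               ~ sort(unique(assign_category(.x))))
  out$merged_accessions <- unname(merged[ord])
  out
}

#' Write catalog sequences and metadata back to disk
#'
#' @param catalog A catalog tibble.
#' @param fasta_path,metadata_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_catalog <- function(catalog, fasta_path, metadata_path) {
  write_fasta(setNames(catalog$sequence, catalog$accession), fasta_path)
  meta <- data.frame(
    accession = catalog$accession, organism = catalog$organism,
    phylum = catalog$phylum, enzyme_class = catalog$enzyme_class,
    polymers = vapply(catalog$polymers, paste, "", collapse = ","),
    category = vapply(catalog$categories, paste, "", collapse = ",")
  )
  write.table(meta, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fasta_path, metadata_path))
}
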