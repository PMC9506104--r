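# round half away from zero, matching how the printed shares were derived
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Reduce a HIT table to unique subject sequences
#'
#' One row is kept per distinct `subject_id`: among duplicates the row with
#' the highest score wins (ties broken by lowest E-value, then first
#' occurrence). The polymer-category, polymer and enzyme-class annotations of
#' all merged rows are preserved as unions in the list-columns `categories`,
#' `polymers` and `enzyme_classes`, so a subject matched by queries of
#' different categories still counts toward each category downstream.
#' Idempotent.
#'
#' @param hits A HIT tibble from [search_collection()].
#' @return The reduced HIT tibble (manifest attribute preserved).
#' @export
unique_hits <- function(hits) {
  man <- attr(hits, "manifest")
  if (nrow(hits) == 0) {
    out <- hits
    out$enzyme_classes <- list()
    attr(out, "manifest") <- man
    return(out)
  }
  if (!"enzyme_classes" %in% names(hits))
    hits$enzyme_classes <- as.list(hits$plastic_enzyme)
  hits$.ord <- seq_len(nrow(hits))
  out <- hits |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      .best = list({
        o <- order(-.data$score, .data$evalue, .data$.ord)
        dplyr::pick(dplyr::everything())[o[1], ]
      }),
      .categories = list(sort(unique(unlist(.data$categories)))),
      .polymers = list(sort(unique(unlist(.data$polymers)))),
      .enzymes = list(sort(unique(unlist(.data$enzyme_classes)))),
      .groups = "drop"
    )
  best <- dplyr::bind_rows(out$.best)
  best$subject_id <- out$subject_id
  best$categories <- out$.categories
  best$polymers <- out$.polymers
  best$enzyme_classes <- out$.enzymes
  best <- best[order(best$.ord), ]
  best$.ord <- NULL
  best <- tibble::as_tibble(best)
  attr(best, "manifest") <- man
  best
}

.key_column <- function(key) {
  switch(key,
    category = "categories",
    plastic = "polymers",
    enzyme_class = "enzyme_classes",
    species = "species",
    stop(sprintf(
      "unknown grouping key '%s'; valid keys: category, plastic, species, enzyme_class",
      key))
  )
}

#' Count unique HITs grouped by annotation keys
#'
#' Counts over the Cartesian grouping of the requested keys. A subject
#' annotated with several categories/polymers/enzyme classes contributes one
#' count to each value of that key (the union semantics of [unique_hits()]),
#' but only once per key value. When grouping includes `species`, every
#' species of the manifest is emitted, with zero counts where it has no
#' hits; grouping by `category` always emits all three categories.
#'
#' @param hits A unique-reduced HIT tibble (see [unique_hits()]).
#' @param keys Character vector, subset of
#'   `c("category", "plastic", "species", "enzyme_class")`.
#' @param manifest Optional manifest tibble (`species`, `n_genomes`);
#'   defaults to the table's `manifest` attribute.
#' @return A count tibble with one column per key plus `n`.
#' @export
count_hits <- function(hits, keys = "category", manifest = NULL) {
  if (is.null(manifest)) manifest <- attr(hits, "manifest")
  cols <- vapply(keys, .key_column, "")
  tbl <- hits[, unique(c("subject_id", unname(cols))), drop = FALSE]
  for (k in seq_along(keys)) {
    col <- unname(cols[k])
    if (col != "species") {
      tbl <- tidyr::unnest(tbl, dplyr::all_of(col))
      tbl <- dplyr::distinct(tbl)
    }
    names(tbl)[names(tbl) == col] <- keys[k]
  }
  counts <- tbl |>
    dplyr::count(dplyr::across(dplyr::all_of(unname(keys))), name = "n")
  # zero-fill known levels
  fill <- list()
  if ("species" %in% keys && !is.null(manifest))
    fill$species <- manifest$species
  if ("category" %in% keys)
    fill$category <- category_levels()
  for (k in setdiff(keys, names(fill)))
    fill[[k]] <- unique(counts[[k]])
  fill <- fill[lengths(fill) > 0]
  if (length(fill) == length(keys) && nrow(counts) >= 0) {
    grid <- do.call(tidyr::expand_grid, fill[keys])
    counts <- dplyr::left_join(grid, counts, by = keys) |>
      dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  }
  structure(tibble::as_tibble(counts), class = c("plastic_counts",
                                                 class(tibble::tibble())))
}

#' Normalize per-species counts by genome count
#'
#' Divides each species' count by the number of genomes searched for that
#' species, yielding per-genome densities comparable across unevenly sampled
#' species.
#'
#' @param counts A count tibble containing a `species` column and `n`.
#' @param manifest Tibble with `species` and `n_genomes` (all >= 1).
#' @return `counts` with an added `normalized` column.
#' @export
normalize_by_genomes <- function(counts, manifest) {
  stopifnot("species" %in% names(counts), "n" %in% names(counts))
  miss <- setdiff(unique(counts$species), manifest$species)
  if (length(miss))
    stop("species missing from manifest: ", paste(miss, collapse = ", "))
  if (any(manifest$n_genomes < 1))
    stop("species with zero genomes in manifest: ",
         paste(manifest$species[manifest$n_genomes < 1], collapse = ", "))
  out <- dplyr::left_join(counts,
                          manifest[, c("species", "n_genomes")],
                          by = "species") |>
    dplyr::mutate(normalized = .data$n / .data$n_genomes) |>
    dplyr::select(-"n_genomes")
  class(out) <- class(counts)
  out
}

#' Percentage share of each group in a set of counts
#'
#' Each group's percentage of the grand total, rounded half-away-from-zero
#' to the nearest integer percent; the rounded shares sum to 100 within
#' rounding error (+/- 1).
#'
#' @param counts Either a named numeric vector of counts, or a count tibble
#'   whose first column is the group label and which has an `n` column.
#' @return Tibble with columns `group`, `n`, `share_pct`.
#' @examples
#' category_shares(c(POLYESTER = 16528, CC_BACKBONE = 7069,
#'                   HETEROATOMIC = 5340))
#' @export
category_shares <- function(counts) {
  if (is.data.frame(counts)) {
    grp <- counts[[1]]
    n <- counts$n
  } else {
    grp <- names(counts)
    n <- unname(counts)
  }
  stopifnot(length(n) > 0, all(n >= 0))
  if (sum(n) == 0) stop("all counts are zero; shares are undefined")
  tibble::tibble(group = grp, n = n,
                 share_pct = round_half_up(100 * n / sum(n)))
}

#' Degradation-potential score matrix
#'
#' For each species and group (polymer category or enzyme class), the sum of
#' raw alignment scores of that species' unique HITs attributed to that
#' group. A hit annotated with several groups contributes its score to each.
#' This summed raw score is the degradation-potential indicator for the
#' species/group pair.
#'
#' @param hits A unique-reduced HIT tibble (see [unique_hits()]).
#' @param group_axis `"category"` or `"enzyme_class"`.
#' @param manifest Optional manifest; species with no hits get zero rows.
#' @return A tidy score tibble (`species`, `group`, `score`) of class
#'   `plastic_scores`; use [score_matrix_wide()] for the matrix layout.
#' @export
species_score <- function(hits, group_axis = c("category", "enzyme_class"),
                          manifest = NULL) {
  group_axis <- match.arg(group_axis)
  if (is.null(manifest)) manifest <- attr(hits, "manifest")
  col <- .key_column(group_axis)
  if (nrow(hits) == 0) {
    out <- tibble::tibble(species = character(), group = character(),
                          score = double())
  } else {
    out <- hits[, c("species", "subject_id", "score", col)] |>
      tidyr::unnest(dplyr::all_of(col)) |>
      dplyr::distinct() |>
      dplyr::rename(group = dplyr::all_of(col)) |>
      dplyr::group_by(.data$species, .data$group) |>
      dplyr::summarise(score = sum(.data$score), .groups = "drop")
  }
  species_lv <- if (!is.null(manifest)) manifest$species
                else unique(out$species)
  group_lv <- if (group_axis == "category") category_levels()
              else unique(out$group)
  if (length(species_lv) && length(group_lv)) {
    grid <- tidyr::expand_grid(species = species_lv, group = group_lv)
    out <- dplyr::left_join(grid, out, by = c("species", "group")) |>
      dplyr::mutate(score = dplyr::coalesce(.data$score, 0))
  }
  structure(tibble::as_tibble(out),
            class = c("plastic_scores", class(tibble::tibble())))
}

#' Pivot a tidy score table to species x group matrix layout
#'
#' @param scores A `plastic_scores` tibble from [species_score()].
#' @return A tibble with one row per species and one column per group.
#' @export
score_matrix_wide <- function(scores) {
  tidyr::pivot_wider(tibble::as_tibble(scores), names_from = "group",
                     values_from = "score", values_fill = 0)
}

#' Rank species by degradation-potential score within a group
#'
#' @param scores A `plastic_scores` tibble from [species_score()].
#' @param group A group label present in `scores$group`.
#' @return Character vector of species, sorted by descending score; ties
#'   broken lexicographically.
#' @export
rank_species <- function(scores, group) {
  if (!group %in% scores$group)
    stop(sprintf("group '%s' not present; available: %s", group,
                 paste(unique(scores$group), collapse = ", ")))
  sub <- scores[scores$group == group, ]
  sub$species[order(-sub$score, sub$species)]
}
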