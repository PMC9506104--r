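#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of grouped unique-HIT counts
#'
#' Plots a count tibble from [count_hits()]; faceted by species when both a
#' species and another key are present, and using the normalized counts when
#' [normalize_by_genomes()] has been applied.
#'
#' @param object A `plastic_counts` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot plastic_counts
#' @export
autoplot.plastic_counts <- function(object, ...) {
  ycol <- if ("normalized" %in% names(object)) "normalized" else "n"
  keys <- setdiff(names(object), c("n", "normalized"))
  xcol <- setdiff(keys, "species")
  if (length(xcol) == 0) xcol <- "species"
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data[[xcol[1]]],
                                    y = .data[[ycol]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = xcol[1],
                  y = if (ycol == "normalized")
                    "unique HITs per genome" else "unique HITs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if ("species" %in% keys && length(xcol) && xcol[1] != "species")
    p <- p + ggplot2::facet_wrap(~species)
  p
}

#' Heatmap of species x group degradation-potential scores
#'
#' @param object A `plastic_scores` tibble from [species_score()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot plastic_scores
#' @export
autoplot.plastic_scores <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$group, y = .data$species,
                               fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "summed score") +
    ggplot2::theme_minimal()
}

#' Pie-style share chart for category shares
#'
#' @param shares Output of [category_shares()].
#' @return A ggplot object.
#' @export
plot_category_shares <- function(shares) {
  ggplot2::ggplot(shares,
                  ggplot2::aes(x = "", y = .data$n, fill = .data$group)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$share_pct, "%")),
                       position = ggplot2::position_stack(vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_void()
}

#' Tidy the bootstrap supports of a clusterization tree
#'
#' @param x A `phylo` tree from [bootstrap_support()].
#' @param ... Ignored.
#' @return Tibble with one row per internal edge: `node`, `support`.
#' @method tidy phylo
#' @export
tidy.phylo <- function(x, ...) {
  supp <- attr(x, "support")
  n_tip <- length(x$tip.label)
  tibble::tibble(
    node = n_tip + seq_len(x$Nnode),
    support = if (!is.null(supp)) supp
              else suppressWarnings(as.numeric(x$node.label %||% NA))
  )
}

#' One-row summary of a mining run
#'
#' @param x A `plastic_mine` result from [run_mine()].
#' @param ... Ignored.
#' @return One-row tibble with query/subject/hit totals and the threshold.
#' @method glance plastic_mine
#' @export
glance.plastic_mine <- function(x, ...) {
  tibble::tibble(
    n_queries = x$summary$n_queries,
    n_species = x$summary$n_species,
    n_subjects = x$summary$n_subjects,
    n_hits = x$summary$n_hits,
    n_unique_hits = x$summary$n_unique_hits,
    e_threshold = x$summary$parameters$e_threshold
  )
}

#' Tidy the unique-HIT table of a mining run
#'
#' @param x A `plastic_mine` result from [run_mine()].
#' @param ... Ignored.
#' @return The unique-HIT tibble.
#' @method tidy plastic_mine
#' @export
tidy.plastic_mine <- function(x, ...) x$unique
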