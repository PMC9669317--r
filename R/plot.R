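# ggplot2 views of the evaluation result types.

rank_factor <- function(x) factor(x, levels = tax_ranks())

#' Plot per-rank novelty
#'
#' @param object An `eco_novelty` (sequence novelty) or `eco_novelty_taxa`
#'   (de novo taxa) result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eco_novelty <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = rank_factor(.data$rank),
                                    y = .data$pct_novel)) +
    ggplot2::geom_col(fill = "#3b6ea5") +
    ggplot2::labs(x = NULL, y = "novel sequences (%)",
                  title = "Sequence novelty by rank threshold")
  if ("domain" %in% names(object)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$domain))
  }
  p
}

#' @rdname autoplot.eco_novelty
#' @export
autoplot.eco_novelty_taxa <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = rank_factor(.data$rank),
                                       y = .data$pct_denovo)) +
    ggplot2::geom_col(fill = "#b05a33") +
    ggplot2::labs(x = NULL, y = "de novo taxa (%)",
                  title = "Taxonomy novelty (placeholder names) by rank")
}

#' Plot per-sample high-identity coverage
#'
#' @param object An `eco_coverage` result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eco_coverage <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("frac_high_identity", "coverage"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$value)) +
    ggplot2::geom_col(fill = "#3b6ea5") +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), ncol = 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "High-identity hit fraction and abundance coverage")
}

#' Plot amplicon taxonomic resolution
#'
#' @param object An `eco_resolution` result.
#' @param ... Unused.
#' @return A ggplot (stacked fractions per rank).
#' @export
autoplot.eco_resolution <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("correct", "wrong", "not_classified"),
                              names_to = "outcome", values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rank, y = .data$fraction,
                                     fill = .data$outcome)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(correct = "#4d8f4d",
                                          wrong = "#b03333",
                                          not_classified = "grey70")) +
    ggplot2::labs(x = NULL, y = "fraction of in-silico ASVs",
                  title = "In-silico amplicon taxonomic resolution")
}

#' Plot primer-bias survey results
#'
#' @param object An `eco_survey` result (uses its per-taxon summary when
#'   available, else overall category fractions).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eco_survey <- function(object, ...) {
  summ <- attr(object, "summary")
  if (is.null(summ)) {
    df <- as_tibble(object) |>
      dplyr::count(.data$category) |>
      mutate(fraction = .data$n / sum(.data$n), group = "all")
  } else {
    df <- tidyr::pivot_longer(summ, c("perfect", "partial", "poor", "no_site"),
                              names_to = "category", values_to = "fraction")
    names(df)[1] <- "group"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$fraction,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(perfect = "#4d8f4d",
                                          partial = "#d9a441",
                                          poor = "#b03333",
                                          no_site = "grey60")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fraction of records",
                  title = "Primer-bias categories")
}
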