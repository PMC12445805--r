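#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_hline
#'   labs theme_minimal facet_wrap coord_equal
#' @export
ggplot2::autoplot

#' Plot an NMDS ordination
#'
#' First two ordination axes, optionally coloured by group.
#'
#' @param object a `sterolome_nmds`.
#' @param groups optional labels, one per point.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.sterolome_nmds <- function(object, groups = NULL, ...) {
  df <- tidy(object)
  if (!is.null(groups)) df$group <- groups
  p <- ggplot(df, aes(x = .data$NMDS1, y = .data$NMDS2)) +
    (if (is.null(groups)) geom_point() else
      geom_point(aes(colour = .data$group))) +
    coord_equal() +
    labs(caption = sprintf("Kruskal stress-1 = %.3f (k = %d)",
                           object$stress, object$k)) +
    theme_minimal()
  p
}

#' Plot a phylogenetic-signal screen
#'
#' Blomberg's K against Pagel's lambda per trait, with the Brownian
#' reference (K = lambda = 1) marked.
#'
#' @param object a `sterolome_signal` table from [signal_screen()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.sterolome_signal <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$lambda, y = .data$K,
                                colour = .data$trait_type)) +
    geom_point() +
    geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    labs(x = "Pagel's lambda (ML)", y = "Blomberg's K",
         colour = "trait") +
    theme_minimal()
}

#' Plot a bee-sufficiency histogram
#'
#' Number of taxa meeting 0..6 of the honeybee sterol requirements.
#'
#' @param summary a [cohort_summary()] result.
#' @return A ggplot.
#' @export
plot_sufficiency <- function(summary) {
  ggplot(summary$histogram, aes(x = factor(.data$count_met),
                                y = .data$n_taxa)) +
    geom_col() +
    labs(x = "requirements met (of 6)", y = "taxa") +
    theme_minimal()
}

#' Plot taxon sterol-class composition
#'
#' Stacked B-ring class proportions per taxon.
#'
#' @param classes a [class_proportions()] table.
#' @param class_type `"bring"` or `"carbons"`.
#' @param id the unit column name (default `"taxon"`).
#' @return A ggplot.
#' @export
plot_class_composition <- function(classes, class_type = "bring",
                                   id = "taxon") {
  df <- filter(classes, .data$class_type == !!class_type)
  ggplot(df, aes(x = .data[[id]], y = .data$proportion,
                 fill = .data$class)) +
    geom_col() +
    labs(x = NULL, y = "proportion", fill = class_type) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1))
}
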