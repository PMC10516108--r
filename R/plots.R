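# ggplot2 views of the main result types.

#' Plot the score trajectory of a run
#'
#' Fraction of scored molecules at or above the threshold, mean score and
#' max score per iteration.
#'
#' @param object An `al_run_state` (from [run_loop()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot al_run_state
#' @export
autoplot.al_run_state <- function(object, ...) {
  m <- object$metrics %>%
    select("iteration", "fraction_above_threshold", "mean_score", "max_score") %>%
    tidyr::pivot_longer(-"iteration", names_to = "metric")
  ggplot(m, aes(x = .data$iteration, y = .data$value)) +
    geom_line() + geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    labs(x = "iteration (0 = pretraining)", y = NULL,
         title = "Score evolution over active-learning iterations") +
    theme_bw()
}

#' Plot a clustering in the first two proxy components
#'
#' @param object A `chem_clustering`.
#' @param coordinates The coordinates that were clustered (tibble or
#'   matrix); only the first two components are drawn.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot chem_clustering
#' @export
autoplot.chem_clustering <- function(object, coordinates, ...) {
  X <- coord_matrix(coordinates)
  df <- tibble(PC1 = X[, 1], PC2 = X[, 2],
               cluster = factor(object$labels))
  ggplot(df, aes(x = .data$PC1, y = .data$PC2, colour = .data$cluster)) +
    geom_point(size = 0.8, show.legend = FALSE) +
    labs(title = sprintf("k-means clustering (k = %d)", object$k)) +
    theme_bw()
}

#' Scree plot of the chemical-space projection
#'
#' @param object A `chem_projection`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot chem_projection
#' @export
autoplot.chem_projection <- function(object, ...) {
  ggplot(tidy(object),
         aes(x = .data$component, y = .data$explained_variance_ratio)) +
    geom_line() + geom_point() +
    labs(x = "principal component", y = "explained variance ratio") +
    theme_bw()
}

#' Plot a similarity profile
#'
#' @param object A [similarity_profile()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_similarity_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$reference, y = .data$mean_tanimoto)) +
    ggplot2::geom_col() +
    labs(x = NULL, y = "mean Tanimoto similarity") +
    theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
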