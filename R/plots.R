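#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.permutation_null <- function(object, bins = 30, ...) {
  df <- tibble::tibble(HI = object$null)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$HI)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red",
                        linewidth = 1) +
    ggplot2::labs(x = "ensemble homoplasy index (HI)", y = "permutations",
                  title = "Taxon-permutation null of the ensemble HI",
                  subtitle = sprintf("observed %.3f (red) vs null mean %.3f",
                                     object$observed, object$null_mean)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hourglass_fit <- function(object, ...) {
  df <- object$quadratic$model
  names(df)[1] <- "y"
  grid <- tibble::tibble(D = seq(min(df$D), max(df$D), length.out = 100))
  grid$y <- predict(object$quadratic, newdata = grid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$D, y = .data$y)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.35, size = 1) +
    ggplot2::geom_line(data = grid, colour = "red", linewidth = 1) +
    ggplot2::labs(x = "developmental stage code D",
                  y = "per-character index",
                  title = "Developmental-hourglass regression") +
    ggplot2::theme_minimal()
}

#' Bar chart of state-category proportions
#'
#' Derived vs ancestral states split into the five categories (plus the
#' transient bucket when present).
#'
#' @param summary a [category_summary()] result
#' @return ggplot
#' @export
plot_category_summary <- function(summary) {
  df <- summary$by_category
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$fraction,
                                   fill = .data$ancestral)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#5778a4",
                                          `FALSE` = "#e49444"),
                               labels = c(`TRUE` = "ancestral",
                                          `FALSE` = "derived"),
                               name = NULL) +
    ggplot2::labs(x = NULL, y = "fraction of states",
                  title = "Character-state categories") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Bar chart of pairwise mechanism proportions
#'
#' @param mech a [mechanism_proportions()] result
#' @return ggplot
#' @export
plot_mechanism_proportions <- function(mech) {
  df <- mech$proportions
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mechanism,
                                   y = .data$proportion)) +
    ggplot2::geom_col(fill = "#5778a4") +
    ggplot2::labs(x = NULL, y = "proportion of taxon pairs",
                  title = "Pairwise evolutionary mechanisms",
                  subtitle = sprintf(
                    "homoplastic share of similar-state pairs: %.1f%%",
                    100 * mech$homoplasy_share_similar)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Scatter of color PCA scores colored by assigned state
#'
#' @param coding a [code_colors()] result
#' @return ggplot
#' @export
plot_color_coding <- function(coding) {
  if (is.null(coding$scores)) stop("degenerate coding has no scores")
  df <- dplyr::left_join(coding$scores, coding$states, by = "name")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = factor(.data$state))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(colour = "state", title = "Color states in PCA space") +
    ggplot2::theme_minimal()
}
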