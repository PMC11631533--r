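#' Plot a fitted PCA
#'
#' `type = "scree"` shows the variance explained per component;
#' `type = "scores"` the individuals on two chosen components.
#'
#' @param object A `pcb_pca`.
#' @param type `"scree"` or `"scores"`.
#' @param dims Two component indices for the score plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcb_pca <- function(object, type = c("scree", "scores"),
                             dims = c(1L, 2L), ...) {
  type <- match.arg(type)
  if (type == "scree") {
    d <- tidy(object)
    d$component <- factor(d$component, levels = d$component)
    ggplot(d, aes(x = .data$component, y = 100 * .data$prop_var)) +
      geom_col() +
      labs(x = NULL, y = "Variance explained (%)") +
      theme_minimal()
  } else {
    stopifnot(length(dims) == 2, max(dims) <= ncol(object$scores))
    d <- pca_scores(object)
    nm <- colnames(object$scores)[dims]
    ggplot(d, aes(x = .data[[nm[1]]], y = .data[[nm[2]]])) +
      geom_point(alpha = 0.6) +
      labs(x = sprintf("%s (%.1f%%)", nm[1], 100 * object$prop_var[dims[1]]),
           y = sprintf("%s (%.1f%%)", nm[2], 100 * object$prop_var[dims[2]])) +
      theme_minimal()
  }
}

#' Bar plot of per-trait contributions to one component
#'
#' @param model A `pcb_pca`.
#' @param k Component index.
#' @return A ggplot object.
#' @export
plot_trait_contributions <- function(model, k = 1L) {
  d <- trait_contributions(model, k)
  d <- d[order(-d$contribution), ]
  d$trait <- factor(d$trait, levels = d$trait)
  ggplot(d, aes(x = .data$trait, y = .data$contribution)) +
    geom_col() +
    labs(x = NULL, y = sprintf("Contribution to PC%d (%%)", k)) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Per-component heritability with standard errors
#'
#' @param object A `pcb_pc_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcb_pc_evaluation <- function(object, ...) {
  d <- tidy(object)
  d$component <- factor(d$component, levels = d$component)
  ggplot(d, aes(x = .data$component, y = .data$h2)) +
    geom_point() +
    ggplot2::geom_errorbar(aes(ymin = .data$h2 - .data$h2_sd,
                               ymax = .data$h2 + .data$h2_sd), width = 0.2) +
    labs(x = NULL, y = expression(h^2)) +
    theme_minimal()
}

#' Restricted log-likelihood trace of a REML fit
#'
#' @param object A `pcb_animal_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcb_animal_model <- function(object, ...) {
  ggplot(object$trace, aes(x = .data$iter, y = .data$loglik)) +
    geom_line() +
    geom_point(size = 0.8) +
    labs(x = "Iteration", y = "Restricted log-likelihood") +
    theme_minimal()
}

#' Scatter comparison of two selection indices
#'
#' @param reference,candidate `pcb_index` tibbles over the same individuals.
#' @return A ggplot object.
#' @export
plot_index_comparison <- function(reference, candidate) {
  d <- dplyr::inner_join(
    dplyr::rename(as_tibble(reference), reference = "index"),
    dplyr::rename(as_tibble(candidate), candidate = "index"),
    by = "id", suffix = c("_ref", "_cand")
  )
  ggplot(d, aes(x = .data$reference, y = .data$candidate)) +
    geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    labs(x = "Reference index", y = "Candidate index") +
    theme_minimal()
}

#' Dendrogram of trait-loading clusters
#'
#' @param x A `pcb_loading_clusters`.
#' @param ... Passed to [plot.hclust].
#' @export
plot.pcb_loading_clusters <- function(x, ...) {
  plot(x$hclust, xlab = "", sub = "", main = "Ward clustering of loadings",
       ...)
}
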