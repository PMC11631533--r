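#' Tidy a fitted PCA
#'
#' @param x A `pcb_pca`.
#' @param ... Unused.
#' @return One row per component: `component`, `eigenvalue`, `prop_var`,
#'   `cum_var`.
#' @export
tidy.pcb_pca <- function(x, ...) {
  tibble(
    component = colnames(x$loadings),
    eigenvalue = x$eigenvalues,
    prop_var = x$prop_var,
    cum_var = cumsum(x$prop_var)
  )
}

#' @rdname tidy.pcb_pca
#' @export
glance.pcb_pca <- function(x, ...) {
  tibble(n = x$n, traits = length(x$traits),
         components = ncol(x$loadings),
         total_prop_var = sum(x$prop_var))
}

#' @rdname tidy.pcb_pca
#' @export
augment.pcb_pca <- function(x, ...) {
  pca_scores(x)
}

#' Tidy a univariate animal-model fit
#'
#' @param x A `pcb_animal_model`.
#' @param ... Unused.
#' @return Rows `sigma_a2`, `sigma_e2`, `h2` with `estimate` and `std.error`.
#' @export
tidy.pcb_animal_model <- function(x, ...) {
  tibble(
    term = c("sigma_a2", "sigma_e2", "h2"),
    estimate = c(x$vc$sigma_a2, x$vc$sigma_e2, x$vc$h2),
    std.error = c(x$vc$sd_a2, x$vc$sd_e2, x$vc$h2_sd)
  )
}

#' @rdname tidy.pcb_animal_model
#' @export
glance.pcb_animal_model <- function(x, ...) {
  tibble(logLik = x$loglik, iterations = x$iterations,
         converged = x$converged, boundary = x$boundary,
         algorithm = x$algorithm)
}

#' @rdname tidy.pcb_animal_model
#' @export
augment.pcb_animal_model <- function(x, ...) {
  if (is.null(x$ebv)) abort("fit was run with ebv = FALSE")
  x$ebv
}

#' Tidy a per-component evaluation
#'
#' @param x A `pcb_pc_evaluation`.
#' @param ... Unused.
#' @return The per-component variance-component table.
#' @export
tidy.pcb_pc_evaluation <- function(x, ...) {
  dplyr::rename(x$varcomp, component = "response")
}

#' @rdname tidy.pcb_pc_evaluation
#' @export
augment.pcb_pc_evaluation <- function(x, ...) {
  x$ebv
}

#' Tidy a bivariate REML fit
#'
#' @param x A `pcb_bivariate`.
#' @param ... Unused.
#' @return Long tibble of the genetic and residual (co)variance estimates.
#' @export
tidy.pcb_bivariate <- function(x, ...) {
  tr <- x$responses
  tibble(
    component = rep(c("genetic", "residual"), each = 3L),
    term = rep(c(paste0("var_", tr[1]), "cov", paste0("var_", tr[2])), 2L),
    estimate = c(x$G0[1, 1], x$G0[1, 2], x$G0[2, 2],
                 x$R0[1, 1], x$R0[1, 2], x$R0[2, 2])
  )
}

#' @rdname tidy.pcb_bivariate
#' @export
glance.pcb_bivariate <- function(x, ...) {
  tibble(logLik = x$loglik, iterations = x$iterations,
         converged = x$converged,
         genetic_correlation = x$genetic_correlation)
}

#' @rdname tidy.pcb_pc_evaluation
#' @export
glance.pcb_bpca <- function(x, ...) {
  tibble(sigma2 = x$sigma2, iterations = x$iterations,
         converged = x$converged, q = ncol(x$W))
}

#' Export a variance-component table as JSON
#'
#' @param vc Tibble of variance components (e.g. `tidy()` of an evaluation).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_varcomp_json <- function(vc, path) {
  jsonlite::write_json(vc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
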