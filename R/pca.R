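#' Read and write wide phenotype tables
#'
#' Phenotype files are delimited text (comma or tab, autodetected) with a
#' header, a first column `id` and one numeric column per trait; missing cells
#' are empty or `NA`.
#'
#' @param path File path.
#' @return A tibble with character `id` and numeric trait columns.
#' @export
read_phenotypes <- function(path) {
  raw <- read_delim_auto(path)
  names(raw)[1] <- "id"
  out <- suppressWarnings(dplyr::mutate(raw, dplyr::across(-"id", as.numeric)))
  as_tibble(out)
}

#' @rdname read_phenotypes
#' @param data Phenotype tibble (`id` + trait columns).
#' @export
write_phenotypes <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE, na = "")
  invisible(path)
}

# Validate a wide phenotype tibble and return its matrix form.
pheno_matrix <- function(data) {
  stopifnot(is.data.frame(data))
  if (!"id" %in% names(data)) {
    abort("phenotype data must contain an `id` column")
  }
  ids <- as.character(data$id)
  if (anyDuplicated(ids)) abort("duplicate individual ids in phenotype data")
  traits <- setdiff(names(data), "id")
  if (length(traits) < 1L) abort("phenotype data has no trait columns")
  if (nrow(data) < 2L) abort("phenotype data needs at least 2 individuals")
  Y <- as.matrix(data[traits])
  if (!is.numeric(Y)) abort("trait columns must be numeric")
  rownames(Y) <- ids
  list(Y = Y, ids = ids, traits = traits)
}

matrix_to_pheno <- function(Y) {
  dplyr::bind_cols(tibble(id = rownames(Y)), as_tibble(Y))
}

#' Filter traits and individuals by missingness
#'
#' Removes traits whose missing fraction exceeds `trait_threshold`, then
#' individuals whose missing fraction over the remaining traits exceeds
#' `individual_threshold` (strictly above, in that order). The defaults are the
#' thresholds used for multi-trial breeding data: drop traits with more than
#' 40% missing records, then individuals with more than 25% missing.
#'
#' @param data Phenotype tibble (`id` + trait columns).
#' @param trait_threshold,individual_threshold Fractions in (0, 1].
#' @return The filtered tibble, with a `removed` attribute (tibble of
#'   `what`, `name`, `missing_fraction`) retrievable via [removal_report()].
#' @export
filter_missing <- function(data, trait_threshold = 0.4,
                           individual_threshold = 0.25) {
  stopifnot(trait_threshold > 0, trait_threshold <= 1,
            individual_threshold > 0, individual_threshold <= 1)
  pm <- pheno_matrix(data)
  Y <- pm$Y
  tf <- colMeans(is.na(Y))
  drop_t <- tf > trait_threshold
  report <- tibble(what = character(), name = character(),
                   missing_fraction = numeric())
  if (any(drop_t)) {
    report <- dplyr::bind_rows(report, tibble(
      what = "trait", name = colnames(Y)[drop_t],
      missing_fraction = unname(tf[drop_t])
    ))
    Y <- Y[, !drop_t, drop = FALSE]
  }
  if (ncol(Y) == 0L) abort("all traits removed by the missingness filter")
  inf <- rowMeans(is.na(Y))
  drop_i <- inf > individual_threshold
  if (any(drop_i)) {
    report <- dplyr::bind_rows(report, tibble(
      what = "individual", name = rownames(Y)[drop_i],
      missing_fraction = unname(inf[drop_i])
    ))
    Y <- Y[!drop_i, , drop = FALSE]
  }
  if (nrow(Y) == 0L) abort("all individuals removed by the missingness filter")
  out <- matrix_to_pheno(Y)
  attr(out, "removed") <- report
  out
}

#' @rdname filter_missing
#' @param x A tibble returned by [filter_missing()].
#' @export
removal_report <- function(x) {
  attr(x, "removed") %||%
    tibble(what = character(), name = character(), missing_fraction = numeric())
}

#' Mean imputation of missing trait values
#'
#' Replaces every missing cell with the observed mean of its trait; observed
#' cells are untouched. This is the baseline imputation method; see
#' [fit_bpca()] for model-based imputation.
#'
#' @param data Phenotype tibble (`id` + trait columns).
#' @return A complete phenotype tibble.
#' @export
impute_mean <- function(data) {
  pm <- pheno_matrix(data)
  Y <- pm$Y
  allmiss <- colSums(!is.na(Y)) == 0L
  if (any(allmiss)) {
    abort(paste0("trait(s) with no observed values (filter first): ",
                 toString(colnames(Y)[allmiss])))
  }
  mu <- colMeans(Y, na.rm = TRUE)
  idx <- which(is.na(Y), arr.ind = TRUE)
  if (nrow(idx)) Y[idx] <- mu[idx[, 2]]
  matrix_to_pheno(Y)
}

#' SVD-based principal component analysis of a complete trait matrix
#'
#' Standard PCA via [stats::prcomp]. Eigenvalues are the sample variances of
#' the scores (denominator n - 1); loadings have orthonormal columns. The sign
#' of each component is fixed deterministically by making its
#' largest-magnitude loading positive, so repeated runs are bitwise identical.
#'
#' @param data Complete phenotype tibble (`id` + trait columns).
#' @param center Subtract trait means (default `TRUE`).
#' @param scale Divide by trait standard deviations (default `FALSE`, matching
#'   standard practice for pre-adjusted breeding phenotypes).
#' @param p Number of components to keep; `NULL` keeps all `min(n - 1, m)`.
#' @return An object of class `pcb_pca`: list with `loadings` (m x p),
#'   `eigenvalues`, `prop_var`, `center`, `scale`, `scores` (n x p), `ids`,
#'   `traits`.
#' @examples
#' y <- tibble::tibble(id = as.character(1:3), t1 = c(1, 3, 5), t2 = c(2, 6, 10))
#' fit <- fit_svd_pca(y)
#' fit$eigenvalues
#' @export
fit_svd_pca <- function(data, center = TRUE, scale = FALSE, p = NULL) {
  pm <- pheno_matrix(data)
  Y <- pm$Y
  if (anyNA(Y)) {
    abort("trait matrix contains missing values; impute first (impute_mean or fit_bpca)")
  }
  if (scale) {
    sds <- apply(Y, 2, sd)
    zv <- sds < .Machine$double.eps^0.5
    if (any(zv)) {
      abort(paste0("zero-variance trait(s) cannot be scaled: ",
                   toString(colnames(Y)[zv])))
    }
  }
  pc <- stats::prcomp(Y, center = center, scale. = scale)
  avail <- ncol(pc$rotation)
  if (is.null(p)) p <- avail
  if (p < 1L || p > avail) {
    abort(paste0("p must be between 1 and ", avail))
  }
  load <- pc$rotation[, seq_len(p), drop = FALSE]
  scores <- pc$x[, seq_len(p), drop = FALSE]
  # deterministic sign: largest-magnitude loading in each column positive
  for (k in seq_len(p)) {
    j <- which.max(abs(load[, k]))
    if (load[j, k] < 0) {
      load[, k] <- -load[, k]
      scores[, k] <- -scores[, k]
    }
  }
  eig <- pc$sdev[seq_len(p)]^2
  # total variance on the analysis scale = sum of all min(n-1, m) eigenvalues
  Ys <- sweep(Y, 2, if (center) colMeans(Y) else rep(0, ncol(Y)))
  if (scale) Ys <- sweep(Ys, 2, apply(Y, 2, sd), "/")
  total_var <- sum(Ys^2) / (nrow(Y) - 1)
  structure(list(
    loadings = load,
    eigenvalues = unname(eig),
    prop_var = unname(eig / total_var),
    center = if (center) colMeans(Y) else setNames(numeric(ncol(Y)), colnames(Y)),
    scale = if (scale) apply(Y, 2, sd) else setNames(rep(1, ncol(Y)), colnames(Y)),
    scores = scores,
    ids = pm$ids,
    traits = pm$traits,
    n = nrow(Y)
  ), class = "pcb_pca")
}

#' Project new phenotype records onto a fitted PCA
#'
#' Applies the fitted centering/scaling and rotation:
#' `scores = (Y - mu) diag(1/s) Lambda`.
#'
#' @param model A `pcb_pca`.
#' @param data Complete phenotype tibble with the model's traits.
#' @return Tibble `id` + one column per component.
#' @export
pca_transform <- function(model, data) {
  stopifnot(inherits(model, "pcb_pca"))
  pm <- pheno_matrix(data)
  if (!identical(pm$traits, model$traits)) {
    abort("trait columns do not match the fitted PCA model")
  }
  Ys <- sweep(sweep(pm$Y, 2, model$center), 2, model$scale, "/")
  sc <- Ys %*% model$loadings
  dplyr::bind_cols(tibble(id = pm$ids), as_tibble(sc))
}

#' Scores of a fitted PCA as a tibble
#' @param model A `pcb_pca`.
#' @return Tibble `id` + component columns.
#' @export
pca_scores <- function(model) {
  stopifnot(inherits(model, "pcb_pca"))
  dplyr::bind_cols(tibble(id = model$ids), as_tibble(model$scores))
}

#' Per-trait contribution to a principal component
#'
#' With orthonormal loadings, the percentage contribution of trait j to
#' component k is `100 * Lambda[j, k]^2`; contributions sum to 100.
#'
#' @param model A `pcb_pca`.
#' @param k Component index.
#' @return Tibble with columns `trait` and `contribution` (percent).
#' @export
trait_contributions <- function(model, k = 1L) {
  stopifnot(inherits(model, "pcb_pca"))
  if (k < 1L || k > ncol(model$loadings)) abort("component index out of range")
  tibble(trait = model$traits,
         contribution = 100 * unname(model$loadings[, k]^2))
}

#' Ward clustering of PCA loadings
#'
#' Hierarchically clusters traits by the Euclidean distance between their
#' loading rows (first `components` columns) using Ward's method
#' (`hclust(method = "ward.D2")`).
#'
#' @param model A `pcb_pca`.
#' @param components Number of leading components to use (default: all).
#' @param k Optional number of flat clusters to cut.
#' @return List of class `pcb_loading_clusters` with elements `hclust`,
#'   `distance`, and (when `k` is given) `clusters` (tibble `trait`, `cluster`).
#' @export
cluster_loadings <- function(model, components = NULL, k = NULL) {
  stopifnot(inherits(model, "pcb_pca"))
  p <- ncol(model$loadings)
  components <- components %||% p
  if (components < 1L || components > p) abort("components out of range")
  if (length(model$traits) < 2L) abort("need at least 2 traits to cluster")
  L <- model$loadings[, seq_len(components), drop = FALSE]
  rownames(L) <- model$traits
  d <- dist(L)
  hc <- hclust(d, method = "ward.D2")
  out <- list(hclust = hc, distance = d)
  if (!is.null(k)) {
    out$clusters <- tibble(trait = model$traits,
                           cluster = unname(cutree(hc, k = k)[model$traits]))
  }
  structure(out, class = "pcb_loading_clusters")
}

#' Mantel test between the loading geometries of two PCA models
#'
#' Computes trait-by-trait Euclidean distance matrices from the loading rows
#' of two models over the same traits and compares them with a Mantel test
#' (Pearson correlation of off-diagonal entries; one-sided permutation
#' p-value), as implemented in \pkg{vegan}.
#'
#' @param model_a,model_b Fitted `pcb_pca` models over identical trait sets.
#' @param permutations Number of permutations (default 999).
#' @param seed Optional integer seed for the permutation stream.
#' @return Tibble with columns `r`, `p_value`, `permutations`.
#' @export
mantel_loadings <- function(model_a, model_b, permutations = 999, seed = NULL) {
  stopifnot(inherits(model_a, "pcb_pca"), inherits(model_b, "pcb_pca"))
  if (!identical(model_a$traits, model_b$traits)) {
    abort("the two models must cover the same traits in the same order")
  }
  da <- dist(model_a$loadings)
  db <- dist(model_b$loadings)
  run <- function() vegan::mantel(da, db, permutations = permutations)
  mt <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  tibble(r = unname(mt$statistic), p_value = unname(mt$signif),
         permutations = permutations)
}

#' Serialize / restore a PCA model as a flat text bundle
#'
#' Writes `loadings.csv`, `eigenvalues.csv`, `centering.csv` and `scores.csv`
#' into a directory so the evaluation stage can reuse a fitted ordination.
#'
#' @param model A `pcb_pca`.
#' @param dir Directory (created if needed).
#' @return `dir` (write) or a `pcb_pca` (read).
#' @export
write_pca_model <- function(model, dir) {
  stopifnot(inherits(model, "pcb_pca"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pcs <- colnames(model$loadings)
  readr::write_csv(dplyr::bind_cols(tibble(trait = model$traits),
                                    as_tibble(model$loadings)),
                   file.path(dir, "loadings.csv"), progress = FALSE)
  readr::write_csv(tibble(pc = pcs, eigenvalue = model$eigenvalues,
                          prop_var = model$prop_var),
                   file.path(dir, "eigenvalues.csv"), progress = FALSE)
  readr::write_csv(tibble(trait = model$traits,
                          center = unname(model$center),
                          scale = unname(model$scale)),
                   file.path(dir, "centering.csv"), progress = FALSE)
  readr::write_csv(pca_scores(model), file.path(dir, "scores.csv"),
                   progress = FALSE)
  invisible(dir)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(dir) {
  ld <- readr::read_csv(file.path(dir, "loadings.csv"),
                        show_col_types = FALSE, progress = FALSE)
  ev <- readr::read_csv(file.path(dir, "eigenvalues.csv"),
                        show_col_types = FALSE, progress = FALSE)
  ct <- readr::read_csv(file.path(dir, "centering.csv"),
                        show_col_types = FALSE, progress = FALSE)
  sc <- readr::read_csv(file.path(dir, "scores.csv"),
                        show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(id = "c", .default = "d"))
  traits <- as.character(ld$trait)
  L <- as.matrix(ld[-1])
  rownames(L) <- traits
  S <- as.matrix(sc[-1])
  rownames(S) <- sc$id
  structure(list(
    loadings = L,
    eigenvalues = ev$eigenvalue,
    prop_var = ev$prop_var,
    center = setNames(ct$center, traits),
    scale = setNames(ct$scale, traits),
    scores = S,
    ids = as.character(sc$id),
    traits = traits,
    n = nrow(S)
  ), class = "pcb_pca")
}

#' @export
print.pcb_pca <- function(x, ...) {
  cat("# PCA:", length(x$traits), "traits,", x$n, "individuals,",
      ncol(x$loadings), "components\n")
  cat("  variance explained:",
      paste0(sprintf("%.1f%%", 100 * head(x$prop_var, 5)), collapse = ", "),
      if (length(x$prop_var) > 5) "..." else "", "\n")
  invisible(x)
}
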