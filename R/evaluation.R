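#' Univariate genetic evaluation of principal components
#'
#' Fits an independent univariate REML animal model to every principal
#' component score column, sharing one eigendecomposition of the phenotyped
#' block of A across components (the components are orthogonal, so each is a
#' separate response). A zero-variance component is skipped with a warning
#' and its breeding values zeroed.
#'
#' @param x A fitted `pcb_pca` (its scores are used) or a tibble with `id`
#'   and one column per component.
#' @param ped A `pcb_pedigree`.
#' @param algorithm REML algorithm, `"em"` or `"ai"`.
#' @param ... Passed to [reml_univariate()] (e.g. `max_iter`, `tol`).
#' @return Object of class `pcb_pc_evaluation`: `ebv` (tibble `id` + one
#'   column per component, all pedigree members), `varcomp` (per-component
#'   variance components, heritability and SEs), `fits` (the univariate
#'   fits).
#' @export
evaluate_pcs <- function(x, ped, algorithm = c("em", "ai"), ...) {
  algorithm <- match.arg(algorithm)
  scores <- if (inherits(x, "pcb_pca")) pca_scores(x) else as_tibble(x)
  if (!"id" %in% names(scores)) abort("scores must contain an `id` column")
  pcs <- setdiff(names(scores), "id")
  if (!length(pcs)) abort("no component columns found")
  A <- additive_relationship(ped)
  Ainv <- relationship_inverse(ped)
  idx <- match(as.character(scores$id), ped$id)
  if (anyNA(idx)) abort("individual(s) not in pedigree")
  eig <- eig_transform(ped, idx, A)
  fits <- vector("list", length(pcs))
  names(fits) <- pcs
  ebv <- tibble(id = ped$id)
  vcs <- list()
  for (pc in pcs) {
    if (sd(scores[[pc]]) < .Machine$double.eps^0.5) {
      warn(paste0("component `", pc, "` has zero variance; skipped"))
      ebv[[pc]] <- 0
      vcs[[pc]] <- tibble(response = pc, sigma_a2 = NA_real_,
                          sigma_e2 = NA_real_, sd_a2 = NA_real_,
                          sd_e2 = NA_real_, sd_p2 = NA_real_, h2 = NA_real_,
                          h2_sd = NA_real_, loglik = NA_real_,
                          iterations = 0L, converged = NA, boundary = NA)
      next
    }
    f <- reml_univariate(scores, pc, ped, algorithm = algorithm,
                         A = A, eig = eig, Ainv = Ainv, ...)
    fits[[pc]] <- f
    ebv[[pc]] <- f$ebv$ebv
    vcs[[pc]] <- f$vc
  }
  structure(list(
    ebv = ebv,
    varcomp = dplyr::bind_rows(vcs),
    fits = fits
  ), class = "pcb_pc_evaluation")
}

#' Back-transform component breeding values to the trait scale
#'
#' Maps an n x p matrix of per-component EBVs back to the original m traits
#' using the rotation of the PCA model that produced the scores:
#' `G_orig = G_ebv Lambda' diag(s) + mu`. When `p = m` the transformation is
#' exact and no information is lost.
#'
#' @param ebv Tibble with `id` and one column per component (e.g. the `ebv`
#'   element of [evaluate_pcs()]), or a bare matrix.
#' @param model The `pcb_pca` whose loadings/centering produced the scores.
#' @return Tibble `id` + one column per trait.
#' @export
back_transform <- function(ebv, model) {
  stopifnot(inherits(model, "pcb_pca"))
  if (is.matrix(ebv)) {
    ids <- rownames(ebv) %||% as.character(seq_len(nrow(ebv)))
    E <- ebv
  } else {
    stopifnot("id" %in% names(ebv))
    ids <- as.character(ebv$id)
    E <- as.matrix(ebv[setdiff(names(ebv), "id")])
  }
  p <- ncol(E)
  m <- length(model$traits)
  if (p > ncol(model$loadings)) {
    abort(paste0("EBV matrix has ", p, " components but the model only has ",
                 ncol(model$loadings)))
  }
  L <- model$loadings[, seq_len(p), drop = FALSE]
  G <- E %*% Matrix::t(L)
  G <- sweep(G, 2, model$scale, "*")
  G <- sweep(G, 2, model$center, "+")
  colnames(G) <- model$traits
  dplyr::bind_cols(tibble(id = ids), as_tibble(G))
}

#' Selection index over trait-scale breeding values
#'
#' Computes `index_i = sum_j w_j g_ij` from signed trait weights, after
#' normalising the weights so their absolute values sum to one. By default
#' each trait's EBVs are standardised (mean-centred, unit variance) before
#' weighting, so traits on incommensurate scales contribute as intended;
#' `standardize = FALSE` uses the EBVs as supplied. Ranks are descending in
#' the index with deterministic ties broken by id.
#'
#' @param ebv Tibble `id` + trait columns of breeding values (e.g. from
#'   [back_transform()]).
#' @param weights Named numeric vector of signed trait weights; names must
#'   resolve to columns of `ebv`.
#' @param standardize Standardise each trait column first (default `TRUE`).
#' @return Tibble of class `pcb_index` with columns `id`, `index`, `rank`
#'   (attributes: normalised `weights`, `standardize`).
#' @examples
#' g <- tibble::tibble(id = c("a", "b", "c"), h = c(1, 3, 2), d = c(2, 1, 3))
#' selection_index(g, c(h = 0.5, d = 0.5))
#' @export
selection_index <- function(ebv, weights, standardize = TRUE) {
  stopifnot("id" %in% names(ebv))
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    abort("weights must be a named vector of trait weights")
  }
  unknown <- setdiff(names(weights), names(ebv))
  if (length(unknown)) {
    abort(paste0("unknown trait(s) in weights: ", toString(unknown)))
  }
  if (all(weights == 0)) abort("weights must not all be zero")
  w <- weights / sum(abs(weights))
  G <- as.matrix(ebv[names(w)])
  if (standardize) {
    sds <- apply(G, 2, sd)
    if (any(sds == 0)) {
      abort(paste0("zero-variance EBV column(s): ",
                   toString(names(w)[sds == 0])))
    }
    G <- scale(G)
  }
  idx <- as.numeric(G %*% w)
  ids <- as.character(ebv$id)
  ord <- order(-idx, ids)
  rk <- integer(length(idx))
  rk[ord] <- seq_along(idx)
  out <- tibble(id = ids, index = idx, rank = rk)
  attr(out, "weights") <- w
  attr(out, "standardize") <- standardize
  class(out) <- c("pcb_index", class(tibble()))
  out
}

#' Contribution of individual components to a selection index
#'
#' With uncorrelated per-component EBVs, the variance share of component k in
#' the index built from trait weights `w` is
#' `share_k = (w' lambda_k)^2 Var(g_k)`, normalised to sum to one (the trait
#' scaling of the PCA model is folded into the weights).
#'
#' @param model A `pcb_pca`.
#' @param ebv_var Numeric vector of per-component EBV variances (length p).
#' @param weights Named trait weights, as in [selection_index()].
#' @return Tibble with columns `pc` and `share` (shares sum to 1).
#' @export
pc_index_contribution <- function(model, ebv_var, weights) {
  stopifnot(inherits(model, "pcb_pca"))
  p <- ncol(model$loadings)
  stopifnot(length(ebv_var) == p)
  unknown <- setdiff(names(weights), model$traits)
  if (length(unknown)) {
    abort(paste0("unknown trait(s) in weights: ", toString(unknown)))
  }
  w <- setNames(numeric(length(model$traits)), model$traits)
  w[names(weights)] <- weights / sum(abs(weights))
  ws <- w * model$scale
  proj <- as.numeric(crossprod(model$loadings, ws)) # w' lambda_k
  contrib <- proj^2 * ebv_var
  if (sum(contrib) <= 0) abort("all component contributions are zero")
  tibble(pc = colnames(model$loadings), share = contrib / sum(contrib))
}

#' Kendall's tau-b rank correlation with p-value
#'
#' Tie-corrected Kendall's tau. The two-sided p-value for the null of no
#' association is exact (by enumeration of the inversion-count distribution)
#' for n <= 10 without ties, and uses the tie-adjusted normal approximation
#' otherwise.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Tibble with columns `tau` and `p_value`.
#' @examples
#' kendall_tau(c(1, 2, 3, 4), c(1, 3, 2, 4)) # tau = 2/3
#' @export
kendall_tau <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3L) abort("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) abort("tau is undefined for a constant vector")
  S <- 0L
  C <- 0L
  D <- 0L
  for (i in seq_len(n - 1L)) {
    dx <- sign(x[(i + 1):n] - x[i])
    dy <- sign(y[(i + 1):n] - y[i])
    s <- dx * dy
    C <- C + sum(s > 0)
    D <- D + sum(s < 0)
  }
  S <- C - D
  tx <- table(x)
  ty <- table(y)
  n0 <- n * (n - 1) / 2
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))
  has_ties <- n1 > 0 || n2 > 0
  if (!has_ties && n <= 10L) {
    # exact null distribution of the inversion count by the standard recursion
    counts <- 1
    for (kk in 2:n) {
      L <- length(counts) + kk - 1L
      cs <- cumsum(counts)
      newc <- numeric(L)
      for (j in 0:(L - 1L)) {
        hi <- min(j, length(counts) - 1L)
        lo <- max(0L, j - (kk - 1L))
        newc[j + 1L] <- cs[hi + 1L] - if (lo > 0L) cs[lo] else 0
      }
      counts <- newc
    }
    probs <- counts / sum(counts)
    dobs <- D # inversions
    pl <- sum(probs[seq_len(dobs + 1L)])
    pr <- sum(probs[(dobs + 1L):length(probs)])
    p <- min(1, 2 * min(pl, pr))
  } else {
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    vS <- (v0 - vt - vu) / 18 + v1 + v2
    z <- S / sqrt(vS)
    p <- 2 * pnorm(-abs(z))
  }
  tibble(tau = tau, p_value = p)
}

#' Compare two selection-index rankings
#'
#' Reports the agreement between a reference ranking and a candidate ranking
#' over the same individuals: Pearson correlation of the index values over
#' the whole population, Kendall's tau over the reference-defined top-k
#' individuals' ranks in both lists, and the size of the intersection of the
#' two top-k sets.
#'
#' @param reference,candidate `pcb_index` tibbles (or tibbles with `id`,
#'   `index`, `rank`) over the same individual set.
#' @param k Top-list size (default 50).
#' @return One-row tibble of class `pcb_rank_comparison` with columns `tau`,
#'   `tau_p`, `r`, `r_p`, `overlap`, `k`.
#' @export
compare_rankings <- function(reference, candidate, k = 50L) {
  stopifnot(all(c("id", "index", "rank") %in% names(reference)),
            all(c("id", "index", "rank") %in% names(candidate)))
  if (!setequal(reference$id, candidate$id)) {
    only_ref <- setdiff(reference$id, candidate$id)
    only_cand <- setdiff(candidate$id, reference$id)
    abort(paste0("individual sets differ; only in reference: ",
                 toString(head(only_ref, 5)), "; only in candidate: ",
                 toString(head(only_cand, 5))))
  }
  n <- nrow(reference)
  if (k > n) abort(paste0("k = ", k, " exceeds population size ", n))
  if (k < 3) abort("k must be at least 3 (Kendall's tau needs 3 pairs)")
  cand <- candidate[match(reference$id, candidate$id), ]
  ct <- cor.test(reference$index, cand$index, method = "pearson")
  top_ref <- reference$id[reference$rank <= k]
  top_cand <- candidate$id[candidate$rank <= k]
  kt <- kendall_tau(reference$rank[match(top_ref, reference$id)],
                    cand$rank[match(top_ref, cand$id)])
  out <- tibble(
    tau = kt$tau, tau_p = kt$p_value,
    r = unname(ct$estimate), r_p = ct$p.value,
    overlap = length(intersect(top_ref, top_cand)), k = as.integer(k)
  )
  class(out) <- c("pcb_rank_comparison", class(tibble()))
  out
}

#' Write per-trait EBV files, an index file, or a comparison report
#'
#' `write_ebv()` writes one `id,ebv` file per trait/component column;
#' `write_index()`/`read_index()` round-trip `id,index,rank` tables;
#' `write_rank_comparison()` writes the comparison as JSON.
#'
#' @param ebv Tibble `id` + value columns.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"ebv_"`).
#' @return The paths written, invisibly.
#' @export
write_ebv <- function(ebv, dir, prefix = "ebv_") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cols <- setdiff(names(ebv), "id")
  paths <- vapply(cols, function(cl) {
    p <- file.path(dir, paste0(prefix, cl, ".csv"))
    readr::write_csv(setNames(ebv[c("id", cl)], c("id", "ebv")), p,
                     progress = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' @rdname write_ebv
#' @param index A `pcb_index`.
#' @param path Output file path.
#' @export
write_index <- function(index, path) {
  readr::write_csv(as_tibble(index), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_ebv
#' @export
read_index <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    id = "c", index = "d", rank = "i"), progress = FALSE)
  class(out) <- c("pcb_index", class(tibble()))
  out
}

#' @rdname write_ebv
#' @param comparison A `pcb_rank_comparison`.
#' @export
write_rank_comparison <- function(comparison, path) {
  jsonlite::write_json(as.list(as_tibble(comparison)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
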