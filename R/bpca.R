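#' Model-based (Bayesian) PCA with missing-value imputation
#'
#' Fits the probabilistic PCA model `y_i = W x_i + mu + eps`,
#' `x ~ N(0, I_q)`, `eps ~ N(0, sigma^2 I)`, by an iterative scheme that
#' alternates (i) factor-score regression of each individual on its observed
#' coordinates, (ii) prediction of missing cells as `y_miss = W_miss x`, and
#' (iii) principal-axis and residual-variance updates (an EM algorithm whose
#' E-step carries the full posterior score covariance). Missing cells are
#' imputed from the model; observed cells are preserved exactly.
#'
#' Convergence is declared when the relative Frobenius-norm change of the
#' imputed matrix falls below `threshold`. The axes are initialised from an
#' SVD of the mean-imputed matrix, so on complete data the fitted subspace
#' coincides with [fit_svd_pca()] and the algorithm stops immediately.
#'
#' @param data Phenotype tibble (`id` + trait columns), missing cells allowed.
#' @param q Number of principal axes; must satisfy `q < min(n, m)`.
#' @param max_steps Maximum number of iterations (default 10000).
#' @param threshold Relative-change convergence threshold (default 1e-6).
#' @param seed Optional integer seed (the default initialisation is
#'   deterministic; the seed is applied for reproducibility of any future
#'   stochastic variants).
#' @return Object of class `pcb_bpca`: list with `W` (m x q principal axes),
#'   `scores` (n x q posterior mean factor scores), `sigma2`, `mu`,
#'   `completed` (imputed phenotype tibble), `iterations`, `converged`.
#' @examples
#' y <- tibble::tibble(id = as.character(1:6),
#'                     t1 = c(1, 2, 3, 4, 5, 6),
#'                     t2 = c(2, 4, NA, 8, 10, 12))
#' fit <- fit_bpca(y, q = 1)
#' fit$completed
#' @export
fit_bpca <- function(data, q, max_steps = 10000L, threshold = 1e-6,
                     seed = NULL) {
  pm <- pheno_matrix(data)
  Y <- pm$Y
  n <- nrow(Y)
  m <- ncol(Y)
  if (q < 1L || q >= min(n, m)) abort("q must satisfy 1 <= q < min(n, m)")
  obs <- !is.na(Y)
  if (any(rowSums(obs) == 0L)) abort("individual(s) with no observed values")
  if (any(colSums(obs) == 0L)) abort("trait(s) with no observed values")

  # init from SVD of the mean-imputed matrix
  mu <- colMeans(Y, na.rm = TRUE)
  Yc <- Y
  idx_miss <- which(!obs, arr.ind = TRUE)
  if (nrow(idx_miss)) Yc[idx_miss] <- mu[idx_miss[, 2]]
  sv <- svd(sweep(Yc, 2, colMeans(Yc)), nu = 0, nv = min(n - 1L, m))
  eig <- sv$d^2 / (n - 1)
  W <- sv$v[, seq_len(q), drop = FALSE] %*% diag(sqrt(eig[seq_len(q)]), q)
  sigma2 <- if (length(eig) > q) max(mean(eig[-seq_len(q)]), 1e-12) else 1e-6
  mu <- colMeans(Yc)

  patterns <- apply(obs, 1, function(r) paste(which(r), collapse = ","))
  groups <- split(seq_len(n), patterns)

  Xbar <- matrix(0, n, q)
  converged <- FALSE
  iter <- 0L
  prev <- Yc
  for (iter in seq_len(max_steps)) {
    SumXX <- vector("list", length(groups))
    # E-step: posterior scores per missing pattern
    gi <- 0L
    Sig_by_row <- vector("list", n)
    for (g in groups) {
      o <- which(obs[g[1], ])
      Wo <- W[o, , drop = FALSE]
      M <- diag(sigma2, q) + crossprod(Wo)
      Minv <- chol2inv(chol(M))
      R <- sweep(Y[g, o, drop = FALSE], 2, mu[o])
      Xg <- R %*% Wo %*% Minv
      Xbar[g, ] <- Xg
      Sig <- sigma2 * Minv
      for (i in g) Sig_by_row[[i]] <- Sig
      # predict missing cells
      miss <- which(!obs[g[1], ])
      if (length(miss)) {
        Yc[g, miss] <- sweep(Xg %*% Matrix::t(W[miss, , drop = FALSE]), 2,
                             mu[miss], "+")
      }
    }
    # M-step: mean, axes (rowwise over traits), residual variance
    for (j in seq_len(m)) {
      oj <- which(obs[, j])
      mu[j] <- mean(Y[oj, j] - Xbar[oj, , drop = FALSE] %*% W[j, ])
    }
    for (j in seq_len(m)) {
      oj <- which(obs[, j])
      Sxx <- crossprod(Xbar[oj, , drop = FALSE]) +
        Reduce(`+`, Sig_by_row[oj])
      sxy <- crossprod(Xbar[oj, , drop = FALSE], Y[oj, j] - mu[j])
      W[j, ] <- solve(Sxx, sxy)
    }
    ss <- 0
    nobs_tot <- 0
    for (j in seq_len(m)) {
      oj <- which(obs[, j])
      r <- Y[oj, j] - mu[j] - Xbar[oj, , drop = FALSE] %*% W[j, ]
      tr <- vapply(oj, function(i) {
        drop(W[j, ] %*% Sig_by_row[[i]] %*% W[j, ])
      }, numeric(1))
      ss <- ss + sum(r^2) + sum(tr)
      nobs_tot <- nobs_tot + length(oj)
    }
    sigma2 <- max(ss / nobs_tot, 1e-12)
    # refresh imputations with updated parameters for the convergence check
    for (g in groups) {
      miss <- which(!obs[g[1], ])
      if (length(miss)) {
        Yc[g, miss] <- sweep(Xbar[g, , drop = FALSE] %*%
                               Matrix::t(W[miss, , drop = FALSE]),
                             2, mu[miss], "+")
      }
    }
    delta <- norm(Yc - prev, "F") / max(norm(prev, "F"), .Machine$double.eps)
    prev <- Yc
    if (delta < threshold) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(paste0("BPCA did not converge within ", max_steps, " steps"))
  }
  # deterministic sign convention, as in fit_svd_pca
  for (k in seq_len(q)) {
    j <- which.max(abs(W[, k]))
    if (W[j, k] < 0) {
      W[, k] <- -W[, k]
      Xbar[, k] <- -Xbar[, k]
    }
  }
  dimnames(W) <- list(pm$traits, paste0("PC", seq_len(q)))
  colnames(Xbar) <- paste0("PC", seq_len(q))
  rownames(Xbar) <- pm$ids
  structure(list(
    W = W,
    scores = Xbar,
    sigma2 = sigma2,
    mu = setNames(mu, pm$traits),
    completed = matrix_to_pheno(Yc),
    iterations = iter,
    converged = converged
  ), class = "pcb_bpca")
}

#' @export
print.pcb_bpca <- function(x, ...) {
  cat("# BPCA:", nrow(x$W), "traits,", nrow(x$scores), "individuals, q =",
      ncol(x$W), "\n")
  cat("  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  residual variance:", format(x$sigma2, digits = 4), "\n")
  invisible(x)
}
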