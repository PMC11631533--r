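#' @noRd
# Assemble the univariate design: response, fixed-effect matrix and the map
# from observations to pedigree positions. Rows with missing response drop.
build_design <- function(data, response, ped, fixed = NULL) {
  stopifnot(is.data.frame(data), inherits(ped, "pcb_pedigree"))
  if (!"id" %in% names(data)) abort("data must contain an `id` column")
  if (!response %in% names(data)) {
    abort(paste0("response column `", response, "` not found"))
  }
  keep <- !is.na(data[[response]])
  d <- data[keep, , drop = FALSE]
  if (nrow(d) < 2L) abort("fewer than 2 non-missing records")
  idx <- match(as.character(d$id), ped$id)
  if (anyNA(idx)) {
    abort(paste0("individual(s) not in pedigree: ",
                 toString(head(unique(d$id[is.na(idx)]), 5))))
  }
  X <- model.matrix(fixed %||% ~1, data = d)
  if (qr(X)$rank < ncol(X)) abort("fixed-effects design is rank deficient")
  list(y = as.numeric(d[[response]]), X = X, idx = idx,
       ids = as.character(d$id))
}

#' Solve Henderson's mixed-model equations (BLUP at known variances)
#'
#' Solves the animal-model equations
#' \deqn{\begin{pmatrix} X'X & X'Z \\ Z'X & Z'Z + \alpha A^{-1} \end{pmatrix}
#'   \begin{pmatrix}\hat b\\ \hat a\end{pmatrix} =
#'   \begin{pmatrix}X'y\\ Z'y\end{pmatrix}, \quad \alpha = \sigma^2_e/\sigma^2_a,}
#' giving BLUE fixed effects and BLUP breeding values for every pedigree
#' member (phenotyped or not). A near-singular coefficient matrix is repaired
#' by a logged diagonal ridge of `1e-8 * trace / ncol` rather than failing.
#'
#' @param data Tibble with columns `id`, the response, and any covariates.
#' @param response Name of the response column.
#' @param ped A `pcb_pedigree`.
#' @param sigma_a2,sigma_e2 Additive-genetic and residual variances (> 0).
#' @param fixed Fixed-effects formula over columns of `data`
#'   (default intercept only).
#' @param Ainv Optional precomputed sparse A-inverse from
#'   [relationship_inverse()].
#' @return List of class `pcb_blup`: `b` (named fixed-effect estimates) and
#'   `ebv` (tibble `id`, `ebv` over all pedigree members).
#' @export
solve_mme <- function(data, response, ped, sigma_a2, sigma_e2,
                      fixed = NULL, Ainv = NULL) {
  if (sigma_a2 <= 0) {
    abort("sigma_a2 must be > 0; for sigma_a2 = 0 fit ordinary least squares")
  }
  if (sigma_e2 <= 0) abort("sigma_e2 must be > 0")
  ds <- build_design(data, response, ped, fixed)
  Ainv <- Ainv %||% relationship_inverse(ped)
  sol <- solve_mme_core(ds$y, ds$X, ds$idx, Ainv, sigma_e2 / sigma_a2)
  structure(list(
    b = setNames(sol$b, colnames(ds$X)),
    ebv = tibble(id = ped$id, ebv = sol$a)
  ), class = "pcb_blup")
}

solve_mme_core <- function(y, X, idx, Ainv, alpha) {
  nq <- nrow(Ainv)
  p <- ncol(X)
  Z <- sparseMatrix(i = seq_along(y), j = idx, x = 1,
                    dims = c(length(y), nq))
  Xs <- Matrix::Matrix(X, sparse = TRUE)
  C <- rbind(
    cbind(Matrix::crossprod(Xs), Matrix::crossprod(Xs, Z)),
    cbind(Matrix::crossprod(Z, Xs), Matrix::crossprod(Z) + alpha * Ainv)
  )
  rhs <- c(as.numeric(crossprod(X, y)), as.numeric(Matrix::crossprod(Z, y)))
  sol <- tryCatch(
    as.numeric(Matrix::solve(C, rhs)),
    error = function(e) {
      ridge <- 1e-8 * sum(Matrix::diag(C)) / ncol(C)
      inform(paste0("near-singular mixed-model equations; adding ridge ",
                    format(ridge, digits = 3)))
      as.numeric(Matrix::solve(C + ridge * Diagonal(ncol(C)), rhs))
    }
  )
  list(b = sol[seq_len(p)], a = sol[-seq_len(p)])
}

# Restricted-likelihood machinery in the eigenbasis of A_obs (the submatrix of
# A over phenotyped individuals): V = sigma_a2 * D + sigma_e2 * I is diagonal,
# so every REML functional is O(n) given the one-off eigendecomposition.
eig_transform <- function(ped, idx, A = NULL) {
  A <- A %||% additive_relationship(ped)
  Ao <- A[idx, idx, drop = FALSE]
  e <- eigen(Ao, symmetric = TRUE)
  list(U = e$vectors, d = pmax(e$values, 0))
}

reml_functionals <- function(sa2, se2, d, yt, Xt) {
  v <- sa2 * d + se2
  w <- 1 / v
  Xw <- Xt * w
  XtVX <- crossprod(Xt, Xw)
  ch <- chol(XtVX)
  bhat <- backsolve(ch, forwardsolve(Matrix::t(ch), crossprod(Xw, yt)))
  r <- yt - Xt %*% bhat
  Py <- as.numeric(w * r)
  yPy <- sum(yt * Py)
  ll <- -0.5 * (sum(log(v)) + 2 * sum(log(diag(ch))) + yPy)
  Pz <- function(z) {
    as.numeric(w * z - Xw %*% backsolve(ch, forwardsolve(Matrix::t(ch),
                                                         crossprod(Xw, z))))
  }
  trP <- sum(w) - sum(chol2inv(ch) * crossprod(Xw))
  trPD <- sum(w * d) - sum(chol2inv(ch) * crossprod(Xt, (w^2 * d) * Xt))
  list(ll = ll, Py = Py, yPy = yPy, trP = trP, trPD = trPD, Pz = Pz,
       bhat = as.numeric(bhat))
}

ai_matrix <- function(fn, d) {
  ua <- d * fn$Py
  ue <- fn$Py
  Pua <- fn$Pz(ua)
  Pue <- fn$Pz(ue)
  matrix(0.5 * c(sum(ua * Pua), sum(ua * Pue), sum(ue * Pua), sum(ue * Pue)),
         2, 2)
}

#' Univariate REML animal model
#'
#' Estimates the additive-genetic and residual variance of a single trait
#' under the animal model `y = Xb + Za + e`, `a ~ N(0, A sigma_a2)`,
#' `e ~ N(0, I sigma_e2)`, by restricted maximum likelihood. Two algorithms
#' are available: `"em"` (expectation--maximisation; the reference algorithm,
#' whose restricted log-likelihood is non-decreasing at every step) and
#' `"ai"` (average information; a quadratically convergent accelerator that
#' falls back to an EM step whenever a proposed update would decrease the
#' restricted likelihood). Estimates are clamped at `1e-8 * var(y)` and
#' flagged as boundary solutions rather than being allowed to go negative.
#'
#' Standard errors of the components (and of their sum) come from the inverse
#' average-information matrix at the optimum; the heritability standard error
#' uses the Taylor approximation of [heritability_se()].
#'
#' @inheritParams solve_mme
#' @param algorithm `"em"` or `"ai"`.
#' @param start Optional `c(sigma_a2, sigma_e2)` starting values
#'   (default `var(y)/2` each).
#' @param max_iter Maximum iterations (default 1000).
#' @param tol Relative parameter-change tolerance (default 1e-8); convergence
#'   additionally requires a restricted log-likelihood change below
#'   `loglik_tol`.
#' @param loglik_tol Restricted log-likelihood change tolerance (default 1e-6).
#' @param A,eig Optional precomputed dense relationship matrix and/or its
#'   phenotyped-submatrix eigendecomposition (as returned internally), for
#'   sharing across traits.
#' @param ebv Compute BLUP breeding values for the whole pedigree at the
#'   converged components (default `TRUE`).
#' @return Object of class `pcb_animal_model`: `vc` (one-row variance
#'   component tibble with `sigma_a2`, `sigma_e2`, SDs, `h2`, `h2_sd`), `b`,
#'   `ebv` tibble, `loglik`, `trace` (per-iteration tibble), `converged`,
#'   `boundary`, `iterations`, `algorithm`.
#' @export
reml_univariate <- function(data, response, ped, fixed = NULL,
                            algorithm = c("em", "ai"), start = NULL,
                            max_iter = 1000L, tol = 1e-8, loglik_tol = 1e-6,
                            A = NULL, eig = NULL, Ainv = NULL, ebv = TRUE) {
  algorithm <- match.arg(algorithm)
  ds <- build_design(data, response, ped, fixed)
  if (length(ds$y) <= ncol(ds$X) + 1L) abort("too few records for REML")
  eig <- eig %||% eig_transform(ped, ds$idx, A)
  yt <- as.numeric(crossprod(eig$U, ds$y))
  Xt <- crossprod(eig$U, ds$X)
  d <- eig$d
  n <- length(yt)
  vy <- var(ds$y)
  lb <- 1e-8 * vy
  th <- start %||% c(vy / 2, vy / 2)
  stopifnot(length(th) == 2, all(th > 0))
  fn <- reml_functionals(th[1], th[2], d, yt, Xt)
  trace <- matrix(NA_real_, max_iter + 1L, 3L)
  trace[1L, ] <- c(th, fn$ll)
  converged <- FALSE
  stall <- 0L
  it <- 0L
  for (it in seq_len(max_iter)) {
    em_step <- c(
      th[1] + th[1]^2 / n * (sum(d * fn$Py^2) - fn$trPD),
      th[2] + th[2]^2 / n * (sum(fn$Py^2) - fn$trP)
    )
    if (algorithm == "em") {
      th_new <- pmax(em_step, lb)
      fn_new <- reml_functionals(th_new[1], th_new[2], d, yt, Xt)
    } else {
      s <- c(-0.5 * (fn$trPD - sum(d * fn$Py^2)),
             -0.5 * (fn$trP - sum(fn$Py^2)))
      AI <- ai_matrix(fn, d)
      step <- tryCatch(solve(AI, s), error = function(e) s / max(diag(AI), 1))
      th_new <- NULL
      for (h in 0:15) {
        cand <- pmax(th + step / 2^h, lb)
        fn_c <- tryCatch(reml_functionals(cand[1], cand[2], d, yt, Xt),
                         error = function(e) NULL)
        if (!is.null(fn_c) && is.finite(fn_c$ll) && fn_c$ll >= fn$ll - 1e-10) {
          th_new <- cand
          fn_new <- fn_c
          break
        }
      }
      if (is.null(th_new)) { # AI failed to improve; guaranteed EM fallback
        th_new <- pmax(em_step, lb)
        fn_new <- reml_functionals(th_new[1], th_new[2], d, yt, Xt)
      }
    }
    rel <- max(abs(th_new - th) / pmax(abs(th), lb))
    dll <- abs(fn_new$ll - fn$ll)
    th <- th_new
    fn <- fn_new
    trace[it + 1L, ] <- c(th, fn$ll)
    # stalled at the optimum (e.g. a boundary limit cycle at the numerical
    # noise floor): likelihood flat and parameters stable to 1e-6
    stall <- if (dll < 1e-8 && rel < 1e-5) stall + 1L else 0L
    if ((rel < tol && dll < loglik_tol) || stall >= 5L) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(paste0("REML (", algorithm, ") did not converge in ", max_iter,
                " iterations for `", response, "`"))
  }
  boundary <- any(th <= lb * (1 + 1e-12))
  AIopt <- ai_matrix(fn, d)
  covth <- tryCatch(solve(AIopt), error = function(e) matrix(NA_real_, 2, 2))
  if (any(!is.finite(covth)) || any(diag(covth) < 0)) {
    covth <- matrix(NA_real_, 2, 2)
  }
  sd_a2 <- sqrt(covth[1, 1])
  sd_e2 <- sqrt(covth[2, 2])
  sd_p2 <- sqrt(sum(covth))
  h2 <- th[1] / sum(th)
  h2_sd <- if (is.finite(sd_a2) && is.finite(sd_p2) && th[1] > 0) {
    heritability_se(th[1], sd_a2, sum(th), sd_p2)$h2_sd
  } else {
    NA_real_
  }
  vc <- tibble(
    response = response,
    sigma_a2 = th[1], sigma_e2 = th[2],
    sd_a2 = sd_a2, sd_e2 = sd_e2, sd_p2 = sd_p2,
    h2 = h2, h2_sd = h2_sd,
    loglik = fn$ll, iterations = it, converged = converged,
    boundary = boundary
  )
  blup <- NULL
  if (ebv) {
    Ainv <- Ainv %||% relationship_inverse(ped)
    sol <- solve_mme_core(ds$y, ds$X, ds$idx, Ainv, th[2] / th[1])
    blup <- list(b = setNames(sol$b, colnames(ds$X)),
                 ebv = tibble(id = ped$id, ebv = sol$a))
  }
  structure(list(
    vc = vc,
    b = blup$b,
    ebv = blup$ebv,
    loglik = fn$ll,
    trace = tibble(iter = 0:it,
                   sigma_a2 = trace[1:(it + 1L), 1],
                   sigma_e2 = trace[1:(it + 1L), 2],
                   loglik = trace[1:(it + 1L), 3]),
    converged = converged,
    boundary = boundary,
    iterations = it,
    algorithm = algorithm,
    response = response
  ), class = "pcb_animal_model")
}

#' Heritability and its Taylor-approximation standard deviation
#'
#' Narrow-sense heritability is the ratio `h2 = A / B` with `A = sigma_a2`
#' and `B = sigma_a2 + sigma_e2`. Assuming no covariation between A and B,
#' the delta-method (first-order Taylor) standard deviation of the ratio is
#' `SD(h2) = (A/B) * sqrt((SD(A)/A)^2 + (SD(B)/B)^2)`.
#'
#' @param a Additive variance A (> 0).
#' @param sd_a Standard deviation of A.
#' @param b Phenotypic variance B = A + E (> 0).
#' @param sd_b Standard deviation of B.
#' @return Tibble with columns `h2` and `h2_sd`.
#' @examples
#' heritability_se(1, 0.2, 4, 0.3)
#' @export
heritability_se <- function(a, sd_a, b, sd_b) {
  if (a <= 0 || b <= 0) abort("variances must be positive")
  tibble(h2 = a / b,
         h2_sd = (a / b) * sqrt((sd_a / a)^2 + (sd_b / b)^2))
}

#' @export
print.pcb_animal_model <- function(x, ...) {
  cat("# Univariate animal model (", x$algorithm, "-REML): `",
      x$response, "`\n", sep = "")
  cat(sprintf("  sigma_a2 = %.4g, sigma_e2 = %.4g, h2 = %.3f (SD %.3f)\n",
              x$vc$sigma_a2, x$vc$sigma_e2, x$vc$h2, x$vc$h2_sd))
  cat("  logLik:", format(x$loglik, digits = 8), "| iterations:",
      x$iterations, if (x$converged) "(converged)" else "(NOT converged)",
      if (x$boundary) "[boundary]" else "", "\n")
  invisible(x)
}
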