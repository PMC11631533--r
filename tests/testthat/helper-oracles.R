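# Independent oracles used across tests. These deliberately re-derive results
# by the most naive route available (double loops, exhaustive enumeration)
# so they stay independent of the package's vectorised implementations.

# tabular relationship matrix by the plain double-loop recursion
oracle_tabular_A <- function(id, sire, dam) {
  n <- length(id)
  si <- match(sire, id)
  di <- match(dam, id)
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      v <- 0
      if (!is.na(si[i])) v <- v + 0.5 * A[j, si[i]]
      if (!is.na(di[i])) v <- v + 0.5 * A[j, di[i]]
      A[i, j] <- A[j, i] <- v
    }
    A[i, i] <- 1
    if (!is.na(si[i]) && !is.na(di[i])) A[i, i] <- 1 + 0.5 * A[si[i], di[i]]
  }
  A
}

# random valid pedigree: founders plus random matings from earlier individuals
random_pedigree_df <- function(n, n_founders = max(2L, n %/% 5L)) {
  id <- sprintf("X%04d", seq_len(n))
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i > n_founders) {
      pair <- sample(i - 1L, 2L)
      sire[i] <- id[pair[1]]
      dam[i] <- id[pair[2]]
    }
  }
  data.frame(id = id, sire = sire, dam = dam)
}

# naive O(n^3) Ward agglomeration over rows of a matrix; returns merge heights
# in merge order, using the cluster-size-weighted centroid distance
oracle_ward_heights <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), function(i) i)
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(clusters)) {
      for (b in seq_len(a - 1L)) {
        ca <- colMeans(X[clusters[[a]], , drop = FALSE])
        cb <- colMeans(X[clusters[[b]], , drop = FALSE])
        na <- length(clusters[[a]])
        nb <- length(clusters[[b]])
        d <- sqrt(2 * na * nb / (na + nb)) * sqrt(sum((ca - cb)^2))
        if (d < best[1]) best <- c(d, a, b)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters[[length(clusters) + 1L]] <- merged
  }
  heights
}

# brute-force Kendall tau over all pairs, and exact permutation p-value by
# enumerating every permutation of y (tie-free inputs, small n)
oracle_kendall <- function(x, y) {
  n <- length(x)
  num <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      num <- num + sign(x[j] - x[i]) * sign(y[j] - y[i])
    }
  }
  tau <- num / choose(n, 2)
  perms <- all_permutations(n)
  taus <- apply(perms, 1, function(p) {
    s <- 0L
    yp <- y[p]
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        s <- s + sign(x[j] - x[i]) * sign(yp[j] - yp[i])
      }
    }
    s / choose(n, 2)
  })
  p <- mean(abs(taus) >= abs(tau) - 1e-12)
  list(tau = tau, p = p)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    out <- rbind(out, cbind(k, sub + (sub >= k)))
  }
  unname(out)
}

# dense-V restricted log-likelihood of the complete-record multitrait model,
# computed the slow direct way (Kronecker V), for joint-REML oracle fits
oracle_multitrait_ll <- function(G0, R0, Aobs, Y) {
  if (any(!is.finite(G0)) || any(!is.finite(R0))) return(-Inf)
  n <- nrow(Y)
  m <- ncol(Y)
  V <- kronecker(G0, Aobs) + kronecker(R0, diag(n))
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  y <- as.numeric(Y)
  X <- kronecker(diag(m), rep(1, n))
  ViX <- backsolve(ch, forwardsolve(t(ch), X))
  Viy <- backsolve(ch, forwardsolve(t(ch), y))
  XtVX <- crossprod(X, ViX)
  ch2 <- chol(XtVX)
  bhat <- backsolve(ch2, forwardsolve(t(ch2), crossprod(X, Viy)))
  r <- y - X %*% bhat
  Vir <- backsolve(ch, forwardsolve(t(ch), r))
  -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(ch2))) + sum(r * Vir))
}

# log-Cholesky <-> symmetric matrix helpers for oracle REML fits
oracle_theta_to_cov <- function(th, m) {
  L <- matrix(0, m, m)
  L[lower.tri(L, diag = TRUE)] <- th
  diag(L) <- exp(diag(L))
  L %*% t(L)
}

oracle_cov_to_theta <- function(S) {
  L <- t(chol(S))
  diag(L) <- log(diag(L))
  L[lower.tri(L, diag = TRUE)]
}

# small complete-data simulation used by several LMM tests
sim_univariate <- function(ped, sigma_a2, sigma_e2, seed) {
  cfg <- pcblup::sim_config(
    founders = sum(is.na(ped$sire) & is.na(ped$dam)), generations = 1L,
    families_per_generation = 1L, offspring_per_family = 1L,
    mu = c(y = 0), G0 = matrix(sigma_a2, 1, 1), R0 = matrix(sigma_e2, 1, 1),
    seed = seed
  )
  pcblup::simulate_traits(ped, cfg)
}
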