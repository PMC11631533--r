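small_sim <- function(m, seed, n_founders = 40, fams = 20, offs = 8,
                      G0 = NULL, R0 = NULL, rho_g = 0.4, rho_r = 0.2,
                      h2 = 0.4) {
  if (is.null(G0)) {
    Cg <- matrix(rho_g, m, m); diag(Cg) <- 1
    Cr <- matrix(rho_r, m, m); diag(Cr) <- 1
    G0 <- Cg * h2
    R0 <- Cr * (1 - h2)
  }
  cfg <- sim_config(founders = n_founders, generations = 2,
                    families_per_generation = fams,
                    offspring_per_family = offs,
                    mu = setNames(rep(10, m), paste0("t", seq_len(m))),
                    G0 = G0, R0 = R0, seed = seed)
  ped <- simulate_pedigree(cfg)
  sim <- simulate_traits(ped, cfg)
  list(ped = ped, d = sim$phenotypes, cfg = cfg, bv = sim$true_bv)
}

test_that("bivariate REML recovers a near-unit genetic correlation in the low-noise limit", {
  # the same genetic signal with two small independent residuals
  s <- small_sim(1, seed = 31)
  cfg <- s$cfg
  set.seed(31)
  bv <- simulate_traits(s$ped, cfg)$true_bv$t1
  d <- tibble::tibble(id = s$ped$id,
                      a = 10 + bv + rnorm(nrow(s$ped), 0, 0.05),
                      b = 20 + bv + rnorm(nrow(s$ped), 0, 0.05))
  f <- reml_bivariate(d, c("a", "b"), s$ped)
  expect_gt(f$genetic_correlation, 0.98)
})

test_that("bivariate REML is unbiased for a zero genetic correlation", {
  reps <- 20
  est <- numeric(reps)
  for (r in seq_len(reps)) {
    s <- small_sim(2, seed = 300 + r, n_founders = 100, fams = 50, offs = 8,
                   G0 = diag(c(0.4, 0.4)), R0 = diag(c(0.6, 0.6)))
    f <- reml_bivariate(s$d, c("t1", "t2"), s$ped)
    est[r] <- f$genetic_correlation
  }
  expect_lt(abs(mean(est)), 0.1)
})

test_that("identical trait pairs are rejected as degenerate", {
  s <- small_sim(1, seed = 33)
  d <- tibble::tibble(id = s$d$id, t1 = s$d$t1, t2 = s$d$t1)
  expect_error(reml_bivariate(d, c("t1", "t2"), s$ped), "degenerate")
})

test_that("bivariate REML handles per-trait missing records", {
  s <- small_sim(2, seed = 35, n_founders = 20, fams = 12, offs = 6)
  d <- s$d
  set.seed(35)
  d$t1[sample(nrow(d), 15)] <- NA
  d$t2[sample(nrow(d), 15)] <- NA
  f <- suppressWarnings(reml_bivariate(d, c("t1", "t2"), s$ped))
  expect_true(is.finite(f$loglik))
  expect_true(all(eigen(f$G0, only.values = TRUE)$values > -1e-8))
  # complete-path and missing-path likelihoods agree on complete data
  fc <- reml_bivariate(s$d, c("t1", "t2"), s$ped)
  dd <- s$d
  attr(dd, "force_missing") <- TRUE
  ll_dense <- pcblup:::bivar_ll_missing(
    fc$G0, fc$R0, additive_relationship(s$ped),
    tibble::tibble(i = rep(match(s$d$id, s$ped$id), 2),
                   t = rep(1:2, each = nrow(s$d))),
    c(s$d$t1, s$d$t2),
    kronecker(diag(2), rep(1, nrow(s$d)))
  )
  expect_equal(ll_dense, fc$loglik, tolerance = 1e-6)
})

test_that("covariance assembly fills all pairs, errors on gaps, and bends", {
  s <- small_sim(3, seed = 37)
  uni <- lapply(paste0("t", 1:3), function(tr) {
    reml_univariate(s$d, tr, s$ped, algorithm = "ai", ebv = FALSE)
  })
  pairs <- utils::combn(paste0("t", 1:3), 2, simplify = FALSE)
  biv <- lapply(pairs, function(pr) reml_bivariate(s$d, pr, s$ped))
  asm <- assemble_covariance(uni, biv)
  expect_equal(unname(diag(asm$G0)),
               vapply(uni, function(f) f$vc$sigma_a2, numeric(1)))
  expect_equal(asm$G0[1, 2], biv[[1]]$G0[1, 2])
  expect_error(assemble_covariance(uni, biv[-2]), "missing pairwise")

  # m = 2: matrices equal the single bivariate fit off-diagonal
  asm2 <- assemble_covariance(uni[1:2], biv[1])
  expect_equal(asm2$G0[1, 2], biv[[1]]$G0[1, 2])

  # hand-built non-PSD input is bent to PSD with diagonals nearly preserved
  bad_uni <- lapply(1:3, function(j) {
    f <- uni[[j]]
    f$vc$sigma_a2 <- 1
    f$vc$sigma_e2 <- 1
    f
  })
  bad_biv <- lapply(seq_along(pairs), function(k) {
    f <- biv[[k]]
    f$G0 <- matrix(c(1, 0.99, 0.99, 1), 2, 2)
    f$R0 <- diag(2)
    f$responses <- pairs[[k]]
    f
  })
  # pairwise correlations (0.99, 0.99, 0.99) are jointly fine; force non-PSD
  bad_biv[[3]]$G0[1, 2] <- bad_biv[[3]]$G0[2, 1] <- -0.9
  expect_message(asm_bad <- assemble_covariance(bad_uni, bad_biv), "bending")
  ev <- eigen(asm_bad$G0, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_lt(max(abs(diag(asm_bad$G0) - 1)), 0.05)
})

test_that("fit_multitrait reduces to univariate BLUP for m = 1 and diagonal components", {
  s <- small_sim(3, seed = 39)
  # m = 1 delegates to the same Henderson solve
  f1 <- fit_multitrait(s$d[c("id", "t1")], s$ped,
                       G0 = matrix(0.4, 1, 1), R0 = matrix(0.6, 1, 1))
  u1 <- solve_mme(s$d, "t1", s$ped, 0.4, 0.6)
  expect_identical(f1$ebv$t1, u1$ebv$ebv)

  # diagonal G0, R0 decouple into trait-by-trait univariate BLUP
  G0 <- diag(c(0.3, 0.5, 0.2))
  R0 <- diag(c(0.7, 0.5, 0.8))
  mt <- fit_multitrait(s$d, s$ped, G0, R0)
  for (j in 1:3) {
    uj <- solve_mme(s$d, paste0("t", j), s$ped, G0[j, j], R0[j, j])
    expect_equal(mt$ebv[[paste0("t", j)]], uj$ebv$ebv, tolerance = 1e-8)
  }
})

test_that("proportional covariances make multitrait BLUP equal back-transformed per-PC BLUP", {
  s <- small_sim(4, seed = 41)
  Y <- as.matrix(s$d[-1])
  P <- cov(Y)
  gam <- 0.35
  pc <- fit_svd_pca(s$d)
  sc <- pca_scores(pc)
  E <- vapply(seq_len(4), function(k) {
    solve_mme(sc, paste0("PC", k), s$ped,
              gam * pc$eigenvalues[k], (1 - gam) * pc$eigenvalues[k])$ebv$ebv
  }, numeric(nrow(s$ped)))
  colnames(E) <- paste0("PC", 1:4)
  rownames(E) <- s$ped$id
  bt <- back_transform(E, pc)
  mt <- fit_multitrait(s$d, s$ped, gam * P, (1 - gam) * P)
  # multitrait EBVs are deviations; back-transform re-adds the trait means
  dev <- sweep(as.matrix(bt[-1]), 2, pc$center)
  expect_lt(max(abs(dev - as.matrix(mt$ebv[-1]))), 1e-6)
})

test_that("staged evaluation schedules the right fits and matches joint REML", {
  expect_equal(sum(staged_schedule(paste0("t", 1:26))$stage == "b"), 325L)
  expect_equal(sum(staged_schedule(paste0("t", 1:15))$stage == "b"), 105L)
  expect_equal(sum(staged_schedule(c("a", "b"))$stage == "b"), 1L)

  s <- small_sim(3, seed = 43, n_founders = 30, fams = 20, offs = 8)
  st <- staged_multitrait_evaluation(s$d, s$ped, algorithm = "ai")
  expect_equal(nrow(st$report), 3 + 3 + 1)
  expect_true(all(st$report$converged))

  # joint-REML oracle: maximise the dense restricted likelihood directly
  idx <- match(s$d$id, s$ped$id)
  Aobs <- additive_relationship(s$ped)[idx, idx]
  Y <- as.matrix(s$d[-1])
  m <- ncol(Y)
  nll <- function(th) {
    -oracle_multitrait_ll(oracle_theta_to_cov(th[1:6], m),
                          oracle_theta_to_cov(th[7:12], m), Aobs, Y)
  }
  vy <- apply(Y, 2, var)
  th0 <- c(oracle_cov_to_theta(diag(vy / 2)), oracle_cov_to_theta(diag(vy / 2)))
  opt <- optim(th0, nll, method = "BFGS", control = list(maxit = 400))
  G0j <- oracle_theta_to_cov(opt$par[1:6], m)
  R0j <- oracle_theta_to_cov(opt$par[7:12], m)
  joint <- fit_multitrait(s$d, s$ped, G0j, R0j)
  for (j in seq_len(m)) {
    expect_gt(cor(st$fit$ebv[[j + 1]], joint$ebv[[j + 1]]), 0.99)
  }
  # staged restricted likelihood cannot beat the joint optimum by more than noise
  expect_lte(pcblup:::multitrait_ll_complete(st$G0, st$R0, s$ped, idx, Y),
             -opt$value + 1e-4)
})

test_that("multitrait BLUP accepts per-cell missingness", {
  s <- small_sim(3, seed = 45, n_founders = 20, fams = 12, offs = 6)
  d <- s$d
  set.seed(45)
  for (j in 2:4) d[[j]][sample(nrow(d), 10)] <- NA
  G0 <- diag(3) * 0.4 + 0.1
  R0 <- diag(3) * 0.6 + 0.05
  mt <- fit_multitrait(d, s$ped, G0, R0)
  expect_equal(nrow(mt$ebv), nrow(s$ped))
  expect_true(all(is.finite(as.matrix(mt$ebv[-1]))))
  # with diagonal components, missing rows simply drop from each trait's solve
  mt2 <- fit_multitrait(d, s$ped, diag(c(0.4, 0.3, 0.5)),
                        diag(c(0.6, 0.7, 0.5)))
  u <- solve_mme(d[!is.na(d$t2), c("id", "t2")], "t2", s$ped, 0.3, 0.7)
  expect_equal(mt2$ebv$t2, u$ebv$ebv, tolerance = 1e-8)
})
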