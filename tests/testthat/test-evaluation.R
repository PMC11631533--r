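eval_sim <- function(m = 3, seed = 51, h2 = 0.4, n_founders = 40, fams = 25) {
  Cg <- matrix(0.3, m, m); diag(Cg) <- 1
  cfg <- sim_config(founders = n_founders, generations = 2,
                    families_per_generation = fams, offspring_per_family = 8,
                    mu = setNames(rep(10, m), paste0("t", seq_len(m))),
                    G0 = Cg * h2, R0 = diag(m) * (1 - h2), seed = seed)
  ped <- simulate_pedigree(cfg)
  sim <- simulate_traits(ped, cfg)
  list(ped = ped, d = sim$phenotypes, bv = sim$true_bv, cfg = cfg)
}

test_that("evaluate_pcs with one component equals a single univariate fit", {
  s <- eval_sim()
  pc <- fit_svd_pca(s$d, p = 1)
  ev <- evaluate_pcs(pc, s$ped, algorithm = "ai")
  direct <- reml_univariate(pca_scores(pc), "PC1", s$ped, algorithm = "ai")
  expect_equal(ev$ebv$PC1, direct$ebv$ebv, tolerance = 1e-10)
  expect_equal(ev$varcomp$h2, direct$vc$h2, tolerance = 1e-10)
})

test_that("per-PC heritabilities recover simulated values on the component scale", {
  # traits simulated independently (diagonal G0, R0) act as their own PCs
  h2_true <- c(0.15, 0.45)
  reps <- 10
  est <- matrix(0, reps, 2)
  for (r in seq_len(reps)) {
    cfg <- sim_config(founders = 60, generations = 2,
                      families_per_generation = 40, offspring_per_family = 8,
                      mu = c(pc1 = 0, pc2 = 0),
                      G0 = diag(h2_true), R0 = diag(1 - h2_true),
                      seed = 700 + r)
    ped <- simulate_pedigree(cfg)
    sim <- simulate_traits(ped, cfg)
    ev <- evaluate_pcs(sim$phenotypes, ped, algorithm = "ai")
    est[r, ] <- ev$varcomp$h2
  }
  expect_lt(max(abs(colMeans(est) - h2_true)), 0.1)
})

test_that("a constant component column is skipped with zero EBVs", {
  s <- eval_sim()
  sc <- pca_scores(fit_svd_pca(s$d, p = 2))
  sc$PC2 <- 0
  expect_warning(ev <- evaluate_pcs(sc, s$ped, algorithm = "ai"),
                 "zero variance")
  expect_true(all(ev$ebv$PC2 == 0))
  expect_true(is.na(ev$varcomp$h2[2]))
})

test_that("back-transformation is the exact inverse at full rank", {
  set.seed(61)
  for (sc in c(FALSE, TRUE)) {
    d <- dplyr::bind_cols(tibble::tibble(id = as.character(1:30)),
                          tibble::as_tibble(matrix(rnorm(150), 30, 5),
                                            .name_repair = ~paste0("t", 1:5)))
    fit <- fit_svd_pca(d, scale = sc)
    for (r in 1:10) {
      Z <- matrix(rnorm(150), 30, 5)
      zd <- d
      zd[-1] <- Z
      rt <- back_transform(pca_transform(fit, zd), fit)
      expect_lt(max(abs(as.matrix(rt[-1]) - Z)), 1e-10)
    }
    # zero component EBVs map every row to the trait means
    zero <- matrix(0, 4, 5, dimnames = list(letters[1:4], NULL))
    bt0 <- back_transform(zero, fit)
    expect_equal(unname(as.matrix(bt0[-1])),
                 matrix(fit$center, 4, 5, byrow = TRUE) *
                   matrix(1, 4, 5), tolerance = 1e-12)
  }
  # random reduced-rank case equals a direct matrix product
  fit <- fit_svd_pca(dplyr::bind_cols(
    tibble::tibble(id = as.character(1:12)),
    tibble::as_tibble(matrix(rnorm(36), 12, 3), .name_repair = ~paste0("t", 1:3))
  ))
  E <- matrix(rnorm(10), 5, 2)
  bt <- back_transform(E, fit)
  direct <- E %*% t(fit$loadings[, 1:2]) +
    matrix(fit$center, 5, 3, byrow = TRUE)
  expect_equal(unname(as.matrix(bt[-1])), unname(direct), tolerance = 1e-12)
  expect_error(back_transform(matrix(0, 2, 7), fit), "components")
})

test_that("selection indices weight, standardize and rank deterministically", {
  g <- tibble::tibble(id = c("d", "c", "b", "a"),
                      h = c(4, 3, 2, 1), bd = c(1, 3, 2, 4))
  # single trait: ranking equals the EBV ranking
  i1 <- selection_index(g, c(h = 1))
  expect_equal(i1$rank, c(1, 2, 3, 4))
  # equal weights on identical columns is proportional to either
  g2 <- tibble::tibble(id = g$id, a = g$h, b = g$h)
  i2 <- selection_index(g2, c(a = 0.5, b = 0.5))
  expect_equal(cor(i2$index, g$h), 1)
  # signed toy weights against hand-computed sums (raw mode)
  g3 <- tibble::tibble(id = c("w", "x", "y", "z"),
                       p = c(2, 1, 0, -1), q = c(1, 1, 2, 0),
                       r = c(0, 2, 1, 1))
  i3 <- selection_index(g3, c(p = 0.5, q = 0.25, r = -0.25),
                        standardize = FALSE)
  expect_equal(i3$index, 0.5 * g3$p + 0.25 * g3$q - 0.25 * g3$r)
  # weight normalisation: scaling all weights leaves the index unchanged
  i4 <- selection_index(g3, c(p = 2, q = 1, r = -1), standardize = FALSE)
  expect_equal(i4$index, i3$index)
  # shift invariance of ranks
  g5 <- g3
  g5[-1] <- g5[-1] + 100
  expect_equal(selection_index(g5, c(p = 0.5, q = 0.25, r = -0.25))$rank,
               selection_index(g3, c(p = 0.5, q = 0.25, r = -0.25))$rank)
  # deterministic tie-break by id
  gt <- tibble::tibble(id = c("b", "a"), t = c(1, 1))
  expect_equal(selection_index(gt, c(t = 1), standardize = FALSE)$rank,
               c(2, 1))
  expect_error(selection_index(g, c(nope = 1)), "unknown trait")
  expect_error(selection_index(g, c(h = 0, bd = 0)), "not all")
})

test_that("per-PC index contributions follow the quadratic projection formula", {
  set.seed(71)
  d <- dplyr::bind_cols(tibble::tibble(id = as.character(1:20)),
                        tibble::as_tibble(matrix(rnorm(60), 20, 3),
                                          .name_repair = ~paste0("t", 1:3)))
  fit <- fit_svd_pca(d)
  # weights aligned with loading column 1: everything on PC1
  w1 <- setNames(fit$loadings[, 1], fit$traits)
  c1 <- pc_index_contribution(fit, rep(1, 3), w1)
  expect_equal(c1$share, c(1, 0, 0), tolerance = 1e-10)
  # symmetric two-component toy: equal shares
  m <- fit
  m$loadings <- cbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  colnames(m$loadings) <- paste0("PC", 1:3)
  cs <- pc_index_contribution(m, c(2, 2, 0), c(t1 = 0.5, t2 = 0.5))
  expect_equal(cs$share, c(0.5, 0.5, 0), tolerance = 1e-12)
  # 3-component toy equals the direct formula
  ev <- c(1.3, 0.8, 0.1)
  w <- c(t1 = 0.5, t2 = 0.3, t3 = -0.2)
  cc <- pc_index_contribution(fit, ev, w)
  wn <- (w / sum(abs(w))) * fit$scale
  direct <- as.numeric(crossprod(fit$loadings, wn))^2 * ev
  expect_equal(cc$share, direct / sum(direct), tolerance = 1e-12)
})

test_that("Kendall tau matches brute force and exact enumeration for n <= 6", {
  expect_equal(kendall_tau(1:4, c(1, 3, 2, 4))$tau, 2 / 3, tolerance = 1e-12)
  expect_equal(kendall_tau(1:5, 1:5)$tau, 1)
  expect_equal(kendall_tau(1:5, 5:1)$tau, -1)
  set.seed(81)
  for (n in 3:6) {
    for (rep in 1:8) {
      x <- sample(n)
      y <- sample(n)
      got <- kendall_tau(x, y)
      want <- oracle_kendall(x, y)
      expect_equal(got$tau, want$tau, tolerance = 1e-12)
      expect_equal(got$p_value, want$p, tolerance = 1e-12)
      ct <- suppressWarnings(cor.test(x, y, method = "kendall"))
      expect_equal(got$tau, unname(ct$estimate), tolerance = 1e-12)
      expect_equal(got$p_value, ct$p.value, tolerance = 1e-12)
    }
  }
  # ties: tie-corrected tau-b against cor.test
  x <- c(1, 2, 2, 3, 4, 5, 5, 6)
  y <- c(2, 1, 3, 3, 5, 4, 6, 6)
  ct <- suppressWarnings(cor.test(x, y, method = "kendall"))
  got <- kendall_tau(x, y)
  expect_equal(got$tau, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(got$p_value, ct$p.value, tolerance = 1e-10)
  expect_error(kendall_tau(rep(1, 5), 1:5), "constant")
})

test_that("rank comparisons report tau, r and top-k overlap", {
  set.seed(91)
  n <- 40
  g <- tibble::tibble(id = sprintf("i%02d", 1:n), a = rnorm(n))
  ref <- selection_index(g, c(a = 1))
  self <- compare_rankings(ref, ref, k = 10)
  expect_equal(self$tau, 1)
  expect_equal(self$r, 1)
  expect_equal(self$overlap, 10L)

  rev_idx <- selection_index(dplyr::mutate(g, a = -a), c(a = 1))
  opp <- compare_rankings(ref, rev_idx, k = 10)
  expect_equal(opp$overlap, 0L)
  expect_equal(opp$r, -1)

  # 10-individual toy pair against hand computation
  g2 <- tibble::tibble(id = letters[1:10], s = c(10:1))
  cand <- tibble::tibble(id = letters[1:10],
                         s = c(9, 10, 7, 8, 5, 6, 3, 4, 1, 2))
  ir <- selection_index(g2, c(s = 1))
  ic <- selection_index(cand, c(s = 1))
  cmp <- compare_rankings(ir, ic, k = 5)
  top <- ir$id[ir$rank <= 5]
  hand <- oracle_kendall(ir$rank[match(top, ir$id)],
                         ic$rank[match(top, ic$id)])
  expect_equal(cmp$tau, hand$tau, tolerance = 1e-12)
  expect_equal(cmp$overlap,
               length(intersect(top, ic$id[ic$rank <= 5])))
  expect_error(compare_rankings(ir, ic, k = 50), "exceeds")
  expect_error(compare_rankings(ir, ic[1:5, ]), "differ")
})

test_that("index and EBV files round-trip and the comparison serialises", {
  g <- tibble::tibble(id = c("a", "b", "c"), h = c(1, 3, 2), d = c(2, 1, 3))
  idx <- selection_index(g, c(h = 0.5, d = 0.5))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "index.csv")
  write_index(idx, p)
  back <- read_index(p)
  expect_equal(back$id, idx$id)
  expect_equal(back$index, idx$index, tolerance = 1e-12)
  expect_equal(back$rank, idx$rank)
  paths <- write_ebv(g, dir)
  expect_true(all(file.exists(paths)))
  ebv_h <- readr::read_csv(paths[["h"]], show_col_types = FALSE)
  expect_equal(ebv_h$ebv, g$h)
  cmp <- compare_rankings(idx, idx, k = 3)
  jp <- file.path(dir, "cmp.json")
  write_rank_comparison(cmp, jp)
  expect_equal(jsonlite::read_json(jp)$tau, 1)
})
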