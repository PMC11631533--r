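#' Simulation configuration for synthetic breeding-trial data
#'
#' Bundles and validates the parameters of the synthetic-data generator:
#' pedigree structure (founders, number of generations including the founder
#' generation, full-sib families per generation, offspring per family), trait
#' means, genetic and residual covariance matrices, and the MCAR missingness
#' rate.
#'
#' @param founders Number of founder individuals (>= 2 when offspring are
#'   requested).
#' @param generations Total generations including the founders (1 = founders
#'   only).
#' @param families_per_generation Full-sib families per offspring generation.
#' @param offspring_per_family Offspring per family.
#' @param mu Trait mean vector (named or not; length m).
#' @param G0,R0 m x m genetic and residual trait covariance matrices
#'   (symmetric PSD).
#' @param missing_rate MCAR missingness probability in `[0, 1)`.
#' @param mechanism Missingness mechanism; only `"MCAR"` is supported.
#' @param seed Integer seed driving all generator randomness.
#' @return A validated list of class `pcb_sim_config`.
#' @export
sim_config <- function(founders, generations, families_per_generation,
                       offspring_per_family, mu, G0, R0,
                       missing_rate = 0, mechanism = "MCAR", seed = 1L) {
  stopifnot(founders >= 1, generations >= 1,
            families_per_generation >= 1, offspring_per_family >= 1)
  if (generations > 1 && founders < 2) {
    abort("need at least 2 founders to form families")
  }
  m <- length(mu)
  stopifnot(is.matrix(G0), is.matrix(R0),
            all(dim(G0) == m), all(dim(R0) == m))
  check_psd(G0, "G0")
  check_psd(R0, "R0")
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("missing_rate must be in [0, 1)")
  }
  mechanism <- match.arg(mechanism, "MCAR")
  traits <- names(mu) %||% paste0("trait", seq_len(m))
  names(mu) <- traits
  dimnames(G0) <- dimnames(R0) <- list(traits, traits)
  structure(list(
    founders = as.integer(founders),
    generations = as.integer(generations),
    families_per_generation = as.integer(families_per_generation),
    offspring_per_family = as.integer(offspring_per_family),
    mu = mu, G0 = G0, R0 = R0,
    missing_rate = missing_rate,
    mechanism = mechanism,
    seed = as.integer(seed)
  ), class = "pcb_sim_config")
}

check_psd <- function(S, label) {
  if (max(abs(S - Matrix::t(S))) > 1e-8) {
    abort(paste0(label, " must be symmetric"))
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    abort(paste0(label, " is not positive semi-definite"))
  }
  invisible(TRUE)
}

#' Simulate a multi-generation pedigree of controlled crosses
#'
#' Founders have unknown parents; each later generation consists of full-sib
#' families whose parents are random distinct pairs drawn from the previous
#' generation, emulating the controlled-cross designs of tree breeding
#' programs.
#'
#' @param config A `pcb_sim_config`.
#' @return A `pcb_pedigree`.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "pcb_sim_config"))
  withr::with_seed(config$seed, {
    recs <- tibble(
      id = sprintf("G1_%04d", seq_len(config$founders)),
      sire = NA_character_, dam = NA_character_
    )
    prev <- recs$id
    if (config$generations > 1) {
      for (g in 2:config$generations) {
        if (length(prev) < 2L) abort("mating pool has fewer than 2 members")
        kid <- 0L
        gen <- list()
        for (fam in seq_len(config$families_per_generation)) {
          pair <- sample(prev, 2L)
          ids <- sprintf("G%d_%04d", g, kid + seq_len(config$offspring_per_family))
          kid <- kid + config$offspring_per_family
          gen[[fam]] <- tibble(id = ids, sire = pair[1], dam = pair[2])
        }
        gen <- dplyr::bind_rows(gen)
        recs <- dplyr::bind_rows(recs, gen)
        prev <- gen$id
      }
    }
    as_pedigree(recs)
  })
}

# symmetric PSD square root
psd_sqrt <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate correlated multitrait phenotypes down a pedigree
#'
#' True breeding values follow the pedigree recursion: founder rows are
#' MVN(0, G0); an offspring's row is the parental average plus a
#' Mendelian-sampling deviation MVN(0, k G0) with
#' `k = 1/2 - (F_sire + F_dam)/4` (parents' own inbreeding reduces the
#' within-family variance; unknown-parent terms follow the same rules as the
#' relationship matrix). Residuals are iid MVN(0, R0) rows, and phenotypes
#' are `Y = mu + a + e`.
#'
#' @param ped A `pcb_pedigree`.
#' @param config A `pcb_sim_config` (its `G0`, `R0`, `mu`, `seed` are used).
#' @return List with `phenotypes` (tibble `id` + traits), `true_bv` (tibble
#'   `id` + traits of simulated breeding values).
#' @export
simulate_traits <- function(ped, config) {
  stopifnot(inherits(ped, "pcb_pedigree"), inherits(config, "pcb_sim_config"))
  n <- nrow(ped)
  m <- length(config$mu)
  sqG <- psd_sqrt(config$G0)
  sqR <- psd_sqrt(config$R0)
  pi <- ped_parent_index(ped)
  si <- pi$sire
  di <- pi$dam
  f <- inbreeding(ped)$F
  withr::with_seed(config$seed + 1L, {
    Zg <- matrix(rnorm(n * m), n, m) %*% sqG
    E <- matrix(rnorm(n * m), n, m) %*% sqR
    a <- matrix(0, n, m)
    for (i in seq_len(n)) {
      s <- si[i]
      d <- di[i]
      if (is.na(s) && is.na(d)) {
        a[i, ] <- Zg[i, ]
      } else if (!is.na(s) && !is.na(d)) {
        k <- 0.5 - 0.25 * (f[s] + f[d])
        a[i, ] <- 0.5 * (a[s, ] + a[d, ]) + sqrt(k) * Zg[i, ]
      } else {
        p <- if (is.na(s)) d else s
        k <- 0.75 - 0.25 * f[p]
        a[i, ] <- 0.5 * a[p, ] + sqrt(k) * Zg[i, ]
      }
    }
  })
  Y <- sweep(a + E, 2, config$mu, "+")
  traits <- names(config$mu)
  colnames(Y) <- colnames(a) <- traits
  rownames(Y) <- rownames(a) <- ped$id
  list(phenotypes = matrix_to_pheno(Y), true_bv = matrix_to_pheno(a))
}

#' Mask phenotype cells completely at random
#'
#' Each trait cell is masked independently with probability `rate` (MCAR).
#' If a draw would leave some trait without any observed value, the mask is
#' re-drawn once before erroring.
#'
#' @param data Phenotype tibble (`id` + trait columns).
#' @param rate Masking probability in `[0, 1)`.
#' @param mechanism Only `"MCAR"`.
#' @param seed Integer seed.
#' @return The tibble with masked cells set to `NA`.
#' @export
apply_missingness <- function(data, rate, mechanism = "MCAR", seed = 1L) {
  mechanism <- match.arg(mechanism, "MCAR")
  if (rate < 0 || rate >= 1) abort("rate must be in [0, 1)")
  if (rate == 0) return(data)
  pm <- pheno_matrix(data)
  draw <- function(s) {
    withr::with_seed(s, matrix(runif(length(pm$Y)) < rate, nrow(pm$Y)))
  }
  mask <- draw(seed)
  emptied <- function(mk) any(colSums(!mk & !is.na(pm$Y)) == 0L)
  if (emptied(mask)) {
    mask <- draw(seed + 1L)
    if (emptied(mask)) {
      abort("missingness rate empties a trait even after re-drawing")
    }
  }
  Y <- pm$Y
  Y[mask] <- NA_real_
  matrix_to_pheno(Y)
}

#' Scaled-down scenario presets
#'
#' Ready-made configurations echoing the family structures and heritability
#' ranges of typical conifer breeding populations, scaled to at most ~600
#' individuals so full analyses run in seconds: `"scots-small"` (15 complete
#' traits), `"scots-large"` (10 traits, 13.3% MCAR missingness) and
#' `"loblolly"` (26 traits from few founders, 8% missingness). Narrow-sense
#' heritabilities span 0.05-0.65 across traits; genetic and residual
#' correlation structures are drawn once, deterministically per preset.
#'
#' @param name One of `"scots-small"`, `"scots-large"`, `"loblolly"`.
#' @param seed Seed stored in the returned config (drives pedigree/trait
#'   draws; the covariance structures themselves are fixed per preset).
#' @return A `pcb_sim_config`.
#' @export
scenario_presets <- function(name = c("scots-small", "scots-large", "loblolly"),
                             seed = 1L) {
  name <- match.arg(name)
  preset <- switch(name,
    "scots-small" = list(m = 15L, founders = 40L, generations = 2L,
                         families = 30L, offspring = 8L, miss = 0,
                         preset_seed = 101L),
    "scots-large" = list(m = 10L, founders = 52L, generations = 2L,
                         families = 34L, offspring = 8L, miss = 0.133,
                         preset_seed = 102L),
    "loblolly" = list(m = 26L, founders = 32L, generations = 2L,
                      families = 33L, offspring = 8L, miss = 0.08,
                      preset_seed = 103L)
  )
  m <- preset$m
  withr::with_seed(preset$preset_seed, {
    h2 <- seq(0.05, 0.65, length.out = m)[sample.int(m)]
    vp <- runif(m, 1, 25)
    Cg <- random_correlation(m)
    Cr <- random_correlation(m)
    mu <- round(runif(m, 5, 60), 1)
  })
  sg <- sqrt(h2 * vp)
  sr <- sqrt((1 - h2) * vp)
  G0 <- Cg * tcrossprod(sg)
  R0 <- Cr * tcrossprod(sr)
  names(mu) <- paste0("trait", seq_len(m))
  sim_config(
    founders = preset$founders, generations = preset$generations,
    families_per_generation = preset$families, offspring_per_family = preset$offspring,
    mu = mu, G0 = G0, R0 = R0,
    missing_rate = preset$miss, seed = seed
  )
}

random_correlation <- function(m) {
  W <- matrix(rnorm(m * m), m, m)
  stats::cov2cor(crossprod(W) + 0.5 * m * diag(m))
}

#' Run a configured simulation and write its files
#'
#' Writes `pedigree.csv`, `phenotypes.csv` (with missingness applied) and
#' `truth.csv` (long table `id,trait,true_bv`) to a directory.
#'
#' @param config A `pcb_sim_config`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written, invisibly; the
#'   simulated objects are attached as attribute `"sim"`.
#' @export
write_simulation <- function(config, dir) {
  stopifnot(inherits(config, "pcb_sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- simulate_pedigree(config)
  sim <- simulate_traits(ped, config)
  pheno <- sim$phenotypes
  if (config$missing_rate > 0) {
    pheno <- apply_missingness(pheno, config$missing_rate,
                               seed = config$seed + 2L)
  }
  paths <- c(
    pedigree = file.path(dir, "pedigree.csv"),
    phenotypes = file.path(dir, "phenotypes.csv"),
    truth = file.path(dir, "truth.csv")
  )
  readr::write_csv(as_tibble(ped)[c("id", "sire", "dam")], paths["pedigree"],
                   progress = FALSE, na = "")
  write_phenotypes(pheno, paths["phenotypes"])
  truth_long <- tidyr::pivot_longer(sim$true_bv, -"id", names_to = "trait",
                                    values_to = "true_bv")
  readr::write_csv(truth_long, paths["truth"], progress = FALSE)
  out <- paths
  attr(out, "sim") <- list(pedigree = ped, phenotypes = pheno,
                           true_bv = sim$true_bv)
  invisible(out)
}
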