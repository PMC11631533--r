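#' Build a validated, topologically sorted pedigree
#'
#' A pedigree is a table of trio records (individual, sire, dam). Unknown
#' parents are permitted on either side. Records are reordered so that every
#' known parent precedes its offspring; parents that are referenced but never
#' declared as individuals are promoted to founders (with a message), which is
#' common pedigree-file practice.
#'
#' @param x A data frame whose first three columns are individual, sire and dam
#'   identifiers (columns named `id`, `sire`, `dam` are used if present).
#' @param unknown_codes Character vector of codes denoting an unknown parent,
#'   in addition to `NA`. Defaults cover the common file dialects.
#' @return A tibble of class `pcb_pedigree` with character columns `id`,
#'   `sire`, `dam` (`NA` = unknown parent) in topological order. Auto-added
#'   founders are recorded in the `added_founders` attribute.
#' @examples
#' ped <- as_pedigree(data.frame(id = c("C", "A", "B"),
#'                               sire = c("A", "0", "0"),
#'                               dam  = c("B", "0", "0")))
#' ped
#' @export
as_pedigree <- function(x, unknown_codes = c("0", "", "NA", ".")) {
  stopifnot(is.data.frame(x), ncol(x) >= 3)
  nms <- tolower(names(x))
  if (all(c("id", "sire", "dam") %in% nms)) {
    x <- x[, match(c("id", "sire", "dam"), nms)]
  } else {
    x <- x[, 1:3]
  }
  names(x) <- c("id", "sire", "dam")
  rec <- tibble(
    id   = trimws(as.character(x$id)),
    sire = decode_unknown(x$sire, unknown_codes),
    dam  = decode_unknown(x$dam, unknown_codes)
  )
  if (anyNA(rec$id) || any(rec$id == "")) {
    abort("pedigree contains missing individual ids")
  }
  if (anyDuplicated(rec$id)) {
    dup <- unique(rec$id[duplicated(rec$id)])
    abort(paste0("duplicate individual id(s): ", toString(head(dup, 5))))
  }
  self <- rec$id == rec$sire | rec$id == rec$dam
  self[is.na(self)] <- FALSE
  if (any(self)) {
    abort(paste0("individual(s) recorded as their own parent: ",
                 toString(rec$id[self])))
  }
  parents <- setdiff(stats::na.omit(c(rec$sire, rec$dam)), rec$id)
  if (length(parents)) {
    inform(paste0("promoting ", length(parents),
                  " undeclared parent(s) to founders: ",
                  toString(head(parents, 5)),
                  if (length(parents) > 5) ", ..." else ""))
    rec <- dplyr::bind_rows(
      tibble(id = parents, sire = NA_character_, dam = NA_character_), rec
    )
  }
  ord <- topo_order(rec)
  out <- rec[ord, ]
  class(out) <- c("pcb_pedigree", class(tibble()))
  attr(out, "added_founders") <- parents
  out
}

decode_unknown <- function(v, unknown_codes) {
  v <- trimws(as.character(v))
  v[v %in% unknown_codes] <- NA_character_
  v
}

# Kahn topological sort over the parent -> offspring DAG; errors on cycles,
# naming the individuals involved.
topo_order <- function(rec) {
  n <- nrow(rec)
  si <- match(rec$sire, rec$id)
  di <- match(rec$dam, rec$id)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    i <- queue[1]
    queue <- queue[-1]
    ord <- c(ord, i)
    for (k in kids[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n) {
    cyc <- rec$id[setdiff(seq_len(n), ord)]
    abort(paste0("pedigree contains a cycle (individual is its own ancestor) ",
                 "involving: ", toString(head(cyc, 10))))
  }
  ord
}

#' Read a pedigree file
#'
#' Reads delimited text (comma or tab, autodetected) with a header and columns
#' `id`, `sire`, `dam`, then validates and sorts it via [as_pedigree()].
#'
#' @param path Path to the pedigree file.
#' @inheritParams as_pedigree
#' @return A `pcb_pedigree` tibble.
#' @export
read_pedigree <- function(path, unknown_codes = c("0", "", "NA", ".")) {
  as_pedigree(read_delim_auto(path), unknown_codes = unknown_codes)
}

read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                    progress = FALSE, show_col_types = FALSE)
}

ped_parent_index <- function(ped) {
  list(sire = match(ped$sire, ped$id), dam = match(ped$dam, ped$id))
}

#' Inbreeding coefficients from a pedigree
#'
#' The inbreeding coefficient F of an individual is half the additive
#' relationship between its parents. Two equivalent algorithms are provided:
#' the dense tabular method (via `diag(A) - 1`) and the Meuwissen--Luo
#' ancestor-traversal algorithm, which avoids forming A and scales to large
#' pedigrees. `"auto"` uses the tabular method up to 2,000 individuals and
#' Meuwissen--Luo above that.
#'
#' @param ped A `pcb_pedigree`.
#' @param method `"auto"`, `"tabular"` or `"meuwissen-luo"`.
#' @return A tibble with columns `id` and `F` in pedigree order.
#' @export
inbreeding <- function(ped, method = c("auto", "tabular", "meuwissen-luo")) {
  method <- match.arg(method)
  stopifnot(inherits(ped, "pcb_pedigree"))
  if (method == "auto") {
    method <- if (nrow(ped) <= 2000L) "tabular" else "meuwissen-luo"
  }
  f <- switch(method,
    "tabular" = diag(additive_relationship(ped)) - 1,
    "meuwissen-luo" = inbreeding_ml(ped)
  )
  tibble(id = ped$id, F = unname(f))
}

# Meuwissen & Luo (1992) ancestor algorithm: for each individual, accumulate
# the squared Cholesky row against the Mendelian-sampling variances of its
# ancestors. Parents always precede offspring, so parental F are available.
inbreeding_ml <- function(ped) {
  n <- nrow(ped)
  pi <- ped_parent_index(ped)
  si <- pi$sire
  di <- pi$dam
  f <- numeric(n)
  dvec <- numeric(n) # Mendelian-sampling variance of each individual
  lvec <- numeric(n)
  for (i in seq_len(n)) {
    fs <- if (is.na(si[i])) -1 else f[si[i]]
    fd <- if (is.na(di[i])) -1 else f[di[i]]
    dvec[i] <- 0.5 - 0.25 * (fs + fd)
    if (is.na(si[i]) && is.na(di[i])) {
      f[i] <- 0
      next
    }
    lvec[seq_len(i)] <- 0
    lvec[i] <- 1
    acc <- 0
    for (j in rev(seq_len(i))) {
      lj <- lvec[j]
      if (lj == 0) next
      if (!is.na(si[j])) lvec[si[j]] <- lvec[si[j]] + 0.5 * lj
      if (!is.na(di[j])) lvec[di[j]] <- lvec[di[j]] + 0.5 * lj
      acc <- acc + lj * lj * dvec[j]
    }
    f[i] <- acc - 1
  }
  f
}

#' Additive (numerator) relationship matrix
#'
#' Computes the dense additive relationship matrix A by the tabular recursion
#' `a_ij = (a_j,sire(i) + a_j,dam(i)) / 2`,
#' `a_ii = 1 + a_sire(i),dam(i) / 2`, with unknown parents contributing zero.
#' Diagonal entries equal `1 + F_i`.
#'
#' @param ped A `pcb_pedigree`.
#' @return A symmetric numeric matrix with individual ids as dimnames.
#' @export
additive_relationship <- function(ped) {
  stopifnot(inherits(ped, "pcb_pedigree"))
  n <- nrow(ped)
  pi <- ped_parent_index(ped)
  si <- pi$sire
  di <- pi$dam
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]
    d <- di[i]
    A[i, i] <- if (!is.na(s) && !is.na(d)) 1 + 0.5 * A[s, d] else 1
    if (i > 1L) {
      j <- seq_len(i - 1L)
      v <- 0.5 * ((if (!is.na(s)) A[j, s] else 0) +
                  (if (!is.na(d)) A[j, d] else 0))
      A[j, i] <- v
      A[i, j] <- v
    }
  }
  A
}

# Mendelian-sampling variances d_i under Henderson's rules.
mendelian_variances <- function(ped, inbreeding = TRUE) {
  pi <- ped_parent_index(ped)
  si <- pi$sire
  di <- pi$dam
  f <- if (inbreeding) inbreeding(ped)$F else numeric(nrow(ped))
  fs <- ifelse(is.na(si), -1, f[ifelse(is.na(si), 1L, si)])
  fd <- ifelse(is.na(di), -1, f[ifelse(is.na(di), 1L, di)])
  0.5 - 0.25 * (fs + fd)
}

#' Sparse inverse of the additive relationship matrix
#'
#' Builds A-inverse directly from the pedigree by Henderson's rules, with
#' Mendelian-sampling variances `d_i = 1/2 - (F_sire + F_dam)/4` (terms for
#' unknown parents dropped). The result is sparse: nonzeros occur only among
#' individual--sire--dam triples.
#'
#' @param ped A `pcb_pedigree`.
#' @param inbreeding Account for inbreeding in the Mendelian-sampling
#'   variances (default `TRUE`). With `FALSE`, all F are treated as zero, as
#'   some evaluation software optionally does.
#' @return A sparse symmetric [Matrix::Matrix] with ids as dimnames. The
#'   Mendelian-sampling variances are attached as attribute `"d"` (so that
#'   `log det A = sum(log d)` is available without factorisation).
#' @export
relationship_inverse <- function(ped, inbreeding = TRUE) {
  stopifnot(inherits(ped, "pcb_pedigree"))
  n <- nrow(ped)
  pi <- ped_parent_index(ped)
  si <- pi$sire
  di <- pi$dam
  dvec <- mendelian_variances(ped, inbreeding = inbreeding)
  ii <- integer(9L * n); jj <- integer(9L * n); xx <- numeric(9L * n)
  k <- 0L
  add <- function(i, j, v) {
    k <<- k + 1L
    ii[k] <<- i; jj[k] <<- j; xx[k] <<- v
  }
  for (i in seq_len(n)) {
    a <- 1 / dvec[i]
    s <- si[i]
    d <- di[i]
    add(i, i, a)
    if (!is.na(s)) {
      add(i, s, -a / 2); add(s, i, -a / 2); add(s, s, a / 4)
    }
    if (!is.na(d)) {
      add(i, d, -a / 2); add(d, i, -a / 2); add(d, d, a / 4)
    }
    if (!is.na(s) && !is.na(d)) {
      add(s, d, a / 4); add(d, s, a / 4)
    }
  }
  ii <- ii[seq_len(k)]; jj <- jj[seq_len(k)]; xx <- xx[seq_len(k)]
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            dimnames = list(ped$id, ped$id))
  M <- Matrix::forceSymmetric(M)
  attr(M, "d") <- dvec
  M
}

#' Export a relationship matrix as triplet text
#'
#' Writes the lower triangle (including the diagonal) of a dense or sparse
#' relationship matrix as `row_id,col_id,value` delimited text.
#'
#' @param M A matrix with id dimnames (dense A or sparse A-inverse).
#' @param path Output file path.
#' @param zero_tol Entries with absolute value below this are skipped.
#' @return `path`, invisibly.
#' @export
write_relationship_triplets <- function(M, path, zero_tol = 0) {
  ids <- rownames(M)
  Md <- as.matrix(M)
  idx <- which(lower.tri(Md, diag = TRUE) & abs(Md) > zero_tol, arr.ind = TRUE)
  out <- tibble(
    row_id = ids[idx[, 1]],
    col_id = ids[idx[, 2]],
    value = Md[idx]
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @export
print.pcb_pedigree <- function(x, ...) {
  founders <- sum(is.na(x$sire) & is.na(x$dam))
  cat("# Pedigree:", nrow(x), "individuals (", founders, "founders )\n")
  NextMethod()
}
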