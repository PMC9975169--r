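#' Generate a nuclear-family pedigree
#'
#' Builds `n_families` independent nuclear families, each with two unrelated
#' founders and a number of children drawn uniformly from
#' `family_size["min"]..family_size["max"]`. Individual ids are zero-padded
#' strings unique across the cohort; missing parents are coded "0"
#' (FAM-file convention).
#'
#' @param n_families number of families (>= 1)
#' @param family_size named vector or list with `min` and `max` children per
#'   family (defaults 1 and 3)
#' @param seed optional integer seed; when given the pedigree is reproducible
#' @return a `data.frame` with columns `fam`, `id`, `father`, `mother`,
#'   `sex` (1 = male, 2 = female), class `c("pedigree_df", "data.frame")`
#' @export
generate_pedigree <- function(n_families, family_size = c(min = 1, max = 3),
                              seed = NULL) {
  if (!is.numeric(n_families) || length(n_families) != 1 || n_families < 1)
    stop("n_families must be a positive count")
  fs <- as.list(family_size)
  kmin <- as.integer(fs$min %||% 1); kmax <- as.integer(fs$max %||% 3)
  stopifnot(kmin >= 0, kmax >= kmin)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_families <- as.integer(n_families)
  nkids <- if (kmax > kmin)
    sample(kmin:kmax, n_families, replace = TRUE) else rep(kmin, n_families)
  rows <- vector("list", n_families)
  counter <- 0L
  for (f in seq_len(n_families)) {
    famid <- sprintf("F%04d", f)
    fa <- sprintf("I%06d", counter + 1L)
    mo <- sprintf("I%06d", counter + 2L)
    kid_ids <- if (nkids[f] > 0)
      sprintf("I%06d", counter + 2L + seq_len(nkids[f])) else character(0)
    counter <- counter + 2L + nkids[f]
    kid_sex <- if (nkids[f] > 0) sample(1:2, nkids[f], replace = TRUE) else integer(0)
    rows[[f]] <- data.frame(
      fam = famid,
      id = c(fa, mo, kid_ids),
      father = c("0", "0", rep(fa, nkids[f])),
      mother = c("0", "0", rep(mo, nkids[f])),
      sex = c(1L, 2L, kid_sex),
      stringsAsFactors = FALSE)
  }
  ped <- do.call(rbind, rows)
  rownames(ped) <- NULL
  class(ped) <- c("pedigree_df", "data.frame")
  ped
}

#' Kinship matrix from a pedigree
#'
#' Computes pairwise kinship coefficients phi by the standard recursion:
#' phi(i,i) = 0.5 * (1 + phi(father_i, mother_i)) and
#' phi(i,j) = 0.5 * (phi(father_i, j) + phi(mother_i, j)) for j not a
#' descendant of i, processing parents before children. Founders are assumed
#' non-inbred and unrelated across families, so the matrix is block-diagonal
#' by family with self-kinship 0.5 for founders.
#'
#' @param ped a pedigree `data.frame` as from [generate_pedigree()]
#' @return symmetric kinship matrix with sample ids as dimnames
#' @export
kinship_from_pedigree <- function(ped) {
  stopifnot(all(c("fam", "id", "father", "mother") %in% names(ped)))
  if (anyDuplicated(ped$id)) stop("duplicate individual ids in pedigree")
  ids <- ped$id
  n <- nrow(ped)
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  # founders across families are unrelated, so work family block by block
  for (rows in split(seq_len(n), ped$fam)) {
    blk <- kinship_block(ped[rows, , drop = FALSE])
    phi[rows, rows] <- blk
  }
  attr(phi, "family") <- setNames(ped$fam, ped$id)
  class(phi) <- c("kinship_matrix", "matrix")
  phi
}

# kinship recursion within one family (parents before children enforced by
# topological sort; cycles reported by individual id)
kinship_block <- function(ped) {
  m <- nrow(ped)
  ids <- ped$id
  idx <- setNames(seq_len(m), ids)
  fa <- ifelse(ped$father %in% ids, idx[ped$father], NA_integer_)
  mo <- ifelse(ped$mother %in% ids, idx[ped$mother], NA_integer_)
  order_out <- integer(0)
  placed <- logical(m)
  remaining <- seq_len(m)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(i) {
      (is.na(fa[i]) || placed[fa[i]]) && (is.na(mo[i]) || placed[mo[i]])
    }, logical(1))]
    if (!length(ready))
      stop("cyclic pedigree involving individual(s): ",
           paste(ids[remaining], collapse = ", "))
    placed[ready] <- TRUE
    order_out <- c(order_out, ready)
    remaining <- setdiff(remaining, ready)
  }
  phi <- matrix(0, m, m, dimnames = list(ids, ids))
  done <- integer(0)
  for (i in order_out) {
    pf <- fa[i]; pm <- mo[i]
    phi[i, i] <- if (!is.na(pf) && !is.na(pm)) 0.5 * (1 + phi[pf, pm]) else 0.5
    for (j in done) {
      v <- 0
      if (!is.na(pf)) v <- v + 0.5 * phi[pf, j]
      if (!is.na(pm)) v <- v + 0.5 * phi[pm, j]
      phi[i, j] <- phi[j, i] <- v
    }
    done <- c(done, i)
  }
  phi
}
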