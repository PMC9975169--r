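# shared fixture builders; everything is generated in code at test time

# small simulated cohort with cell PCs attached
small_bundle <- function(seed = 1, n_families = 120, n_probes = 300, ...) {
  cfg <- sim_config(n_families = n_families, n_probes = n_probes,
                    seed = seed, ...)
  b <- suppressMessages(simulate_cohort(cfg))
  add_cell_pcs(b)
}

# identity-family kinship (unrelated singletons)
singleton_kinship <- function(n, ids = sprintf("s%03d", seq_len(n))) {
  k <- diag(0.5, n)
  dimnames(k) <- list(ids, ids)
  attr(k, "family") <- stats::setNames(ids, ids)
  class(k) <- c("kinship_matrix", "matrix")
  k
}

# independent recursive kinship oracle (memoized pair recursion, coded
# separately from the package's iterative block algorithm)
oracle_kinship <- function(ped) {
  ids <- ped$id
  fa <- stats::setNames(ifelse(ped$father %in% ids, ped$father, NA), ids)
  mo <- stats::setNames(ifelse(ped$mother %in% ids, ped$mother, NA), ids)
  depth <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  gen <- function(i) {
    if (!is.na(depth[[i]])) return(depth[[i]])
    par <- c(fa[[i]], mo[[i]])
    par <- par[!is.na(par)]
    d <- if (!length(par)) 0L
         else 1L + max(vapply(par, gen, integer(1)))
    depth[[i]] <<- d
    d
  }
  for (i in ids) gen(i)
  memo <- new.env()
  phi <- function(i, j) {
    key <- paste(sort(c(i, j)), collapse = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      if (is.na(fa[[i]]) || is.na(mo[[i]])) 0.5
      else 0.5 * (1 + phi(fa[[i]], mo[[i]]))
    } else {
      # recurse on the individual of greater generation depth
      if (depth[[i]] < depth[[j]]) { tmp <- i; i <- j; j <- tmp }
      if (is.na(fa[[i]]) && is.na(mo[[i]])) 0
      else mean(c(if (!is.na(fa[[i]])) phi(fa[[i]], j) else 0,
                  if (!is.na(mo[[i]])) phi(mo[[i]], j) else 0))
    }
    memo[[key]] <- val
    val
  }
  out <- outer(ids, ids, Vectorize(function(a, b)
    if (ped$fam[match(a, ids)] == ped$fam[match(b, ids)]) phi(a, b) else 0))
  dimnames(out) <- list(ids, ids)
  out
}

# Li & Ji formula recomputed independently from a raw eigendecomposition
oracle_meff <- function(X) {
  C <- stats::cor(as.matrix(X), use = "pairwise.complete.obs")
  ev <- pmax(eigen(C, symmetric = TRUE)$values, 0)
  sum(ifelse(ev >= 1, 1, 0) + ev - floor(ev))
}
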