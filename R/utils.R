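#' @keywords internal
"_PACKAGE"

#' @importFrom data.table data.table fread fwrite as.data.table setcolorder :=
#' @importFrom stats rnorm runif rbinom rgamma qgamma pnorm qnorm var sd cor
#'   coef lm optimize prcomp hclust cutree as.dist complete.cases median
#'   qchisq pchisq setNames quantile
#' @importFrom utils packageVersion
NULL

# clamp a numeric vector into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Draw Dirichlet-distributed rows
#'
#' @param n number of draws (rows)
#' @param alpha concentration parameters, strictly positive
#' @return an `n x length(alpha)` matrix whose rows sum to 1
#' @keywords internal
rdirichlet <- function(n, alpha) {
  stopifnot(all(alpha > 0))
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' Genomic inflation factor of a p-value vector
#'
#' Median chi-square statistic of the observed p-values divided by the
#' median of the 1-df chi-square distribution.
#'
#' @param p vector of p-values in (0, 1]
#' @return the inflation factor lambda (1 under a calibrated null)
#' @export
inflation_lambda <- function(p) {
  p <- p[is.finite(p) & p > 0 & p <= 1]
  if (!length(p)) stop("no usable p-values")
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}

# stable hash of an R object (config provenance): serialize to a temp file
# and md5 it. version = 2 keeps the stream stable across R >= 3.5.
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
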