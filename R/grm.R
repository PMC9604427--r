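#' Genetic relationship matrix from standardized dosages
#'
#' `K = (1/m) sum_k z_k z_k'` with
#' `z_k = (g_k - 2 f_k) / sqrt(2 f_k (1 - f_k))`, where `f_k` is the alt
#' allele frequency of variant `k`. Monomorphic variants are excluded.
#' Under Hardy-Weinberg equilibrium the diagonal averages 1.
#'
#' @param genos a [genotype_matrix()].
#' @return An object of class `kinship_matrix`: list with the n x n
#'   symmetric PSD matrix `K` and `m`, the number of variants used.
#' @export
compute_grm <- function(genos) {
  stopifnot(inherits(genos, "genotype_matrix"))
  g <- genos$dosages
  f <- colMeans(g) / 2
  poly <- f > 0 & f < 1
  if (!any(poly)) stop("all variants are monomorphic; GRM undefined")
  g <- g[, poly, drop = FALSE]
  f <- f[poly]
  z <- sweep(sweep(g, 2, 2 * f, "-"), 2, sqrt(2 * f * (1 - f)), "/")
  m <- ncol(z)
  K <- tcrossprod(z) / m
  K <- (K + t(K)) / 2
  structure(list(K = K, m = m), class = "kinship_matrix")
}
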