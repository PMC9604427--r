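#' Generative truth for a gene's cis-regulated expression
#'
#' @param causal_indices integer indices (into the panel's variant columns)
#'   of the causal cis-eQTLs.
#' @param causal_effects numeric effects, one per causal index.
#' @param target_h2 cis SNP-heritability of expression in \[0, 1).
#' @return An object of class `expression_truth`.
#' @export
expression_truth <- function(causal_indices, causal_effects, target_h2) {
  if (length(causal_indices) != length(causal_effects)) {
    stop("causal_indices and causal_effects must have equal length")
  }
  if (target_h2 < 0 || target_h2 >= 1) stop("target_h2 must lie in [0, 1)")
  structure(list(causal_indices = as.integer(causal_indices),
                 causal_effects = as.numeric(causal_effects),
                 target_h2 = target_h2),
            class = "expression_truth")
}

#' Simulate expression values for a reference panel
#'
#' Generates `y = G_c beta_c + e` over the panel samples and rescales the
#' genetic and noise parts so that the realized variance ratio
#' `var(genetic) / var(y)` equals `target_h2` exactly on this panel: the
#' noise is first residualized against the genetic value (making the two
#' parts empirically orthogonal) and both are then scaled to the target
#' split. The total variance of `y` is 1 up to sampling of the components.
#'
#' @param genos panel [genotype_matrix()].
#' @param truth an [expression_truth()].
#' @param seed integer seed for the noise draw.
#' @return Numeric expression vector of length `nrow(genos$dosages)`, with
#'   the realized genetic value in attribute `"genetic_value"`.
#' @export
simulate_expression_panel <- function(genos, truth, seed = 1) {
  stopifnot(inherits(genos, "genotype_matrix"),
            inherits(truth, "expression_truth"))
  p <- nrow(genos$variants)
  if (length(truth$causal_indices) &&
      (max(truth$causal_indices) > p || min(truth$causal_indices) < 1)) {
    stop("causal indices outside the variant range 1..", p)
  }
  n <- nrow(genos$dosages)
  h2 <- truth$target_h2
  g <- if (length(truth$causal_indices)) {
    drop(genos$dosages[, truth$causal_indices, drop = FALSE] %*%
           truth$causal_effects)
  } else {
    rep(0, n)
  }
  g <- g - mean(g)
  eps <- withr::with_seed(seed, stats::rnorm(n))
  scale_g <- 0
  if (h2 > 0 && stats::var(g) > 0) {
    # orthogonalize the noise so the realized variance split is exact
    eps <- stats::resid(stats::lm(eps ~ g))
    scale_g <- sqrt(h2 / stats::var(g))
    g <- g * scale_g
    eps <- eps * sqrt((1 - h2) / stats::var(eps))
  } else {
    g <- rep(0, n)
    eps <- (eps - mean(eps)) / stats::sd(eps)
  }
  y <- g + eps
  attr(y, "genetic_value") <- g
  # causal effects on the rescaled (analysis) expression scale
  attr(y, "scaled_effects") <- truth$causal_effects * scale_g
  y
}
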