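#' Train a cis-expression weight model under one scheme
#'
#' Three schemes mirror the standard TWAS weight pipelines: `top1` keeps
#' only the single best marginal eQTL (largest absolute marginal z) with
#' its OLS coefficient; `lasso` and `enet` are penalized regressions
#' (glmnet coordinate descent, elastic-net mixing 1 and 0.5 respectively)
#' with the penalty chosen by an inner 5-fold cross-validation on the
#' training samples. Weights apply to alt-allele dosages on their original
#' 0..2 scale (glmnet standardizes internally and back-transforms its
#' coefficients).
#'
#' @param genos panel [genotype_matrix()] (n >= 20).
#' @param expression numeric expression vector.
#' @param scheme one of `"top1"`, `"lasso"`, `"enet"`.
#' @param seed integer seed fixing the inner-CV fold assignment.
#' @param lambda optional fixed penalty for the penalized schemes,
#'   bypassing the inner CV (`Inf` shrinks all weights to zero).
#' @return List with `weights` (length p, dosage scale), `intercept`,
#'   `fitted` (in-sample predictions) and `scheme`.
#' @export
fit_weights <- function(genos, expression, scheme = c("enet", "lasso", "top1"),
                        seed = 1, lambda = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(genos, "genotype_matrix"))
  y <- as.numeric(expression)
  g <- genos$dosages
  n <- nrow(g)
  if (length(y) != n) stop("expression length must match sample count")
  if (n < 20) stop("at least 20 panel samples are required")
  if (stats::sd(y) == 0) stop("expression has zero variance")
  p <- ncol(g)
  w <- numeric(p)
  if (scheme == "top1") {
    sds <- apply(g, 2, stats::sd)
    usable <- which(sds > 0)
    if (!length(usable)) stop("all variants monomorphic")
    z <- vapply(usable, function(j) {
      x <- g[, j]
      b <- stats::cov(x, y) / stats::var(x)
      res <- y - mean(y) - b * (x - mean(x))
      se <- sqrt(sum(res^2) / (n - 2) / (stats::var(x) * (n - 1)))
      b / se
    }, 0)
    best <- usable[which.max(abs(z))]
    x <- g[, best]
    w[best] <- stats::cov(x, y) / stats::var(x)
    a <- mean(y) - w[best] * mean(x)
  } else {
    alpha <- if (scheme == "lasso") 1 else 0.5
    if (!is.null(lambda) && is.infinite(lambda)) {
      a <- mean(y)
    } else if (!is.null(lambda)) {
      fit <- glmnet::glmnet(g, y, alpha = alpha, lambda = lambda)
      co <- as.numeric(stats::coef(fit))
      a <- co[1]
      w <- co[-1]
    } else {
      foldid <- withr::with_seed(seed,
        sample(rep_len(1:5, n)))
      cvfit <- glmnet::cv.glmnet(g, y, alpha = alpha, foldid = foldid,
                                 nlambda = 100)
      co <- as.numeric(stats::coef(cvfit, s = "lambda.min"))
      a <- co[1]
      w <- co[-1]
    }
  }
  list(weights = w, intercept = a,
       fitted = drop(a + g %*% w), scheme = scheme)
}

#' Out-of-fold cross-validated R-squared of a weight scheme
#'
#' k-fold cross-validation with a seeded shuffled fold assignment: the
#' scheme is retrained on each training fold and the pooled out-of-fold
#' predictions are scored as `R2 = 1 - SSE / SST` (negative when the model
#' predicts worse than the mean).
#'
#' @inheritParams fit_weights
#' @param k number of folds (default 5).
#' @return Scalar cross-validated R-squared.
#' @export
cv_r2 <- function(genos, expression, scheme = "enet", k = 5, seed = 1) {
  y <- as.numeric(expression)
  n <- length(y)
  if (k > n) stop("k (", k, ") exceeds sample count (", n, ")")
  fold <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  pred <- numeric(n)
  for (f in seq_len(k)) {
    test <- fold == f
    fit <- fit_weights(subset_genotypes(genos, samples = which(!test)),
                       y[!test], scheme = scheme, seed = seed + f)
    pred[test] <- fit$intercept +
      drop(genos$dosages[test, , drop = FALSE] %*% fit$weights)
  }
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' Build a gene's final expression model with heritability gating
#'
#' Pipeline per gene: take variants in the cis window (gene boundaries
#' +/- `window_kb` kb, clipped at position 1, optionally restricted by a
#' panel-subset mask), estimate cis SNP-heritability by REML, gate the gene
#' out unless the heritability is significant at `h2_gate`, then fit all
#' three weight schemes, score each by 5-fold cross-validation and keep the
#' best (ties broken in the order enet > lasso > top1). Genes passing the
#' heritability gate are retained even when the best cross-validated R2 is
#' non-positive, since the gate is the only inclusion criterion.
#'
#' @param annotation list or one-row data.frame with `gene_id`, `chrom`,
#'   `start`, `end` (1-based gene boundaries).
#' @param genos panel [genotype_matrix()] covering the gene's chromosome.
#' @param expression panel expression vector for the gene.
#' @param h2_gate heritability-gate p-value threshold (default 0.01).
#' @param window_kb cis window half-width in kb on either side of the gene
#'   boundary (default 500).
#' @param k cross-validation folds.
#' @param seed integer seed for fold assignments.
#' @param panel_mask optional logical vector over the variants of `genos`
#'   restricting which variants may enter models (e.g. a reference-panel
#'   SNP subset such as a HapMap3-style inclusion list).
#' @return An object of class `expression_model` (fields `gene_id`,
#'   `chrom`, `window`, `scheme`, `weights`, `cv_r2`, `h2est`, `variants`,
#'   `cv_r2_all`), or a gated-out marker (list with `gated_out = TRUE` and
#'   a `reason` of `"h2_gate"` or `"no_variants"`).
#' @export
build_gene_model <- function(annotation, genos, expression, h2_gate = 0.01,
                             window_kb = 500, k = 5, seed = 1,
                             panel_mask = NULL) {
  ann <- as.list(annotation)
  window <- c(max(1, ann$start - window_kb * 1000), ann$end + window_kb * 1000)
  in_win <- genos$variants$chrom == as.character(ann$chrom) &
    genos$variants$pos >= window[1] & genos$variants$pos <= window[2]
  if (!is.null(panel_mask)) in_win <- in_win & panel_mask
  gated <- function(reason, h2est = NULL) {
    structure(list(gene_id = ann$gene_id, gated_out = TRUE, reason = reason,
                   window = window, h2est = h2est),
              class = "expression_model")
  }
  if (!any(in_win)) return(gated("no_variants"))
  gw <- subset_genotypes(genos, variants = which(in_win))
  poly <- gw$variants$maf > 0
  if (!any(poly)) return(gated("no_variants"))
  gw <- subset_genotypes(gw, variants = which(poly))
  h2est <- estimate_h2_reml(expression, compute_grm(gw))
  if (h2est$p_value >= h2_gate) return(gated("h2_gate", h2est))
  schemes <- c("enet", "lasso", "top1")
  fits <- lapply(schemes, function(s) fit_weights(gw, expression, s, seed = seed))
  r2 <- vapply(seq_along(schemes), function(i) {
    cv_r2(gw, expression, schemes[i], k = k, seed = seed)
  }, 0)
  names(r2) <- schemes
  best <- which.max(r2)  # first max wins: enet > lasso > top1 on ties
  structure(list(
    gene_id = ann$gene_id, chrom = as.character(ann$chrom), window = window,
    scheme = schemes[best], weights = fits[[best]]$weights,
    intercept = fits[[best]]$intercept,
    cv_r2 = r2[[best]], cv_r2_all = r2, h2est = h2est,
    variants = gw$variants, gated_out = FALSE
  ), class = "expression_model")
}

#' @export
print.expression_model <- function(x, ...) {
  if (isTRUE(x$gated_out)) {
    cat("expression_model:", x$gene_id, "- gated out (", x$reason, ")\n")
  } else {
    cat("expression_model:", x$gene_id, " scheme =", x$scheme,
        " cv_r2 =", signif(x$cv_r2, 3),
        " h2 =", signif(x$h2est$h2, 3),
        " (p =", format(x$h2est$p_value, digits = 3), ")",
        " snps =", nrow(x$variants), "\n")
  }
  invisible(x)
}
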