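#' Bonferroni significance threshold for a genes x exposures scan
#'
#' @param n_genes,n_exposures family dimensions (>= 1).
#' @param alpha family-wise error rate in (0, 1).
#' @return `alpha / (n_genes * n_exposures)`.
#' @export
bonferroni_threshold <- function(n_genes, n_exposures, alpha = 0.05) {
  stopifnot(n_genes >= 1, n_exposures >= 1, alpha > 0, alpha < 1)
  alpha / (n_genes * n_exposures)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Step-up FDR adjustment: with the p-values sorted ascending,
#' `adj_(i) = min_{j >= i} m p_(j) / j`, capped at 1 and returned in the
#' original order (the classic BH procedure, applied here once per
#' exposure over all genes tested for that exposure).
#'
#' @param pvalues numeric vector with all values in (0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Genomic inflation factor and QQ coordinates
#'
#' `lambda_GC` is the ratio of the median of the chi-square-transformed
#' p-values to the null median of a 1-df chi-square (0.4549...), a
#' standard diagnostic for systematic inflation of test statistics;
#' values near 1 indicate a well-calibrated scan. QQ coordinates (expected
#' vs observed -log10 p under uniform order statistics) are returned for
#' plotting.
#'
#' @param pvalues at least 10 p-values in (0, 1\].
#' @return List with `lambda` and a `qq` data.frame (`expected`,
#'   `observed` on the -log10 scale).
#' @export
genomic_inflation <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (length(pvalues) < 10) {
    stop("at least 10 p-values are required for an inflation estimate")
  }
  if (any(pvalues <= 0 | pvalues > 1)) stop("p-values must lie in (0, 1]")
  chi <- stats::qchisq(pvalues, df = 1, lower.tail = FALSE)
  lambda <- stats::median(chi) / stats::qchisq(0.5, df = 1, lower.tail = FALSE)
  ord <- sort(pvalues)
  qq <- data.frame(
    expected = -log10(stats::ppoints(length(ord))),
    observed = -log10(ord)
  )
  list(lambda = lambda, qq = qq[order(qq$expected, decreasing = TRUE), ])
}

#' Genome-wide gene x exposure interaction scan
#'
#' Orchestrates the full scan: for each exposure it applies the
#' eligibility filter (all samples, parous women only, or a menopausal
#' stratum), restricts to complete cases on the exposure, assembles the
#' adjustment covariates (intercept, study indicators, age, five principal
#' components, plus any exposure-specific extra covariates such as former
#' MHT use), harmonizes each gene's weights to the cohort genotypes and
#' runs [misti_gene_test()]. Per exposure, adaptive p-values receive a
#' Benjamini-Hochberg adjustment; genome-wide significance is called at
#' the Bonferroni threshold `alpha / (n_genes x n_exposures)` and
#' suggestive findings are flagged at `fdr_adjusted < fdr`.
#'
#' @param models list of gene weight entries ([read_weights()] entries or
#'   non-gated `expression_model` objects).
#' @param genos cohort [genotype_matrix()].
#' @param pheno phenotype table ([read_phenotypes()] layout).
#' @param exposures list of [exposure_spec()] objects to test.
#' @param alpha family-wise error rate for the Bonferroni call.
#' @param fdr FDR threshold for the suggestive-findings flag.
#' @param grid adaptive-combination weight grid.
#' @return An object of class `scan_result`: list with `results` (one row
#'   per tested gene x exposure, Table-style columns plus diagnostics),
#'   `inflation` (per-exposure `lambda_GC` and QQ coordinates),
#'   `skipped` (records for exposures/genes not tested) and `meta`.
#' @export
run_scan <- function(models, genos, pheno, exposures, alpha = 0.05,
                     fdr = 0.2, grid = seq(0, 1, by = 0.1)) {
  stopifnot(length(models) >= 1, length(exposures) >= 1)
  if (is.null(names(models))) {
    names(models) <- vapply(models, function(m) m$gene_id, "")
  }
  n_genes <- length(models)
  n_expo <- length(exposures)
  bonf <- bonferroni_threshold(n_genes, n_expo, alpha)
  all_rows <- list()
  skipped <- list()
  inflation <- list()

  for (ex in exposures) {
    eligible <- switch(ex$eligibility,
      all = rep(TRUE, nrow(pheno)),
      parous_only = pheno$parous == 1,
      premenopausal_only = pheno$postmenopausal == 0,
      postmenopausal_only = pheno$postmenopausal == 1
    )
    if (!all(ex$extra_covariates %in% names(pheno))) {
      stop("exposure '", ex$name, "' requires covariate column(s): ",
           paste(setdiff(ex$extra_covariates, names(pheno)), collapse = ", "))
    }
    keep <- which(eligible & !is.na(pheno[[ex$name]]))
    if (length(keep) < 50) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        exposure = ex$name, gene_id = NA, reason = "empty_or_tiny_stratum",
        stringsAsFactors = FALSE)
      warning("exposure '", ex$name, "' skipped: eligible stratum has ",
              length(keep), " complete cases")
      next
    }
    ph <- pheno[keep, , drop = FALSE]
    sub <- subset_genotypes(genos, samples = keep)
    study <- factor(ph$study)
    X <- cbind(
      intercept = 1,
      if (nlevels(study) > 1) {
        stats::model.matrix(~study)[, -1, drop = FALSE]
      },
      age = ph$age,
      as.matrix(ph[, paste0("pc", 1:5)])
    )
    for (covar in ex$extra_covariates) X <- cbind(X, ph[[covar]])
    E <- ph[[ex$name]]
    Y <- ph$case_status

    rows <- list()
    for (gene in names(models)) {
      m <- models[[gene]]
      harm <- tryCatch(harmonize_alleles(m, sub), error = function(e) NULL)
      if (is.null(harm) || !any(harm$weights != 0)) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          exposure = ex$name, gene_id = gene, reason = "no_usable_weights",
          stringsAsFactors = FALSE)
        next
      }
      res <- misti_gene_test(harm$weights, harm$genos$dosages, E, X, Y,
                             gene_id = gene, chrom = m$chrom, grid = grid)
      res$exposure <- ex$name
      res$n_eligible <- length(keep)
      rows[[gene]] <- res
    }
    if (!length(rows)) next
    tab <- do.call(rbind, rows)
    ok <- !is.na(tab$p_amisti)
    tab$fdr_adjusted <- NA_real_
    tab$fdr_adjusted[ok] <- bh_adjust(tab$p_amisti[ok])
    tab$bonferroni_significant <- !is.na(tab$p_amisti) & tab$p_amisti < bonf
    tab$suggestive <- !is.na(tab$fdr_adjusted) & tab$fdr_adjusted < fdr
    if (sum(ok) >= 10) {
      inflation[[ex$name]] <- genomic_inflation(tab$p_amisti[ok])
    }
    all_rows[[ex$name]] <- tab
  }
  results <- if (length(all_rows)) do.call(rbind, all_rows) else
    data.frame()
  rownames(results) <- NULL
  structure(list(
    results = results,
    inflation = inflation,
    skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
    meta = list(n_genes = n_genes, n_exposures = n_expo, alpha = alpha,
                fdr = fdr, bonferroni_threshold = bonf,
                grid = grid)
  ), class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("gxescan scan:", x$meta$n_genes, "genes x", x$meta$n_exposures,
      "exposures;", nrow(x$results), "tests\n")
  cat("  Bonferroni threshold:", format(x$meta$bonferroni_threshold,
                                        digits = 3), "\n")
  if (nrow(x$results)) {
    cat("  Bonferroni-significant:", sum(x$results$bonferroni_significant),
        " suggestive (FDR <", x$meta$fdr, "):", sum(x$results$suggestive),
        "\n")
  }
  invisible(x)
}
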