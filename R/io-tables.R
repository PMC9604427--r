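#' Read a phenotype/covariate/exposure table
#'
#' Reads the tab-separated cohort table: case-control status, age, study,
#' principal components, exposure columns and eligibility flags (`parous`,
#' `postmenopausal`, former-MHT-use indicators). Missing exposure cells are
#' kept as `NA`; each exposure is analyzed complete-case downstream.
#'
#' @param path TSV file with a header row; required columns are
#'   `case_status`, `age`, `study`, `pc1`..`pc5`.
#' @return A data.frame with `study` as factor and `case_status` in \{0, 1\}.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  required <- c("case_status", "age", "study", paste0("pc", 1:5))
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("phenotype table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!all(tab$case_status %in% c(0L, 1L))) {
    stop("case_status must be coded 0/1; found: ",
         paste(setdiff(unique(tab$case_status), 0:1), collapse = ", "))
  }
  if (!is.null(tab$sample_id) && anyDuplicated(tab$sample_id)) {
    stop("sample_id values must be unique")
  }
  tab$study <- factor(tab$study)
  tab
}

#' Write a phenotype table
#'
#' @param pheno data.frame as returned by [read_phenotypes()] or
#'   [simulate_cohort()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write expression weight models to a TSV weight file
#'
#' One row per (gene, variant) with the gene-level metadata (scheme,
#' cross-validated R-squared, heritability estimate and its p-value, cis
#' window) repeated on each row. Only genes that passed the heritability
#' gate are written.
#'
#' @param models list of `expression_model` objects from
#'   [build_gene_model()] (gated-out entries are skipped).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(models, path) {
  rows <- list()
  for (m in models) {
    if (is.null(m) || isTRUE(m$gated_out)) next
    v <- m$variants
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = m$gene_id, gene_chrom = m$chrom,
      window_start = m$window[1], window_end = m$window[2],
      scheme = m$scheme,
      cv_r2 = sprintf("%.6g", m$cv_r2),
      h2 = sprintf("%.6g", m$h2est$h2),
      h2_p = sprintf("%.4e", m$h2est$p_value),
      variant_id = v$id, chrom = v$chrom, pos = v$pos,
      ref = v$ref, alt = v$alt,
      weight = sprintf("%.8e", m$weights),
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop("no non-gated models to write")
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV weight file into per-gene weight entries
#'
#' @param path weight file written by [write_weights()].
#' @return Named list of gene entries, each a list with `gene_id`, `chrom`,
#'   `window`, `scheme`, `cv_r2`, `h2`, `h2_p`, `variants` (data.frame) and
#'   `weights` (numeric vector aligned to `variants`).
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) stop("weight file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "gene_chrom", "window_start", "window_end", "scheme",
            "cv_r2", "h2", "h2_p", "variant_id", "chrom", "pos", "ref",
            "alt", "weight")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("weight file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!all(is.finite(tab$weight))) stop("weight file contains non-finite weights")
  entries <- lapply(split(tab, tab$gene_id), function(g) {
    scheme <- g$scheme[1]
    if (scheme == "top1" && sum(g$weight != 0) != 1) {
      stop("top1 entry for gene ", g$gene_id[1],
           " must have exactly one nonzero weight")
    }
    if (g$h2_p[1] >= 0.01) {
      stop("gene ", g$gene_id[1], " fails the heritability gate (h2_p = ",
           g$h2_p[1], ")")
    }
    list(
      gene_id = g$gene_id[1], chrom = g$gene_chrom[1],
      window = c(g$window_start[1], g$window_end[1]),
      scheme = scheme, cv_r2 = g$cv_r2[1],
      h2 = g$h2[1], h2_p = g$h2_p[1],
      variants = data.frame(id = g$variant_id, chrom = g$chrom, pos = g$pos,
                            ref = g$ref, alt = g$alt,
                            stringsAsFactors = FALSE),
      weights = g$weight
    )
  })
  entries[order(vapply(entries, function(e) e$gene_id, ""))]
}

#' Write gene-by-exposure interaction results to TSV
#'
#' Columns follow the standard gene-based GxE report: gene, chromosome,
#' SNP count, fixed-effect p, random-effect p, adaptive weighted p and the
#' per-exposure FDR-adjusted adaptive p. P-values are printed in scientific
#' notation with three significant digits.
#'
#' @param results data.frame of results (one row per gene x exposure), as
#'   produced by [run_scan()] or [misti_gene_test()] rows.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (!NROW(results)) stop("no results to write")
  out <- as.data.frame(results, stringsAsFactors = FALSE)
  for (col in intersect(c("p_fixed", "p_random", "p_fisher", "p_amisti"),
                        names(out))) {
    out[[col]] <- ifelse(is.na(out[[col]]), "NA", sprintf("%.3e", out[[col]]))
  }
  if ("fdr_adjusted" %in% names(out)) {
    out$fdr_adjusted <- ifelse(is.na(out$fdr_adjusted), "NA",
                               sprintf("%.3e", out$fdr_adjusted))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an interaction results TSV back into a data.frame
#'
#' @param path TSV written by [write_results()].
#' @return data.frame with numeric p-value columns.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  for (col in intersect(c("p_fixed", "p_random", "p_fisher", "p_amisti",
                          "fdr_adjusted"), names(tab))) {
    tab[[col]] <- as.numeric(tab[[col]])
  }
  tab
}
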