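#' Genotype dosage matrix with variant metadata
#'
#' Container shared by the reference expression panel and the case-control
#' cohort: an n x p matrix of alt-allele dosages in \[0, 2\] plus per-variant
#' metadata. Weights trained on a panel refer to the alt allele of the
#' variant records stored here, so the same container carries both sides of
#' the harmonization step.
#'
#' @param dosages numeric matrix, samples x variants, values in \[0, 2\].
#' @param variants data.frame with columns `id`, `chrom`, `pos`, `ref`,
#'   `alt` and optionally `info` (imputation quality in \[0, 1\], `NA` when
#'   unavailable). A `maf` column is recomputed from the dosages.
#' @param sample_ids character vector of unique sample identifiers.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `variants`, `sample_ids`.
#' @export
genotype_matrix <- function(dosages, variants, sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosages)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosages)))
  }
  stopifnot(is.data.frame(variants))
  required <- c("id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols)) {
    stop("variant metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(variants) != ncol(dosages)) {
    stop("variant count (", nrow(variants), ") does not match dosage columns (",
         ncol(dosages), ")")
  }
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (length(sample_ids) != nrow(dosages)) {
    stop("sample_ids length does not match dosage rows")
  }
  rng <- if (length(dosages)) range(dosages, finite = TRUE) else c(0, 0)
  if (length(dosages) && (rng[1] < -1e-8 || rng[2] > 2 + 1e-8)) {
    stop("dosages must lie in [0, 2]; observed range [",
         signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
  }
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
  if (any(variants$pos < 1)) stop("positions are 1-based; pos >= 1 required")
  variants$chrom <- as.character(variants$chrom)
  variants$maf <- dosage_maf(dosages)
  if (is.null(variants$info)) variants$info <- NA_real_
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variants$id
  structure(
    list(dosages = dosages, variants = variants, sample_ids = sample_ids),
    class = "genotype_matrix"
  )
}

# MAF from alt-dosage column means: min(mean/2, 1 - mean/2)
dosage_maf <- function(dosages) {
  m <- colMeans(dosages) / 2
  pmin(m, 1 - m)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      nrow(x$variants), "variants\n")
  if (nrow(x$variants)) {
    cat("  chrom:", paste(unique(x$variants$chrom), collapse = ", "),
        " MAF range:", paste(signif(range(x$variants$maf), 3), collapse = "-"), "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by samples and/or variants
#'
#' @param genos a [genotype_matrix()].
#' @param samples integer/logical/character index into samples (optional).
#' @param variants integer/logical index into variants (optional).
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(genos, samples = NULL, variants = NULL) {
  stopifnot(inherits(genos, "genotype_matrix"))
  d <- genos$dosages
  v <- genos$variants
  s <- genos$sample_ids
  if (!is.null(variants)) {
    d <- d[, variants, drop = FALSE]
    v <- v[variants, , drop = FALSE]
    rownames(v) <- NULL
  }
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, s)
    d <- d[samples, , drop = FALSE]
    s <- s[samples]
  }
  genotype_matrix(d, v, s)
}
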