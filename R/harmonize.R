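#' Harmonize a gene's weight variants with cohort genotypes
#'
#' Aligns a per-gene weight entry (alleles as stored in the weight file) to
#' a cohort [genotype_matrix()], matching variants on chrom:pos. Exact
#' ref/alt matches are kept unchanged; swapped ref/alt matches have the
#' cohort dosage replaced by `2 - dosage`; matches up to strand complement
#' (A<->T, C<->G applied to both alleles) are treated as exact or swapped
#' after complementing. Strand-ambiguous variants (ref/alt pair A/T or C/G)
#' are always dropped, as their orientation cannot be resolved; unmatched
#' weight variants are dropped with a count.
#'
#' @param entry gene entry as returned by [read_weights()] (or any list
#'   with `variants` data.frame and `weights` vector).
#' @param genos cohort [genotype_matrix()].
#' @return List with `weights` (aligned weight vector), `genos` (aligned
#'   `genotype_matrix` with flipped dosages where needed), `n_dropped`
#'   (unmatched), `n_ambiguous` (strand-ambiguous) and `n_flipped`.
#' @export
harmonize_alleles <- function(entry, genos) {
  stopifnot(inherits(genos, "genotype_matrix"))
  wv <- entry$variants
  w <- entry$weights
  stopifnot(nrow(wv) == length(w))
  key_w <- paste0(wv$chrom, ":", wv$pos)
  key_g <- paste0(genos$variants$chrom, ":", genos$variants$pos)
  idx <- match(key_w, key_g)

  ambiguous <- strand_ambiguous(wv$ref, wv$alt)
  keep <- integer(0)     # index into weight rows
  gcol <- integer(0)     # matching cohort column
  flip <- logical(0)
  for (i in seq_along(w)) {
    j <- idx[i]
    if (is.na(j) || ambiguous[i]) next
    g_ref <- genos$variants$ref[j]
    g_alt <- genos$variants$alt[j]
    status <- match_alleles(wv$ref[i], wv$alt[i], g_ref, g_alt)
    if (is.na(status)) next
    keep <- c(keep, i)
    gcol <- c(gcol, j)
    flip <- c(flip, status)
  }
  if (!length(keep)) {
    stop("no overlapping variants between weight entry '",
         entry$gene_id %||% "?", "' and cohort genotypes")
  }
  out <- subset_genotypes(genos, variants = gcol)
  if (any(flip)) {
    out$dosages[, flip] <- 2 - out$dosages[, flip, drop = FALSE]
    # after flipping, the stored alleles follow the weight-file orientation
    out$variants$ref[flip] <- wv$ref[keep][flip]
    out$variants$alt[flip] <- wv$alt[keep][flip]
    out$variants$maf <- dosage_maf(out$dosages)
  }
  list(
    weights = w[keep],
    genos = out,
    n_dropped = sum(!ambiguous) - length(keep),
    n_ambiguous = sum(ambiguous),
    n_flipped = sum(flip)
  )
}

strand_ambiguous <- function(ref, alt) {
  pair <- paste0(ref, alt)
  pair %in% c("AT", "TA", "CG", "GC")
}

complement_allele <- function(a) {
  chartr("ACGT", "TGCA", a)
}

# TRUE = swap (dosage -> 2 - dosage), FALSE = keep, NA = no match
match_alleles <- function(w_ref, w_alt, g_ref, g_alt) {
  if (w_ref == g_ref && w_alt == g_alt) return(FALSE)
  if (w_ref == g_alt && w_alt == g_ref) return(TRUE)
  cr <- complement_allele(w_ref)
  ca <- complement_allele(w_alt)
  if (cr == g_ref && ca == g_alt) return(FALSE)
  if (cr == g_alt && ca == g_ref) return(TRUE)
  NA
}

`%||%` <- function(a, b) if (is.null(a)) b else a
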