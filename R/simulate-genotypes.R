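#' Specification of a block-structured LD panel
#'
#' Parameters of the latent-Gaussian haplotype model used by
#' [simulate_ld_genotypes()]: variants are arranged in blocks, the latent
#' Gaussian is AR(1) with correlation `within_block_rho^|i-j|` inside a
#' block and zero between blocks, and per-variant MAFs are drawn uniformly
#' in `[maf_low, maf_high]`.
#'
#' @param n_blocks number of independent LD blocks.
#' @param block_size variants per block.
#' @param within_block_rho AR(1) latent correlation in \[0, 1).
#' @param maf_low,maf_high MAF range; `0.005 <= maf_low <= maf_high <= 0.5`.
#' @param seed integer seed fixing MAFs and haplotype draws.
#' @param chrom chromosome label for the emitted variant records.
#' @param pos_start,pos_step base-pair position of the first variant and
#'   spacing between consecutive variants.
#' @return An object of class `ld_spec`.
#' @export
ld_spec <- function(n_blocks = 4, block_size = 25, within_block_rho = 0.7,
                    maf_low = 0.05, maf_high = 0.5, seed = 1,
                    chrom = "1", pos_start = 1e6, pos_step = 2000) {
  if (block_size < 1 || n_blocks < 1) stop("n_blocks and block_size must be >= 1")
  if (within_block_rho < 0 || within_block_rho >= 1) {
    stop("within_block_rho must lie in [0, 1)")
  }
  if (!(maf_low >= 0.005 && maf_low <= maf_high && maf_high <= 0.5)) {
    stop("require 0.005 <= maf_low <= maf_high <= 0.5")
  }
  structure(list(n_blocks = as.integer(n_blocks),
                 block_size = as.integer(block_size),
                 within_block_rho = within_block_rho,
                 maf_low = maf_low, maf_high = maf_high,
                 seed = as.integer(seed), chrom = as.character(chrom),
                 pos_start = pos_start, pos_step = pos_step),
            class = "ld_spec")
}

#' Simulate LD-structured genotype dosages
#'
#' Each of two independent haplotypes per sample is generated by
#' thresholding a block-autoregressive latent Gaussian vector at the
#' per-variant MAF-matched quantile; the dosage is the sum of the two
#' haplotypes, so variants follow Hardy-Weinberg proportions with the
#' requested allele frequency and an AR(1)-decaying LD profile within each
#' block. Deterministic given `spec$seed`.
#'
#' @param n number of samples (>= 2).
#' @param spec an [ld_spec()].
#' @param seed seed for the haplotype draws; defaults to `spec$seed`. The
#'   variant grid (loci and MAFs) always derives from `spec$seed`, so two
#'   calls with different `seed` yield independent samples at the same
#'   variants — a reference panel and a cohort population sharing loci.
#' @return A [genotype_matrix()] with `n` rows and
#'   `spec$n_blocks * spec$block_size` columns.
#' @export
simulate_ld_genotypes <- function(n, spec, seed = spec$seed) {
  stopifnot(inherits(spec, "ld_spec"))
  if (n < 2) stop("n must be >= 2")
  p <- spec$n_blocks * spec$block_size
  mafs <- withr::with_seed(spec$seed,
                           stats::runif(p, spec$maf_low, spec$maf_high))
  withr::with_seed(seed, {
    thr <- stats::qnorm(mafs)
    hap <- function() {
      z <- matrix(0, n, p)
      rho <- spec$within_block_rho
      for (b in seq_len(spec$n_blocks)) {
        cols <- (b - 1L) * spec$block_size + seq_len(spec$block_size)
        e <- matrix(stats::rnorm(n * spec$block_size), n, spec$block_size)
        zb <- e
        if (spec$block_size > 1 && rho > 0) {
          for (j in 2:spec$block_size) {
            zb[, j] <- rho * zb[, j - 1] + sqrt(1 - rho^2) * e[, j]
          }
        }
        z[, cols] <- zb
      }
      # alt allele carried when the latent value falls below the MAF quantile
      sweep(z, 2, thr, "<") + 0
    }
    dos <- hap() + hap()
  })
  variants <- data.frame(
    id = sprintf("rs%d_%d", spec$seed, seq_len(p)),
    chrom = spec$chrom,
    pos = as.integer(spec$pos_start + (seq_len(p) - 1L) * spec$pos_step),
    ref = "A", alt = "G",
    info = NA_real_,
    stringsAsFactors = FALSE
  )
  genotype_matrix(dos, variants, paste0("S", seq_len(n)))
}
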