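#' Read genotype dosages from a VCF file
#'
#' Reads a VCF (v4.x) into a [genotype_matrix()], taking per-sample dosages
#' from the `DS` FORMAT field when present and otherwise counting alt
#' alleles in `GT`. Variants are filtered on minor allele frequency and,
#' when an `INFO=` key carries an imputation quality score, on that score
#' (variants without a score are retained). The default thresholds are the
#' conventional post-imputation filters MAF >= 0.5% and INFO >= 0.3.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param region optional `"chrom:start-end"` string; both endpoints are
#'   1-based and inclusive.
#' @param maf_min minimum minor allele frequency, computed from the dosages.
#' @param info_min minimum imputation INFO score; only applied to variants
#'   that carry a score.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, region = NULL, maf_min = 0.005, info_min = 0.3) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  stopifnot(maf_min >= 0, maf_min <= 0.5, info_min >= 0, info_min <= 1)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF '", path, "' contains no variant records")
  n_samples <- ncol(vcf@gt) - 1L
  if (is.na(n_samples) || n_samples < 1) {
    stop("VCF '", path, "' contains no sample columns")
  }
  keep <- rep(TRUE, nrow(fix))
  pos <- as.integer(fix$POS)
  if (!is.null(region)) {
    reg <- parse_region(region)
    keep <- fix$CHROM == reg$chrom & pos >= reg$start & pos <= reg$end
  }
  if (!any(keep)) {
    return(genotype_matrix(matrix(0, n_samples, 0),
                           empty_variant_frame(),
                           colnames(vcf@gt)[-1]))
  }
  fix <- fix[keep, , drop = FALSE]
  pos <- pos[keep]
  gt <- vcf@gt[keep, , drop = FALSE]

  ds <- extract_dosages(gt)
  info <- parse_info_score(fix$INFO)
  ids <- fix$ID
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix$CHROM[no_id], ":", pos[no_id])

  variants <- data.frame(
    id = ids, chrom = fix$CHROM, pos = pos,
    ref = fix$REF, alt = fix$ALT, info = info,
    stringsAsFactors = FALSE
  )
  maf <- dosage_maf(ds)
  pass <- maf >= maf_min & (is.na(info) | info >= info_min)
  genotype_matrix(ds[, pass, drop = FALSE],
                  variants[pass, , drop = FALSE],
                  colnames(gt)[-1])
}

parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4) {
    stop("malformed region '", region, "'; expected chrom:start-end")
  }
  out <- list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
  if (out$start > out$end) stop("region start exceeds end: ", region)
  out
}

empty_variant_frame <- function() {
  data.frame(id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), info = numeric(),
             stringsAsFactors = FALSE)
}

# samples x variants dosage matrix from the vcfR @gt slot (FORMAT + samples)
extract_dosages <- function(gt) {
  format_field <- gt[, 1]
  body <- gt[, -1, drop = FALSE]
  out <- matrix(NA_real_, nrow = ncol(body), ncol = nrow(body))
  for (i in seq_len(nrow(body))) {
    keys <- strsplit(format_field[i], ":", fixed = TRUE)[[1]]
    fields <- strsplit(body[i, ], ":", fixed = TRUE)
    ds_idx <- match("DS", keys)
    if (!is.na(ds_idx)) {
      vals <- as.numeric(vapply(fields, function(f) f[ds_idx], ""))
    } else {
      gt_idx <- match("GT", keys)
      if (is.na(gt_idx)) {
        stop("VCF record ", i, " carries neither DS nor GT in FORMAT")
      }
      gt_str <- vapply(fields, function(f) f[gt_idx], "")
      vals <- vapply(gt_str, count_alt_alleles, 0)
    }
    if (anyNA(vals)) {
      stop("missing or unparseable dosage for variant record ", i)
    }
    out[, i] <- vals
  }
  rownames(out) <- colnames(body)
  out
}

count_alt_alleles <- function(gt_str) {
  alleles <- strsplit(gt_str, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_real_)
  sum(as.integer(alleles) > 0)
}

# INFO score from key INFO= or R2=; NA when absent
parse_info_score <- function(info_col) {
  vapply(info_col, function(s) {
    if (is.na(s)) return(NA_real_)
    for (key in c("INFO", "R2")) {
      m <- regmatches(s, regexec(paste0("(?:^|;)", key, "=([0-9.eE+-]+)"), s))[[1]]
      if (length(m) == 2) return(as.numeric(m[2]))
    }
    NA_real_
  }, 0, USE.NAMES = FALSE)
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Emits a minimal VCFv4.2 file with a `DS` FORMAT field (and a hard-called
#' `GT` derived by rounding the dosage) plus an `INFO=` key when the variant
#' carries an imputation quality score. Round-trips through
#' [read_genotypes()].
#'
#' @param genos a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genos, path) {
  stopifnot(inherits(genos, "genotype_matrix"))
  v <- genos$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation quality score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genos$sample_ids), collapse = "\t")
  ), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(v))) {
    ds <- genos$dosages[, j]
    info <- if (is.na(v$info[j])) "." else sprintf("INFO=%.4g", v$info[j])
    cells <- paste0(gt_code[pmin(pmax(round(ds), 0), 2) + 1L],
                    ":", formatC(ds, format = "g", digits = 6))
    writeLines(paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j],
                       ".", "PASS", info, "GT:DS", cells), collapse = "\t"), con)
  }
  invisible(path)
}
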