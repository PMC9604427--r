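#' Generative truth for a case-control GxE cohort
#'
#' Parameters of the disease model
#' `logit(p_i) = alpha0 + X_i gamma + beta_E E_i + beta_T T_i +
#'  beta_TE T_i E_i + sum_j b_j G_ij E_i`, with `T = G w` the genetic value
#' of expression and `b_j ~ N(0, tau^2)` per-variant residual interaction
#' effects drawn once per gene. `beta_TE` is the fixed
#' expression-by-exposure interaction; `tau` indexes the residual
#' (variance-component) interaction signal.
#'
#' @param beta_E,beta_T,beta_TE main-effect and fixed-interaction log-odds
#'   coefficients.
#' @param tau standard deviation (>= 0) of the per-variant random
#'   interaction effects.
#' @param alpha0 intercept; controls population disease prevalence.
#' @param gamma_age log-odds per year of (centered) age.
#' @param gamma_study log-odds offset per unit of the study index beyond
#'   the first study.
#' @param gamma_pc length-5 log-odds vector on the genotype PCs.
#' @param seed integer seed for all cohort randomness.
#' @return An object of class `cohort_truth`.
#' @export
cohort_truth <- function(beta_E = 0, beta_T = 0, beta_TE = 0, tau = 0,
                         alpha0 = 0, gamma_age = 0.01, gamma_study = 0.1,
                         gamma_pc = rep(0, 5), seed = 1) {
  if (tau < 0) stop("tau must be >= 0")
  structure(list(beta_E = beta_E, beta_T = beta_T, beta_TE = beta_TE,
                 tau = tau, alpha0 = alpha0, gamma_age = gamma_age,
                 gamma_study = gamma_study, gamma_pc = gamma_pc,
                 seed = as.integer(seed)),
            class = "cohort_truth")
}

#' Leading genotype principal components
#'
#' PCs of the column-standardized dosage matrix; the returned score columns
#' are orthonormal over samples (left singular vectors).
#'
#' @param genos a [genotype_matrix()].
#' @param k number of components; when the matrix supports fewer, the
#'   remaining columns are filled with orthonormal complements drawn from
#'   a fixed rotation, so the output always has `k` orthonormal columns.
#' @return n x k matrix with orthonormal columns named `pc1..pck`.
#' @export
genotype_pcs <- function(genos, k = 5) {
  x <- scale(genos$dosages)
  x[, !is.finite(colSums(x))] <- 0  # monomorphic columns
  k_data <- min(k, nrow(x) - 1L, ncol(x))
  if (k_data < k) {
    u <- genotype_pcs_core(x, k_data)
    # complete the basis with vectors orthogonal to the data PCs
    extra <- withr::with_seed(99173, matrix(stats::rnorm(nrow(x) * (k - k_data)),
                                            nrow(x)))
    extra <- extra - u %*% crossprod(u, extra)
    extra <- qr.Q(qr(extra))
    out <- cbind(u, extra[, seq_len(k - k_data), drop = FALSE])
    colnames(out) <- paste0("pc", seq_len(k))
    return(out)
  }
  k <- k_data
  genotype_pcs_core(x, k)
}

genotype_pcs_core <- function(x, k) {
  # p is small relative to n: eigendecompose the p x p cross-product
  cp <- crossprod(x)
  eg <- eigen(cp, symmetric = TRUE)
  d <- sqrt(pmax(eg$values[seq_len(k)], 1e-12))
  u <- x %*% eg$vectors[, seq_len(k), drop = FALSE] %*% diag(1 / d, k)
  colnames(u) <- paste0("pc", seq_len(k))
  u
}

#' Simulate an ascertained case-control cohort with GxE structure
#'
#' Draws disease outcomes for every sample of a simulated population under
#' the mixed-effects interaction model of [cohort_truth()], then samples
#' the requested case and control quotas without replacement (ascertained,
#' outcome-dependent sampling). Covariates are a categorical `study`, age,
#' and five genotype principal components; exposures (including the
#' interacting one, the first spec in `exposure_specs`) come from
#' [make_exposures()]. The emitted PCs are recomputed on the sampled
#' cohort, so they are orthonormal over the rows of the output table.
#'
#' @param genos population [genotype_matrix()]; its size bounds
#'   `n_cases + n_controls` and should comfortably exceed the quotas (a
#'   population around 20x the target size mimics strong ascertainment of
#'   a rare disease; balanced designs need much less).
#' @param weights numeric weight vector (length = variants in `genos`)
#'   defining the genetic value `T = G w`; typically true simulation
#'   weights or a trained model's weights.
#' @param exposure_specs list of [exposure_spec()]; the first is the
#'   exposure that interacts in the disease model.
#' @param truth a [cohort_truth()].
#' @param n_cases,n_controls sampling quotas.
#' @param n_studies number of study strata.
#' @return List with `genos` (cohort genotypes), `pheno` (phenotype table
#'   with `sample_id`, `case_status`, `age`, `study`, `pc1..pc5`,
#'   eligibility flags and exposure columns) and `truth_b` (the realized
#'   per-variant random interaction effects).
#' @export
simulate_cohort <- function(genos, weights, exposure_specs = NULL,
                            truth = cohort_truth(), n_cases, n_controls,
                            n_studies = 2) {
  stopifnot(inherits(genos, "genotype_matrix"),
            inherits(truth, "cohort_truth"))
  N <- nrow(genos$dosages)
  p <- ncol(genos$dosages)
  if (length(weights) != p) stop("weights length must equal variant count")
  if (n_cases + n_controls > N) {
    stop("population of ", N, " cannot supply ", n_cases, " cases + ",
         n_controls, " controls")
  }
  if (is.null(exposure_specs)) {
    exposure_specs <- list(exposure_spec("exposure", "continuous"))
  }
  T_all <- drop(genos$dosages %*% weights)
  pcs_pop <- genotype_pcs(genos, 5)

  pop <- withr::with_seed(truth$seed, {
    tab <- data.frame(
      sample_id = genos$sample_ids,
      age = stats::rnorm(N, 56, 8),
      study = paste0("study", sample.int(n_studies, N, replace = TRUE)),
      stringsAsFactors = FALSE
    )
    tab <- make_exposures(tab, exposure_specs, seed = truth$seed + 1L)
    E <- tab[[exposure_specs[[1]]$name]]
    E_lp <- ifelse(is.na(E), 0, E)  # ineligible samples carry no E signal
    b <- if (truth$tau > 0) stats::rnorm(p, 0, truth$tau) else rep(0, p)
    study_idx <- as.integer(factor(tab$study))
    lp <- truth$alpha0 +
      truth$gamma_age * (tab$age - mean(tab$age)) +
      truth$gamma_study * (study_idx - 1) +
      drop(pcs_pop %*% truth$gamma_pc) +
      truth$beta_E * E_lp + truth$beta_T * T_all +
      truth$beta_TE * T_all * E_lp +
      drop(genos$dosages %*% b) * E_lp
    y <- stats::rbinom(N, 1, stats::plogis(lp))
    cases <- which(y == 1)
    controls <- which(y == 0)
    if (length(cases) < n_cases || length(controls) < n_controls) {
      stop("population yielded ", length(cases), " cases / ",
           length(controls), " controls; quotas unreachable - adjust the ",
           "intercept alpha0 or enlarge the population")
    }
    idx <- c(sample(cases, n_cases), sample(controls, n_controls))
    tab$case_status <- y
    list(tab = tab, idx = idx, b = b)
  })

  idx <- pop$idx
  cohort_genos <- subset_genotypes(genos, samples = idx)
  pheno <- pop$tab[idx, , drop = FALSE]
  rownames(pheno) <- NULL
  pcs <- genotype_pcs(cohort_genos, 5)
  for (k in 1:5) pheno[[paste0("pc", k)]] <- pcs[, k]
  front <- c("sample_id", "case_status", "age", "study", paste0("pc", 1:5))
  pheno <- pheno[, c(front, setdiff(names(pheno), front)), drop = FALSE]
  list(genos = cohort_genos, pheno = pheno, truth_b = pop$b)
}
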