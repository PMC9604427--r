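#' Fixed-effect interaction score test
#'
#' 1-df score test of the predicted-expression-by-exposure coefficient in
#' the logistic model, against the fitted null. With interaction column
#' `c = T * E` (elementwise), `U_f = c'(Y - mu)` and the efficient
#' variance `V_f = c'Wc - c'WD (D'WD)^-1 D'Wc` projects out the null
#' design `D = [X, E, T]`; the statistic `U_f^2 / V_f` is compared to a
#' 1-df chi-square.
#'
#' @param null a [fit_null_logistic()] fit.
#' @param T_hat predicted expression vector (defaults to the one stored in
#'   the null fit).
#' @param E exposure vector (defaults likewise).
#' @return An object of class `fixed_score`: list with `U`, `V`, `stat`,
#'   `p`.
#' @export
fixed_score_test <- function(null, T_hat = NULL, E = NULL) {
  stopifnot(inherits(null, "null_fit"))
  T_hat <- T_hat %||% null$T_hat
  E <- E %||% null$E
  cc <- T_hat * E
  r <- null$Y - null$mu
  D <- null$D
  W <- null$W
  U <- sum(cc * r)
  WD <- D * W
  cWD <- crossprod(cc, WD)                       # 1 x q
  V <- sum(cc^2 * W) - drop(cWD %*% solve(crossprod(D, WD), t(cWD)))
  if (V <= 1e-12) {
    stop("degenerate interaction term: efficient variance is zero ",
         "(interaction column lies in the null design span)")
  }
  stat <- U^2 / V
  p <- max(stats::pchisq(stat, 1, lower.tail = FALSE), 1e-300)
  structure(list(U = U, V = V, stat = stat, p = p), class = "fixed_score")
}

#' Variance-component score test for residual SNP-by-exposure effects
#'
#' Tests `tau^2 = 0` in the random-effects part of the interaction model,
#' where each SNP's interaction coefficient is `b_j ~ N(0, tau^2)`. The
#' score statistic is `Q = || Z'(Y - mu_a) ||^2` with `Z = diag(E) G`.
#' The residuals come from an augmented null that also contains the fixed
#' interaction column `c = T * E`, which projects the fixed-effect signal
#' out of the random component and renders the two component scores
#' asymptotically independent. The null distribution of `Q` is the
#' mixture `sum_k lambda_k chi2_1` with `lambda_k` the eigenvalues of
#' `Z' P_a Z`, `P_a = W_a - W_a D_a (D_a' W_a D_a)^-1 D_a' W_a`.
#'
#' @param null a [fit_null_logistic()] fit.
#' @param G genotype dosage matrix for the gene's variants (n x p),
#'   harmonized to the weight orientation.
#' @param E exposure vector (defaults to the null fit's).
#' @param include_fixed_in_null augment the null with the fixed
#'   interaction column (default `TRUE`, the independence construction).
#' @return An object of class `random_score`: list with `Q`, `lambdas`,
#'   `p` and the mixture-tail `method` flag.
#' @export
random_score_test <- function(null, G, E = NULL, include_fixed_in_null = TRUE) {
  stopifnot(inherits(null, "null_fit"))
  G <- as.matrix(G)
  E <- E %||% null$E
  if (ncol(G) < 1) stop("G must have at least one column")
  if (include_fixed_in_null) {
    cc <- null$T_hat * E
    Da <- cbind(null$D, fixed_gxe = cc)
    # drop the augmentation column if it is numerically collinear with D
    qr_d <- qr(Da)
    if (qr_d$rank < ncol(Da)) Da <- null$D
    fit <- suppressWarnings(
      stats::glm.fit(Da, null$Y, family = stats::binomial(),
                     control = list(epsilon = 1e-10, maxit = 100))
    )
    mu <- fit$fitted.values
  } else {
    Da <- null$D
    mu <- null$mu
  }
  W <- mu * (1 - mu)
  r <- null$Y - mu
  Z <- G * E
  Q <- sum(crossprod(Z, r)^2)
  WD <- Da * W
  ZtWD <- crossprod(Z, WD)
  M <- crossprod(Z, Z * W) -
    ZtWD %*% solve(crossprod(Da, WD), t(ZtWD))
  lam <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > max(lam[1], 0) * 1e-10 & lam > 1e-12]
  if (!length(lam)) {
    stop("degenerate random component: all eigenvalues of the projected ",
         "score covariance are zero")
  }
  p <- mixture_tail_prob(Q, lam)
  structure(list(Q = Q, lambdas = lam, p = as.numeric(p),
                 method = attr(p, "method")),
            class = "random_score")
}

#' Gene-level mixed-effects GxE interaction test
#'
#' Runs the full per-gene test for one exposure: computes predicted
#' expression `T = G w`, fits the logistic null (covariates + exposure +
#' predicted expression), then the fixed-effect score test on `T * E`, the
#' residual variance-component test on the gene's SNPs, and the Fisher and
#' adaptive weighted combinations of the two component p-values.
#'
#' @param weights numeric weight vector over the gene's (harmonized)
#'   variants.
#' @param G harmonized genotype dosage matrix (n x p).
#' @param E exposure vector (complete cases only).
#' @param X covariate matrix including intercept.
#' @param Y 0/1 case status.
#' @param gene_id,chrom identifiers carried into the result.
#' @param grid weight grid for [combine_adaptive()].
#' @return An object of class `gxe_result`: one-row data.frame with
#'   `gene_id`, `chrom`, `n_snps`, `p_fixed`, `p_random`, `p_fisher`,
#'   `p_amisti`, `mixture_method`, `note`.
#' @export
misti_gene_test <- function(weights, G, E, X, Y, gene_id = "gene",
                            chrom = NA_character_,
                            grid = seq(0, 1, by = 0.1)) {
  G <- as.matrix(G)
  stopifnot(length(weights) == ncol(G))
  T_hat <- drop(G %*% weights)
  null <- fit_null_logistic(X, E, T_hat, Y)
  note <- ""
  p_fixed <- tryCatch(fixed_score_test(null)$p, error = function(e) {
    note <<- paste0("fixed: ", conditionMessage(e))
    NA_real_
  })
  rs <- tryCatch(random_score_test(null, G), error = function(e) {
    note <<- paste0(note, if (nzchar(note)) "; ", "random: ",
                    conditionMessage(e))
    NULL
  })
  p_random <- if (is.null(rs)) NA_real_ else rs$p
  if (is.na(p_fixed) || is.na(p_random)) {
    p_fisher <- p_amisti <- NA_real_
  } else {
    p_fisher <- as.numeric(combine_fisher(p_fixed, p_random))
    p_amisti <- as.numeric(combine_adaptive(p_fixed, p_random, grid = grid))
  }
  structure(data.frame(
    gene_id = gene_id, chrom = chrom, n_snps = ncol(G),
    p_fixed = p_fixed, p_random = p_random,
    p_fisher = p_fisher, p_amisti = p_amisti,
    mixture_method = if (is.null(rs)) NA_character_ else rs$method,
    note = note, stringsAsFactors = FALSE
  ), class = c("gxe_result", "data.frame"))
}
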