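#' Fit the logistic null model for the interaction score tests
#'
#' Maximum-likelihood logistic regression of case-control status on the
#' adjustment covariates, the exposure main effect and the predicted
#' expression main effect, by iteratively reweighted least squares. The
#' interaction tests are score tests against this null, so only the null
#' (no-interaction) model is ever fitted.
#'
#' @param X n x q covariate matrix including an intercept column (study
#'   indicators, age, principal components, any exposure-specific extra
#'   adjustments).
#' @param E exposure vector.
#' @param T_hat predicted expression vector (genetic value `G w`).
#' @param Y 0/1 case status.
#' @return An object of class `null_fit`: list with `coef`, `mu` (fitted
#'   probabilities), `W` (working weights `mu (1 - mu)`), design matrix
#'   `D = [X, E, T]`, `E`, `T_hat`, `Y`.
#' @export
fit_null_logistic <- function(X, E, T_hat, Y) {
  X <- as.matrix(X)
  n <- length(Y)
  stopifnot(nrow(X) == n, length(E) == n, length(T_hat) == n)
  if (!all(Y %in% c(0, 1))) stop("Y must be 0/1")
  if (stats::sd(E) == 0 || stats::sd(T_hat) == 0) {
    stop("exposure and predicted expression must be non-constant")
  }
  const_x <- apply(X, 2, function(col) stats::sd(col) == 0)
  if (!any(const_x)) stop("design must include an intercept column")
  # keep one intercept, drop further constant covariate columns
  drop_const <- which(const_x)[-1]
  if (length(drop_const)) X <- X[, -drop_const, drop = FALSE]
  D <- cbind(X, E = E, T_hat = T_hat)
  # drop linearly dependent covariate columns (aliased, as lm does);
  # rank is assessed on unit-norm columns so scale differences cannot
  # masquerade as rank deficiency
  qr_d <- qr(sweep(D, 2, sqrt(colSums(D^2)), "/"))
  if (qr_d$rank < ncol(D)) {
    keep <- qr_d$pivot[seq_len(qr_d$rank)]
    if (!all(c(ncol(D) - 1L, ncol(D)) %in% keep)) {
      stop("exposure or predicted expression is collinear with covariates")
    }
    D <- D[, sort(keep), drop = FALSE]
  }
  if (n <= ncol(D) + 5) stop("too few samples for the null design")
  fit <- suppressWarnings(
    stats::glm.fit(D, Y, family = stats::binomial(),
                   control = list(epsilon = 1e-10, maxit = 100))
  )
  if (!fit$converged) {
    stop("null logistic model failed to converge after 100 IRLS iterations")
  }
  mu <- fit$fitted.values
  eps <- 1e-10
  if (any(mu < eps | mu > 1 - eps)) {
    stop("fitted probabilities numerically 0 or 1: complete or ",
         "quasi-complete separation in the null model")
  }
  structure(list(coef = fit$coefficients, mu = mu, W = mu * (1 - mu),
                 D = D, E = E, T_hat = T_hat, Y = Y,
                 converged = fit$converged),
            class = "null_fit")
}
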