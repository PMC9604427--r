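# Null logistic fit and the two component score tests.

sim_null_design <- function(n = 2000, seed = 91) {
  withr::with_seed(seed, {
    X <- cbind(intercept = 1, study = stats::rbinom(n, 1, 0.5),
               age = stats::rnorm(n, 0, 8))  # centered age
    E <- stats::rnorm(n)
    T_hat <- stats::rnorm(n)
    Y <- stats::rbinom(n, 1, 0.5)
    list(X = X, E = E, T_hat = T_hat, Y = Y)
  })
}

test_that("null logistic fit matches glm and stays near zero under the null", {
  d <- sim_null_design()
  fit <- fit_null_logistic(d$X, d$E, d$T_hat, d$Y)
  ref <- stats::glm(d$Y ~ 0 + cbind(d$X, d$E, d$T_hat),
                    family = stats::binomial())
  expect_equal(unname(fit$coef), unname(stats::coef(ref)), tolerance = 1e-8)
  expect_lt(abs(fit$coef[["intercept"]]), 0.15)  # |logit| small, balanced null
  expect_true(all(fit$mu > 0 & fit$mu < 1))
})

test_that("known coefficients are recovered within 3 SE at n = 10000", {
  n <- 10000
  d <- withr::with_seed(92, {
    X <- cbind(intercept = 1, z = stats::rnorm(n))
    E <- stats::rnorm(n)
    T_hat <- stats::rnorm(n)
    lp <- -0.3 + 0.4 * X[, "z"] + 0.25 * E - 0.2 * T_hat
    Y <- stats::rbinom(n, 1, stats::plogis(lp))
    list(X = X, E = E, T_hat = T_hat, Y = Y)
  })
  fit <- fit_null_logistic(d$X, d$E, d$T_hat, d$Y)
  ref <- summary(stats::glm(d$Y ~ d$X[, "z"] + d$E + d$T_hat,
                            family = stats::binomial()))$coefficients
  truth <- c(-0.3, 0.4, 0.25, -0.2)
  expect_true(all(abs(unname(fit$coef) - truth) < 3 * ref[, "Std. Error"]))
})

test_that("separation and degenerate designs raise informative errors", {
  # perfectly separated toy
  X <- cbind(1, c(0, 0, 1, 1))
  expect_error(
    fit_null_logistic(X, c(0.1, 0.2, 5, 6), c(1, 2, 1, 2), c(0, 0, 1, 1)),
    "separation|too few samples"
  )
  d <- sim_null_design(n = 500, seed = 93)
  expect_error(fit_null_logistic(d$X, rep(1, 500), d$T_hat, d$Y),
               "non-constant")
  # exposure collinear with a covariate
  expect_error(fit_null_logistic(d$X, d$X[, "age"], d$T_hat, d$Y),
               "collinear")
})

test_that("fixed score test errors when the interaction column is degenerate", {
  d <- sim_null_design(n = 500, seed = 94)
  fit <- fit_null_logistic(d$X, d$E, d$T_hat, d$Y)
  expect_error(fixed_score_test(fit, T_hat = rep(0, 500)), "degenerate")
})

test_that("single-SNP fixed test equals the direct 1-df score test", {
  # cohort genotyped at 10 variants; the tested gene has a single SNP
  spec <- ld_spec(n_blocks = 1, block_size = 10, maf_low = 0.3, maf_high = 0.4,
                  seed = 95)
  pop <- simulate_ld_genotypes(3000, spec)
  w_pop <- c(0.5, rep(0, 9))
  coh <- simulate_cohort(pop, w_pop, NULL, cohort_truth(seed = 96), 600, 600)
  X <- cohort_design(coh$pheno)
  E <- coh$pheno$exposure
  Y <- coh$pheno$case_status
  g <- coh$genos$dosages[, 1]
  fit <- fit_null_logistic(X, E, 0.5 * g, Y)
  fs <- fixed_score_test(fit)

  # independent route: score test for the g*E coefficient computed from
  # first principles on the same null fit
  cc <- g * E  # proportional to T*E; the statistic is scale-invariant
  D <- cbind(X, E, 0.5 * g)
  W <- fit$W
  U <- sum(cc * (Y - fit$mu))
  V <- sum(cc^2 * W) -
    drop(t(cc * W) %*% D %*% solve(t(D) %*% (D * W), t(D) %*% (cc * W)))
  p_direct <- stats::pchisq(U^2 / V, 1, lower.tail = FALSE)
  expect_equal(fs$p, p_direct, tolerance = 1e-10)
})

test_that("random component annihilates a single SNP already carried by the burden", {
  spec <- ld_spec(n_blocks = 1, block_size = 10, maf_low = 0.3, maf_high = 0.4,
                  seed = 97)
  pop <- simulate_ld_genotypes(2000, spec)
  w_pop <- c(1, rep(0, 9))
  coh <- simulate_cohort(pop, w_pop, NULL, cohort_truth(seed = 98), 400, 400)
  X <- cohort_design(coh$pheno)
  fit <- fit_null_logistic(X, coh$pheno$exposure, coh$genos$dosages[, 1],
                           coh$pheno$case_status)
  # the gene's only SNP: its Z column is proportional to the fixed
  # interaction column, which the augmented null projects out
  expect_error(random_score_test(fit, coh$genos$dosages[, 1, drop = FALSE]),
               "degenerate")
})

test_that("p-values are invariant to exposure rescaling and study relabeling", {
  spec <- ld_spec(n_blocks = 2, block_size = 10, within_block_rho = 0.6,
                  maf_low = 0.05, maf_high = 0.5, seed = 17)
  pop <- simulate_ld_genotypes(ceiling(2.3 * 800), spec, seed = 99)
  w <- withr::with_seed(1234, {
    idx <- sample.int(20, 5); w <- numeric(20)
    w[idx] <- stats::rnorm(5, 0, 0.3); w
  })
  coh <- simulate_cohort(pop, w, NULL,
                         cohort_truth(beta_E = 0.05, beta_T = 0.1, seed = 99),
                         400, 400)
  X <- cohort_design(coh$pheno)
  Y <- coh$pheno$case_status
  base <- misti_gene_test(w, coh$genos$dosages, coh$pheno$exposure, X, Y)
  scaled <- misti_gene_test(w, coh$genos$dosages, 10 * coh$pheno$exposure,
                            X, Y)
  expect_equal(scaled$p_fixed, base$p_fixed, tolerance = 1e-6)
  expect_equal(scaled$p_random, base$p_random, tolerance = 1e-6)
  expect_equal(scaled$p_amisti, base$p_amisti, tolerance = 1e-5)

  # relabel the study factor
  ph2 <- coh$pheno
  ph2$study <- ifelse(ph2$study == "study1", "zzz", "aaa")
  X2 <- cohort_design(ph2)
  relab <- misti_gene_test(w, coh$genos$dosages, coh$pheno$exposure, X2, Y)
  expect_equal(relab$p_fixed, base$p_fixed, tolerance = 1e-6)
  expect_equal(relab$p_random, base$p_random, tolerance = 1e-6)
})
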