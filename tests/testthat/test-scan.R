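# Multiple-testing procedures, inflation diagnostics and the scan driver.

test_that("Bonferroni threshold arithmetic", {
  expect_equal(signif(bonferroni_threshold(4864, 14, 0.05), 3), 7.34e-7)
  expect_equal(bonferroni_threshold(1, 1, 0.05), 0.05)
  expect_equal(bonferroni_threshold(10, 2, 0.10), 0.005)
  expect_error(bonferroni_threshold(0, 14, 0.05))
})

test_that("BH adjustment matches a brute-force step-up oracle", {
  p <- withr::with_seed(101, stats::runif(100))
  adj <- bh_adjust(p)
  # O(m^2) evaluation of adj_(i) = min_{j >= i} m p_(j) / j
  m <- length(p)
  ord <- order(p)
  brute <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    brute[i] <- min(1, min(m * p[ord[rank_i:m]] / (rank_i:m)))
  }
  expect_equal(adj, brute, tolerance = 1e-12)
  # fixed point: all equal values stay equal
  expect_equal(bh_adjust(rep(0.07, 9)), rep(0.07, 9))
  # monotone in rank, never below the raw values
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(bh_adjust(c(0.1, 0)), "0, 1")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("step-up ties: close-ranked minima share an adjusted value", {
  # two smallest raw p with m p1 > m p2 / 2 collapse to one adjusted value
  m <- 4864
  filler <- seq(0.05, 1, length.out = m - 2)
  p <- c(3.58e-5, 6.85e-5, filler)
  adj <- bh_adjust(p)
  expect_equal(adj[1], adj[2])
  expect_equal(round(adj[1], 2), 0.17)
})

test_that("genomic inflation is calibrated and detects inflation", {
  expect_equal(genomic_inflation(rep(0.5, 50))$lambda, 1)
  p_unif <- withr::with_seed(102, stats::runif(10000))
  expect_lt(abs(genomic_inflation(p_unif)$lambda - 1), 0.05)
  # inflate chi-square statistics by 1.2
  stats_infl <- 1.2 * stats::qchisq(p_unif, 1, lower.tail = FALSE)
  p_infl <- stats::pchisq(stats_infl, 1, lower.tail = FALSE)
  expect_lt(abs(genomic_inflation(p_infl)$lambda - 1.2), 0.05)
  expect_error(genomic_inflation(rep(0.2, 5)), "at least 10")
  qq <- genomic_inflation(p_unif)$qq
  expect_equal(nrow(qq), 10000)
  expect_true(all(qq$observed >= 0))
})

test_that("scan tests every eligible gene x exposure with per-exposure BH", {
  inputs <- sim_scan_inputs(n_genes = 4, seed = 9)
  n_models <- length(inputs$models)
  expect_gte(n_models, 2)
  exposures <- list(
    exposure_spec("alcohol_gday", "continuous", scale = 10, mean = 6, sd = 8),
    exposure_spec("age_first_ftp", "continuous", scale = 5,
                  eligibility = "parous_only", mean = 25, sd = 4.6)
  )
  scan <- run_scan(inputs$models, inputs$genos, inputs$pheno, exposures)
  expect_s3_class(scan, "scan_result")
  expect_equal(nrow(scan$results), n_models * 2)
  # eligibility arithmetic: parous-only analysis n equals parous complete cases
  n_parous <- sum(inputs$pheno$parous == 1 &
                    !is.na(inputs$pheno$age_first_ftp))
  ftp <- scan$results[scan$results$exposure == "age_first_ftp", ]
  expect_true(all(ftp$n_eligible == n_parous))
  # per-exposure BH: adjusted values computed within exposure families
  alc <- scan$results[scan$results$exposure == "alcohol_gday", ]
  expect_equal(alc$fdr_adjusted, bh_adjust(alc$p_amisti))
  expect_true(all(scan$results$fdr_adjusted >= scan$results$p_amisti))
  expect_equal(scan$meta$bonferroni_threshold,
               0.05 / (n_models * 2))
})

test_that("MHT-style exposures adjust for the former-use covariate", {
  inputs <- sim_scan_inputs(n_genes = 2, seed = 12)
  ex <- exposure_spec("mht_e_current", "binary",
                      eligibility = "postmenopausal_only",
                      extra_covariates = "former_mht_e", prevalence = 0.16)
  scan <- run_scan(inputs$models, inputs$genos, inputs$pheno, list(ex))
  expect_true(nrow(scan$results) >= 1)
  # adjustment changes the null fit: dropping the covariate changes p-values
  ex_no <- exposure_spec("mht_e_current", "binary",
                         eligibility = "postmenopausal_only",
                         prevalence = 0.16)
  scan2 <- run_scan(inputs$models, inputs$genos, inputs$pheno, list(ex_no))
  expect_false(isTRUE(all.equal(scan$results$p_fixed, scan2$results$p_fixed)))
  # missing covariate column is an error
  ph3 <- inputs$pheno
  ph3$former_mht_e <- NULL
  expect_error(run_scan(inputs$models, inputs$genos, ph3, list(ex)),
               "former_mht_e")
})

test_that("scans are deterministic: identical inputs give byte-identical output", {
  inputs <- sim_scan_inputs(n_genes = 3, seed = 14)
  ex <- list(exposure_spec("height_cm", "continuous", scale = 5,
                           mean = 164, sd = 6.5))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  s1 <- run_scan(inputs$models, inputs$genos, inputs$pheno, ex)
  s2 <- run_scan(inputs$models, inputs$genos, inputs$pheno, ex)
  write_results(s1$results, f1)
  write_results(s2$results, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("tiny eligible strata are skipped with a warning record", {
  inputs <- sim_scan_inputs(n_genes = 2, seed = 15)
  ph <- inputs$pheno
  ph$rare_expo <- NA_real_
  ph$rare_expo[1:10] <- 1
  ex <- list(exposure_spec("rare_expo", "binary"))
  expect_warning(
    scan <- run_scan(inputs$models, inputs$genos, ph, ex),
    "skipped"
  )
  expect_equal(nrow(scan$results), 0)
  expect_true(any(scan$skipped$reason == "empty_or_tiny_stratum"))
})
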