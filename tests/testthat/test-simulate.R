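# Synthetic-data generator: LD structure, MAF targeting, expression
# heritability construction, exposures and the ascertained cohort sampler.

test_that("LD generator respects block structure and the rho = 0 case", {
  spec0 <- ld_spec(n_blocks = 2, block_size = 5, within_block_rho = 0,
                   maf_low = 0.2, maf_high = 0.4, seed = 21)
  g0 <- simulate_ld_genotypes(5000, spec0)
  cors <- stats::cor(g0$dosages)
  off <- abs(cors[upper.tri(cors)])
  expect_lt(max(off), 0.05)

  spec <- ld_spec(n_blocks = 2, block_size = 5, within_block_rho = 0.8,
                  maf_low = 0.2, maf_high = 0.4, seed = 22)
  g <- simulate_ld_genotypes(5000, spec)
  cors <- stats::cor(g$dosages)
  # adjacent within-block pairs are strongly correlated
  expect_gt(cors[1, 2], 0.3)
  # cross-block pairs are near zero
  cross <- abs(cors[1:5, 6:10])
  expect_lt(max(cross), 0.05)
})

test_that("empirical MAFs match the requested range", {
  spec <- ld_spec(n_blocks = 1, block_size = 30, within_block_rho = 0.5,
                  maf_low = 0.3, maf_high = 0.3, seed = 23)
  g <- simulate_ld_genotypes(5000, spec)
  expect_true(all(abs(g$variants$maf - 0.3) < 0.02))
})

test_that("generation is bit-deterministic given seeds", {
  spec <- ld_spec(seed = 31)
  a <- simulate_ld_genotypes(50, spec)
  b <- simulate_ld_genotypes(50, spec)
  expect_identical(a, b)
  # same variant grid, independent draws
  c2 <- simulate_ld_genotypes(50, spec, seed = 99)
  expect_identical(a$variants$pos, c2$variants$pos)
  expect_false(identical(a$dosages, c2$dosages))
})

test_that("expression generator hits the target heritability exactly", {
  spec <- ld_spec(n_blocks = 1, block_size = 40, seed = 41)
  g <- simulate_ld_genotypes(1000, spec)

  y0 <- simulate_expression_panel(g, expression_truth(c(3, 7), c(1, -1), 0),
                                  seed = 1)
  expect_lt(max(stats::cor(y0, g$dosages[, c(3, 7)])^2), 0.05)

  y9 <- simulate_expression_panel(g, expression_truth(5, 1, 0.99), seed = 2)
  expect_gt(summary(stats::lm(y9 ~ g$dosages[, 5]))$r.squared, 0.9)

  y5 <- simulate_expression_panel(g, expression_truth(c(1, 5, 9),
                                                      c(0.3, 0.5, -0.4), 0.5),
                                  seed = 3)
  gv <- attr(y5, "genetic_value")
  expect_equal(stats::var(gv) / stats::var(y5), 0.5, tolerance = 1e-6)
  expect_error(expression_truth(1, 1, 1), "target_h2")
})

test_that("exposure generator applies scales, prevalences and eligibility", {
  tab <- data.frame(sample_id = paste0("S", 1:10000))
  specs <- list(
    exposure_spec("binexp", "binary", prevalence = 0.5),
    exposure_spec("contexp", "continuous", scale = 5, mean = 25, sd = 5),
    exposure_spec("repro", "continuous", scale = 5, mean = 25, sd = 4,
                  eligibility = "parous_only"),
    exposure_spec("births", "ordinal", probs = c(0.2, 0.4, 0.25, 0.15))
  )
  out <- make_exposures(tab, specs, seed = 77)
  expect_lt(abs(mean(out$binexp) - 0.5), 0.02)
  # scale division is exact: same seed with scale 1 gives the raw values
  specs_raw <- specs
  specs_raw[[2]] <- exposure_spec("contexp", "continuous", scale = 1,
                                  mean = 25, sd = 5)
  out_raw <- make_exposures(tab, specs_raw, seed = 77)
  expect_identical(out$contexp, out_raw$contexp / 5)
  expect_true(all(is.na(out$repro[out$parous == 0])))
  expect_true(all(!is.na(out$repro[out$parous == 1])))
  expect_true(all(out$births %in% 1:4))
  expect_error(exposure_spec("x", "continuous", scale = 0), "scale")
})

test_that("cohort sampler fills quotas, emits orthonormal PCs and errors when unreachable", {
  spec <- ld_spec(n_blocks = 2, block_size = 10, seed = 51)
  pop <- simulate_ld_genotypes(2500, spec)
  w <- numeric(20); w[c(2, 12)] <- 0.4
  coh <- simulate_cohort(pop, w, NULL, cohort_truth(seed = 3), 500, 500)
  expect_equal(nrow(coh$pheno), 1000)
  expect_equal(sum(coh$pheno$case_status), 500)
  pcs <- as.matrix(coh$pheno[, paste0("pc", 1:5)])
  expect_equal(unname(crossprod(pcs)), diag(5), tolerance = 1e-8)
  # determinism
  coh2 <- simulate_cohort(pop, w, NULL, cohort_truth(seed = 3), 500, 500)
  expect_identical(coh$pheno, coh2$pheno)

  expect_error(
    simulate_cohort(pop, w, NULL, cohort_truth(alpha0 = -12, seed = 4),
                    1200, 100),
    "intercept"
  )
})
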