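# Weight training schemes, cross-validation and gene-model building.

test_that("all schemes find a lone causal variant without LD", {
  spec <- ld_spec(n_blocks = 1, block_size = 30, within_block_rho = 0,
                  maf_low = 0.2, maf_high = 0.5, seed = 71)
  g <- simulate_ld_genotypes(500, spec)
  y <- simulate_expression_panel(g, expression_truth(17, 1, 0.9), seed = 72)
  for (scheme in c("top1", "lasso", "enet")) {
    fit <- fit_weights(g, y, scheme, seed = 1)
    expect_equal(which.max(abs(fit$weights)), 17)
  }
})

test_that("top1 has exactly one nonzero weight; infinite penalty zeroes the lasso", {
  pan <- sim_gene_panel(n = 200, seed = 73)
  top1 <- fit_weights(pan$genos, pan$y, "top1")
  expect_equal(sum(top1$weights != 0), 1)
  shrunk <- fit_weights(pan$genos, pan$y, "lasso", lambda = Inf)
  expect_true(all(shrunk$weights == 0))
  expect_error(fit_weights(pan$genos, rep(1, 200), "enet"), "zero variance")
})

test_that("cross-validated R2 is deterministic, high for clean signal, low for noise", {
  spec <- ld_spec(n_blocks = 1, block_size = 20, within_block_rho = 0.3,
                  seed = 74)
  g <- simulate_ld_genotypes(500, spec)

  a <- cv_r2(g, simulate_expression_panel(
    g, expression_truth(3, 1, 0.5), seed = 75), "enet", seed = 4)
  b <- cv_r2(g, simulate_expression_panel(
    g, expression_truth(3, 1, 0.5), seed = 75), "enet", seed = 4)
  expect_identical(a, b)

  # near-deterministic expression
  y_clean <- simulate_expression_panel(g, expression_truth(3, 1, 0.999),
                                       seed = 76)
  expect_gt(cv_r2(g, y_clean, "enet", seed = 1), 0.98)

  # pure noise: cv R2 stays near or below zero
  r2_null <- vapply(1:10, function(r) {
    y <- simulate_expression_panel(g, expression_truth(integer(0), numeric(0),
                                                       0), seed = 100 + r)
    cv_r2(g, y, "lasso", seed = r)
  }, 0)
  expect_lt(stats::median(r2_null), 0.02)
  expect_error(cv_r2(g, y_clean, "enet", k = 501), "exceeds")
})

test_that("gene model building gates on heritability and selects the best scheme", {
  pan <- sim_gene_panel(n = 250, h2 = 0.5, seed = 77)
  ann <- list(gene_id = "g1", chrom = "1",
              start = min(pan$genos$variants$pos),
              end = max(pan$genos$variants$pos))
  m <- build_gene_model(ann, pan$genos, pan$y, seed = 5)
  expect_false(isTRUE(m$gated_out))
  expect_equal(m$cv_r2, max(m$cv_r2_all))
  expect_true(m$scheme %in% c("enet", "lasso", "top1"))
  expect_lt(m$h2est$p_value, 0.01)

  # non-heritable gene is gated out (h2 p-value >= 0.01 almost surely here)
  y_null <- withr::with_seed(78, stats::rnorm(250))
  m0 <- build_gene_model(ann, pan$genos, y_null, seed = 5)
  if (isTRUE(m0$gated_out)) {
    expect_equal(m0$reason, "h2_gate")
  } else {
    succeed("rare null passing the 1% gate")
  }

  # gene far away from all variants
  ann_far <- list(gene_id = "g2", chrom = "1", start = 9e8, end = 9.1e8)
  m_far <- build_gene_model(ann_far, pan$genos, pan$y)
  expect_true(m_far$gated_out)
  expect_equal(m_far$reason, "no_variants")
})

test_that("cis window arithmetic is +/- 500 kb clipped at 1", {
  spec <- ld_spec(n_blocks = 1, block_size = 5, seed = 79,
                  pos_start = 705000, pos_step = 1000)
  g <- simulate_ld_genotypes(60, spec)
  y <- withr::with_seed(80, stats::rnorm(60))
  m <- build_gene_model(list(gene_id = "g", chrom = "1",
                             start = 1200000, end = 1210000), g, y)
  expect_equal(m$window, c(700000, 1710000))
  m2 <- build_gene_model(list(gene_id = "g", chrom = "1",
                              start = 100, end = 200), g, y)
  expect_equal(m2$window[1], 1)

  # a panel-subset mask restricts which variants can enter the model
  pan <- sim_gene_panel(n = 250, h2 = 0.6, seed = 81)
  mask <- rep(c(TRUE, FALSE), length.out = nrow(pan$genos$variants))
  ann <- list(gene_id = "g3", chrom = "1",
              start = min(pan$genos$variants$pos),
              end = max(pan$genos$variants$pos))
  mm <- build_gene_model(ann, pan$genos, pan$y, seed = 6, panel_mask = mask)
  if (!isTRUE(mm$gated_out)) {
    expect_true(all(mm$variants$id %in% pan$genos$variants$id[mask]))
  }
})
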