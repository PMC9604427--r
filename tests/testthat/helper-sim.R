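# Shared simulation helpers for the test suite. Fixtures are built in code;
# sizes are desk-scale versions of the study design (reference panel with a
# heritable sparse cis-eQTL component; ascertained case-control cohort).

# A reference panel plus expression with known causal structure.
sim_gene_panel <- function(n = 300, n_blocks = 2, block_size = 25,
                           rho = 0.6, h2 = 0.4, n_causal = 3, seed = 1) {
  spec <- ld_spec(n_blocks = n_blocks, block_size = block_size,
                  within_block_rho = rho, seed = seed)
  genos <- simulate_ld_genotypes(n, spec)
  p <- n_blocks * block_size
  causal <- withr::with_seed(seed + 1, sample.int(p, n_causal))
  effects <- withr::with_seed(seed + 2, stats::rnorm(n_causal))
  truth <- expression_truth(causal, effects, h2)
  y <- simulate_expression_panel(genos, truth, seed = seed + 3)
  list(spec = spec, genos = genos, y = y, truth = truth, causal = causal)
}

# Cohort covariate matrix in the layout run_scan() assembles.
cohort_design <- function(pheno) {
  study <- factor(pheno$study)
  cbind(
    intercept = 1,
    if (nlevels(study) > 1) stats::model.matrix(~study)[, -1, drop = FALSE],
    age = pheno$age,
    as.matrix(pheno[, paste0("pc", 1:5)])
  )
}

# One case-control replicate and its four test p-values for a single gene.
# Under beta_TE = 0, tau = 0 this is a draw from the null.
sim_gxe_replicate <- function(seed, n_per_arm = 1000, p = 50,
                              beta_TE = 0, tau = 0, spec = NULL) {
  if (is.null(spec)) {
    spec <- ld_spec(n_blocks = 2, block_size = p / 2, within_block_rho = 0.6,
                    maf_low = 0.05, maf_high = 0.5, seed = 17)
  }
  pop_n <- ceiling(1.6 * 2 * n_per_arm)
  pop <- simulate_ld_genotypes(pop_n, spec, seed = seed)
  w <- withr::with_seed(1234, {
    idx <- sample.int(ncol(pop$dosages), 5)
    w <- numeric(ncol(pop$dosages))
    w[idx] <- stats::rnorm(5, 0, 0.3)
    w
  })
  truth <- cohort_truth(beta_E = 0.05, beta_T = 0.1, beta_TE = beta_TE,
                        tau = tau, seed = seed)
  coh <- simulate_cohort(pop, w, NULL, truth, n_per_arm, n_per_arm)
  X <- cohort_design(coh$pheno)
  res <- misti_gene_test(w, coh$genos$dosages, coh$pheno$exposure, X,
                         coh$pheno$case_status, gene_id = "g1")
  res
}

# Trained weight models over a panel of `n_genes` single-block genes laid
# out along one chromosome, plus a matching cohort. Used by scan tests.
sim_scan_inputs <- function(n_genes = 4, n_panel = 250, n_per_arm = 400,
                            block_size = 12, h2 = 0.5, seed = 9) {
  spec <- ld_spec(n_blocks = n_genes, block_size = block_size,
                  within_block_rho = 0.5, seed = seed,
                  pos_start = 1e6, pos_step = 2000)
  panel <- simulate_ld_genotypes(n_panel, spec)
  models <- list()
  for (g in seq_len(n_genes)) {
    cols <- (g - 1) * block_size + seq_len(block_size)
    causal <- cols[c(2, 5)]
    truth <- expression_truth(causal, c(0.8, -0.6), h2)
    y <- simulate_expression_panel(panel, truth, seed = seed + 10 * g)
    ann <- list(gene_id = paste0("gene", g), chrom = "1",
                start = panel$variants$pos[cols[1]],
                end = panel$variants$pos[cols[block_size]])
    m <- build_gene_model(ann, panel, y, window_kb = 1, seed = seed + g)
    if (!isTRUE(m$gated_out)) models[[m$gene_id]] <- m
  }
  pop <- simulate_ld_genotypes(ceiling(4.6 * n_per_arm), spec, seed = seed + 99)
  w_all <- numeric(ncol(pop$dosages))
  truth <- cohort_truth(seed = seed + 7)
  coh <- simulate_cohort(pop, w_all, default_exposure_specs(), truth,
                         n_per_arm, n_per_arm)
  list(models = models, genos = coh$genos, pheno = coh$pheno)
}
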