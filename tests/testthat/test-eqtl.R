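test_that("variant filters use strict 'greater-than' survival", {
  d <- matrix(c(0, 1, 2, 0, 1, 2, 0, 1), 2, 4)
  geno <- makeGeno(d)
  v <- variantInfo(geno)
  v$maf <- c(0.05, 0.051, 0.3, 0.3)
  v$call_rate <- c(1, 1, 0.95, 0.96)
  geno <- GenotypeData(dosageMatrix(geno), v)
  kept <- variantInfo(filterVariants(geno))
  # maf == 0.05 removed, call_rate == 0.95 removed
  expect_equal(kept$variant_id, c("v002", "v004"))

  v$chromosome <- "X"
  geno_x <- GenotypeData(dosageMatrix(geno), v)
  expect_warning(res <- filterVariants(geno_x), "no variants")
  expect_equal(nrow(variantInfo(res)), 0)
})

test_that("additive model matches hand OLS and handles edge cases", {
  g <- c(0, 1, 2, 0, 1, 2)
  fit <- fitAdditiveModel(2 * g, g)
  expect_equal(fit$beta, 2, tolerance = 1e-12)

  # hand-check: n = 4, Sxy/Sxx = 2/2 = 1, exact fit
  fit2 <- fitAdditiveModel(c(1, 2, 2, 3), c(0, 1, 1, 2))
  expect_equal(fit2$beta, 1, tolerance = 1e-12)
  expect_equal(fit2$df, 2)
  expect_lt(fit2$p_value, 1e-10)

  # non-degenerate hand case: residuals present
  y <- c(1, 2, 2, 3, 5, 4)
  g3 <- c(0, 0, 1, 1, 2, 2)
  fit3 <- fitAdditiveModel(y, g3)
  cf <- summary(lm(y ~ g3))$coefficients
  expect_equal(fit3$beta, cf["g3", "Estimate"], tolerance = 1e-12)
  expect_equal(fit3$se, cf["g3", "Std. Error"], tolerance = 1e-12)
  expect_equal(fit3$p_value, cf["g3", "Pr(>|t|)"], tolerance = 1e-12)

  const <- fitAdditiveModel(rnorm(10), rep(1, 10))
  expect_true(is.na(const$beta))
  expect_match(const$reason, "constant")
})

test_that("null fits are calibrated", {
  set.seed(42)
  n <- 50
  p <- replicate(2000, fitAdditiveModel(
    rnorm(n), rbinom(n, 2, 0.3))$p_value)
  # binomial bound on the rejection rate at alpha = 0.05
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 2000) + 0.002)
})

test_that("cis/trans classification uses span distance and 1 Mb inclusive", {
  r <- classifyCisTrans("chr1", 5e5, "chr1", 14e5, 145e4)
  expect_equal(r$eqtl_class, "cis")
  expect_equal(r$distance_bp, 9e5)

  # inside the span: distance 0
  r0 <- classifyCisTrans("chr1", 1.42e6, "chr1", 14e5, 145e4)
  expect_equal(r0$distance_bp, 0)

  # exactly 1 Mb away: cis (inclusive window)
  r1 <- classifyCisTrans("chr1", 4e5, "chr1", 14e5, 145e4)
  expect_equal(r1$distance_bp, 1e6)
  expect_equal(r1$eqtl_class, "cis")
  r2 <- classifyCisTrans("chr1", 4e5 - 1, "chr1", 14e5, 145e4)
  expect_equal(r2$eqtl_class, "trans")

  # different chromosome: always trans
  r3 <- classifyCisTrans("chr1", 14e5, "chr2", 14e5, 145e4)
  expect_equal(r3$eqtl_class, "trans")
})

test_that("BH q-values match the step-up formula", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(0.5), 0.5)
  p <- c(0.001, 0.2, 0.04, 0.9, 0.015)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bhFdr(p)[perm], bhFdr(p[perm]))
  expect_warning(q <- bhFdr(c(0.1, NA)), "NA")
  expect_true(is.na(q[2]))
  expect_error(bhFdr(c(0.5, 1.2)), "0, 1")
})

test_that("matrix scan equals per-pair OLS and covers all pairs", {
  cfg <- simConfig(n_samples = 60, n_variants = 20, n_genes = 10,
                   n_cis_pairs = 3, hotspot_n_targets = 2, seed = 17)
  genome <- simulateGenome(cfg)
  geno <- simulateGenotypes(genome$variants, cfg)
  ex <- simulateExpression(geno, genome$genes, cfg)
  cov <- ex$covariates
  eq <- mapEqtl(geno, ex$expression, genome$genes, cov)
  expect_equal(nrow(eq), 20 * 10)

  set.seed(1)
  for (i in sample.int(nrow(eq), 20)) {
    fit <- fitAdditiveModel(
      ex$expression[eq$gene_id[i], ],
      dosageMatrix(geno)[, eq$variant_id[i]],
      cov[, c("contemporary_group", "lane", "age")])
    expect_equal(eq$beta[i], fit$beta, tolerance = 1e-10)
    expect_equal(eq$se[i], fit$se, tolerance = 1e-10)
    expect_equal(eq$p_value[i], fit$p_value, tolerance = 1e-10)
  }
})

test_that("adding an orthogonal covariate leaves the slope unchanged", {
  set.seed(7)
  n <- 64
  g <- rbinom(n, 2, 0.4)
  y <- 0.5 * g + rnorm(n)
  base <- fitAdditiveModel(y, g)
  # construct a covariate orthogonal to both g and y (and the intercept)
  z <- rnorm(n)
  z <- residuals(lm(z ~ g + y))
  withcov <- fitAdditiveModel(y, g, data.frame(z = z))
  expect_lt(abs(base$beta - withcov$beta), 1e-8)
})

test_that("sample misalignment is a hard error naming ids", {
  cfg <- simConfig(n_samples = 20, n_variants = 10, n_genes = 5,
                   hotspot_n_targets = 0, seed = 1)
  genome <- simulateGenome(cfg)
  geno <- simulateGenotypes(genome$variants, cfg)
  ex <- simulateExpression(geno, genome$genes, cfg)
  expr_bad <- ex$expression
  colnames(expr_bad)[1] <- "intruder"
  expect_error(mapEqtl(geno, expr_bad, genome$genes), "intruder")
})

test_that("planted cis effects are recovered with the right sign", {
  cfg <- simConfig(n_samples = 300, n_variants = 60, n_genes = 30,
                   n_cis_pairs = 8, cis_beta = 1, noise_sd = 1,
                   hotspot_n_targets = 0, seed = 23)
  genome <- simulateGenome(cfg)
  geno <- simulateGenotypes(genome$variants, cfg)
  ex <- simulateExpression(geno, genome$genes, cfg)
  eq <- mapEqtl(geno, ex$expression, genome$genes, ex$covariates)
  tr <- ex$truth$cis_truth
  idx <- match(paste(tr$variant_id, tr$gene_id),
               paste(eq$variant_id, eq$gene_id))
  expect_true(all(eq$significant[idx]))
  expect_true(all(eq$beta[idx] > 0))
  expect_true(all(eq$eqtl_class[idx] == "cis"))
})
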