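test_that("genome simulation is sorted, deterministic and size-checked", {
  cfg <- simConfig(n_chromosomes = 1, n_variants = 10, n_genes = 5,
                   hotspot_n_targets = 2, seed = 3)
  g1 <- simulateGenome(cfg)
  expect_equal(nrow(g1$variants), 10)
  expect_true(all(g1$variants$chromosome == "chr1"))
  expect_false(is.unsorted(g1$variants$position, strictly = TRUE))
  expect_true(all(g1$genes$start < g1$genes$end))

  g2 <- simulateGenome(cfg)
  expect_identical(g1, g2)

  tiny <- simConfig(n_chromosomes = 1, chrom_length_bp = 50,
                    n_variants = 100, seed = 1)
  expect_error(simulateGenome(tiny), "too short")
})

test_that("config invariants are enforced", {
  expect_error(simConfig(n_samples = 0), "count")
  expect_error(simConfig(ld_copy_prob = 1.2), "probability")
  expect_error(simConfig(noise_sd = 0), "noise_sd")
  expect_error(simConfig(maf_range = c(0, 0.5)), "maf_range")
  expect_error(simConfig(hotspot_n_targets = 500, n_genes = 100),
               "exceed")
})

test_that("LD copying produces the expected adjacent-variant correlation", {
  # perfect copying: every variant on a chromosome is identical
  cfg1 <- simConfig(n_samples = 100, n_chromosomes = 1, n_variants = 10,
                    ld_copy_prob = 1, seed = 11)
  geno1 <- simulateGenotypes(simulateGenome(cfg1)$variants, cfg1)
  d <- dosageMatrix(geno1)
  for (j in 2:10) expect_equal(ldR2(d[, j - 1], d[, j]), 1)

  # no copying: adjacent squared correlation has expectation ~ 1/n
  cfg0 <- simConfig(n_samples = 2000, n_chromosomes = 1, n_variants = 201,
                    ld_copy_prob = 0, seed = 12)
  geno0 <- simulateGenotypes(simulateGenome(cfg0)$variants, cfg0)
  d0 <- dosageMatrix(geno0)
  r2 <- vapply(2:201, function(j) ldR2(d0[, j - 1], d0[, j]), 1)
  expect_gt(mean(r2), 0.2 / 2000)   # 200 replicate pairs around 1/n
  expect_lt(mean(r2), 5 / 2000)
})

test_that("allele frequencies respect the configured MAF range", {
  cfg <- simConfig(n_samples = 500, n_chromosomes = 1, n_variants = 50,
                   maf_range = c(0.5, 0.5), ld_copy_prob = 0.5, seed = 5)
  geno <- simulateGenotypes(simulateGenome(cfg)$variants, cfg)
  af <- colMeans(dosageMatrix(geno)) / 2
  # exact binomial bounds on 2n = 1000 draws at p = 0.5 (central 0.9999)
  ci <- qbinom(c(5e-5, 1 - 5e-5), 1000, 0.5) / 1000
  expect_true(all(af >= ci[1] & af <= ci[2]))
})

test_that("noiseless cis construction returns the planted slope exactly", {
  cfg <- simConfig(n_samples = 60, n_variants = 30, n_genes = 20,
                   n_chromosomes = 1, chrom_length_bp = 2e6,
                   n_cis_pairs = 5, cis_beta = 2, noise_sd = 1e-9,
                   hotspot_n_targets = 0, seed = 21)
  genome <- simulateGenome(cfg)
  geno <- simulateGenotypes(genome$variants, cfg)
  ex <- simulateExpression(geno, genome$genes, cfg)
  tr <- ex$truth$cis_truth
  expect_equal(nrow(tr), 5)
  for (i in seq_len(nrow(tr))) {
    fit <- fitAdditiveModel(ex$expression[tr$gene_id[i], ],
                            dosageMatrix(geno)[, tr$variant_id[i]],
                            ex$covariates[, c("contemporary_group",
                                              "lane", "age")])
    expect_equal(fit$beta, 2, tolerance = 1e-6)
  }
})

test_that("truth bundle structure matches the configuration", {
  cfg <- simConfig(n_samples = 50, hotspot_n_targets = 12, n_genes = 60,
                   n_variants = 60, seed = 8)
  sim <- simulateStudy(cfg)
  expect_length(sim$truth$hotspot_targets, 12)
  expect_false(anyDuplicated(sim$truth$hotspot_targets) > 0)
  expect_true(all(sim$truth$hotspot_targets %in% sim$genes$gene_id))
  expect_true(sim$truth$hotspot_variant %in%
                variantInfo(sim$genotypes)$variant_id)
  expect_length(sim$truth$trait_loadings, cfg$n_traits)
})

test_that("phenotype simulation is deterministic and loading-sensitive", {
  cfg0 <- simConfig(n_samples = 300, trait_loading = 0, seed = 31)
  sim0 <- simulateStudy(cfg0)
  # planted-group mean expression against an unloaded trait: null corr
  adj <- adjustPhenotype(sim0$phenotypes$trait01,
                         sim0$covariates[, c("contemporary_group",
                                             "lane", "age")])
  gs <- colMeans(t(scale(t(
    sim0$expression[sim0$truth$hotspot_targets, ]))))
  expect_lt(abs(cor(adj, gs)), 4 / sqrt(300))

  cfg1 <- simConfig(n_samples = 300, trait_loading = 5, seed = 31)
  sim1 <- simulateStudy(cfg1)
  adj1 <- adjustPhenotype(sim1$phenotypes$trait01,
                          sim1$covariates[, c("contemporary_group",
                                              "lane", "age")])
  gs1 <- colMeans(t(scale(t(
    sim1$expression[sim1$truth$hotspot_targets, ]))))
  # expression carries the shared covariate shift too; compare on the
  # covariate-adjusted scale on both sides
  gs1_adj <- adjustPhenotype(gs1, sim1$covariates[, c("contemporary_group",
                                                      "lane", "age")])
  expect_gt(abs(cor(adj1, gs1_adj)), 0.5)

  rerun <- simulateStudy(cfg1)
  expect_identical(sim1$phenotypes, rerun$phenotypes)
})

test_that("promoter simulation plants recoverable motifs at 1500 bp", {
  cfg <- simConfig(n_samples = 20, n_genes = 30, n_variants = 30,
                   hotspot_n_targets = 5, motif_plant_fraction = 1,
                   seed = 41)
  genome <- simulateGenome(cfg)
  # consensus-only PFM: the planted occurrence is the exact consensus
  counts <- matrix(0, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[cbind(c(1, 2, 3, 4, 1, 3), 1:6)] <- 10
  pssm <- pfmToPssm(counts, pseudocount = 0.25)
  prom <- simulatePromoters(genome$genes, pfmToPssm(counts, 0),
                            cfg, target_genes = genome$genes$gene_id[1:10])
  expect_true(all(Biostrings::width(prom$promoters) == 1500))
  expect_equal(nrow(prom$placements), 10)
  scan <- scanPromoters(pssm, prom$promoters, p_threshold = 1 / 4^6 + 1e-9)
  expect_true(all(prom$placements$gene_id %in% scan$hits$gene_id))
  # planted offsets are reported at the recorded location and strand
  key_hits <- paste(scan$hits$gene_id, scan$hits$offset, scan$hits$strand)
  key_truth <- paste(prom$placements$gene_id, prom$placements$offset,
                     prom$placements$strand)
  expect_true(all(key_truth %in% key_hits))

  expect_error(simulatePromoters(genome$genes, pssm, cfg,
                                 promoter_length = 3),
               "longer than")
})
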