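.pipelineDefaults <- function() list(
  simulate = TRUE,
  seed = 1L,
  # generator (see simConfig for meanings)
  n_samples = 300L, n_chromosomes = 3L, chrom_length_bp = 1e7,
  n_variants = 300L, n_genes = 150L, maf_range = c(0.1, 0.5),
  ld_copy_prob = 0.9, n_cis_pairs = 20L, cis_beta = 1,
  hotspot_n_targets = 40L, hotspot_beta = 1, target_gamma = 1,
  noise_sd = 1, n_contemporary_groups = 4L, n_lanes = 3L,
  age_range = c(1.5, 3), n_traits = 15L, trait_loading = 2,
  motif_plant_fraction = 1,
  # analysis settings
  min_call_rate = 0.95, min_maf = 0.05,
  fdr = 0.05, cis_window_bp = 1e6,
  n_perm = 1000L, hotspot_quantile = 0.95, r2_merge = 0.5,
  hotspot_half_width_bp = 2e6,
  overlap_n_perm = 1000L,
  tfbs_p_threshold = 0.05, promoter_length = 1500L,
  soft_power = 6L, min_module_size = 30L, deep_split = 2L,
  merge_height = 0.25, scale_quantile = 0.95,
  module_min_traits = 3L, module_p_threshold = 0.1, n_hubs = 20L,
  enrich_fdr = 0.05,
  # externally supplied inputs when simulate = FALSE
  genotype_path = NULL, genotype_format = "vcf", expression_path = NULL,
  genes_path = NULL, covariates_path = NULL, phenotypes_path = NULL,
  regions_path = NULL, promoters_path = NULL, pfm_path = NULL,
  gmt_path = NULL)

#' Validate a pipeline configuration
#'
#' Fills defaults, type- and range-checks every parameter and rejects
#' unknown keys. With `simulate = FALSE` all input paths must be set.
#'
#' @param config named list of overrides (empty list = all defaults).
#' @return validated config list of class `PipelineConfig`.
#' @export
validateConfig <- function(config = list()) {
  defaults <- .pipelineDefaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  probs <- c("ld_copy_prob", "motif_plant_fraction", "min_call_rate",
             "min_maf", "fdr", "hotspot_quantile", "r2_merge",
             "tfbs_p_threshold", "scale_quantile", "module_p_threshold",
             "enrich_fdr")
  bad <- character()
  for (nm in probs)
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 0 || cfg[[nm]] > 1)
      bad <- c(bad, paste0(nm, " must lie in [0, 1]"))
  if (cfg$hotspot_quantile >= 1 || cfg$hotspot_quantile <= 0)
    bad <- c(bad, "hotspot_quantile must lie strictly inside (0, 1)")
  counts <- c("n_samples", "n_variants", "n_genes", "n_traits", "n_perm",
              "overlap_n_perm", "min_module_size", "n_hubs")
  for (nm in counts)
    if (cfg[[nm]] < 1) bad <- c(bad, paste0(nm, " must be >= 1"))
  if (!cfg$deep_split %in% 0:4) bad <- c(bad, "deep_split must be in 0..4")
  if (length(bad)) stop("config validation failed:\n  ",
                        paste(bad, collapse = "\n  "))
  if (!isTRUE(cfg$simulate)) {
    need <- c("genotype_path", "expression_path", "genes_path",
              "covariates_path", "phenotypes_path", "regions_path",
              "promoters_path", "pfm_path", "gmt_path")
    miss <- need[vapply(need, function(nm) is.null(cfg[[nm]]), TRUE)]
    if (length(miss))
      stop("simulate = FALSE but input path(s) missing: ",
           paste(miss, collapse = ", "))
  }
  class(cfg) <- "PipelineConfig"
  cfg
}

.md5 <- function(paths) {
  h <- tools::md5sum(paths)
  setNames(as.vector(h), basename(names(h)))
}

#' Run the full analysis pipeline
#'
#' Executes all stages in dependency order -- simulate (or load), filter,
#' eQTL scan, hotspot calling, region-overlap test, hotspot-phenotype
#' ANOVA, promoter TFBS scan, genotype-stratified co-expression networks
#' with module-trait correlation and hub genes, and gene-set enrichment --
#' writing each stage's outputs under `out_dir` plus a manifest with file
#' checksums and the child seed of every stochastic stage. Rerunning with
#' the same config and seed reproduces identical checksums.
#'
#' @param config a [validateConfig()] result or a plain list of overrides.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly (list: config, stages, files, checksums).
#' @export
runPipeline <- function(config = list(), out_dir = tempfile("eqtl_run_")) {
  if (!inherits(config, "PipelineConfig")) config <- validateConfig(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config), stages = list())
  emit <- function(stage, files, extra = list()) {
    manifest$stages[[stage]] <<- c(list(files = basename(files),
                                        md5 = .md5(files)), extra)
  }
  fp <- function(...) file.path(out_dir, ...)

  ## stage 1: inputs ---------------------------------------------------
  if (isTRUE(config$simulate)) {
    sim_cfg <- simConfig(
      n_samples = config$n_samples, n_chromosomes = config$n_chromosomes,
      chrom_length_bp = config$chrom_length_bp,
      n_variants = config$n_variants, n_genes = config$n_genes,
      maf_range = config$maf_range, ld_copy_prob = config$ld_copy_prob,
      n_cis_pairs = config$n_cis_pairs, cis_beta = config$cis_beta,
      hotspot_n_targets = config$hotspot_n_targets,
      hotspot_beta = config$hotspot_beta,
      target_gamma = config$target_gamma, noise_sd = config$noise_sd,
      n_contemporary_groups = config$n_contemporary_groups,
      n_lanes = config$n_lanes, age_range = config$age_range,
      n_traits = config$n_traits, trait_loading = config$trait_loading,
      motif_plant_fraction = config$motif_plant_fraction,
      seed = config$seed)
    sim <- simulateStudy(sim_cfg)
    writeGenotypesVcf(sim$genotypes, fp("genotypes.vcf"))
    writeGenesGff3(sim$genes, fp("genes.gff3"))
    writeExpressionTsv(sim$expression, fp("expression.tsv"))
    writeSampleTsv(sim$covariates, fp("covariates.tsv"))
    writeSampleTsv(sim$phenotypes, fp("phenotypes.tsv"))
    writeRegionsBed(sim$regions, fp("known_qtl.bed"))
    Biostrings::writeXStringSet(sim$promoters, fp("promoters.fasta"))
    writeGmt(sim$gene_sets, fp("gene_sets.gmt"))
    jsonlite::write_json(
      list(cis_truth = sim$truth$cis_truth,
           hotspot_variant = sim$truth$hotspot_variant,
           tf_gene = sim$truth$tf_gene,
           hotspot_targets = sim$truth$hotspot_targets),
      fp("truth.json"), auto_unbox = TRUE, digits = NA)
    emit("simulate", fp(c("genotypes.vcf", "genes.gff3", "expression.tsv",
                          "covariates.tsv", "phenotypes.tsv",
                          "known_qtl.bed", "promoters.fasta",
                          "gene_sets.gmt", "truth.json")),
         list(seed = config$seed))
    geno <- sim$genotypes; genes <- sim$genes
    expression <- sim$expression; covariates <- sim$covariates
    phenotypes <- sim$phenotypes; regions <- sim$regions
    promoters <- sim$promoters; pssm <- sim$pssm
    gene_sets <- sim$gene_sets
  } else {
    geno <- readGenotypes(config$genotype_path, config$genotype_format)
    genes <- readGenesGff3(config$genes_path)
    expression <- readExpressionTsv(config$expression_path)
    covariates <- readSampleTsv(config$covariates_path)
    phenotypes <- readSampleTsv(config$phenotypes_path)
    regions <- readRegionsBed(config$regions_path)
    promoters <- Biostrings::readDNAStringSet(config$promoters_path)
    pssm <- pfmToPssm(readPfmJaspar(config$pfm_path))
    gene_sets <- readGmt(config$gmt_path)
  }
  if (isTRUE(config$simulate)) {
    chrom_lengths <- setNames(rep(config$chrom_length_bp,
                                  config$n_chromosomes),
                              paste0("chr", seq_len(config$n_chromosomes)))
  } else {
    # best available bound when no assembly is given: the largest observed
    # coordinate per chromosome across variants, genes and regions
    coord <- rbind(
      data.frame(chr = variantInfo(geno)$chromosome,
                 pos = variantInfo(geno)$position),
      data.frame(chr = genes$chromosome, pos = genes$end),
      data.frame(chr = as.character(GenomicRanges::seqnames(regions)),
                 pos = GenomicRanges::end(regions)))
    chrom_lengths <- tapply(coord$pos, coord$chr, max)
  }

  ## stage 2: variant filtering ----------------------------------------
  geno_f <- filterVariants(geno, config$min_call_rate, config$min_maf)
  writeDosageTsv(geno_f, fp("genotypes_filtered.tsv"))
  emit("filter", fp("genotypes_filtered.tsv"),
       list(n_kept = ncol(dosageMatrix(geno_f))))

  ## stage 3: eQTL scan -------------------------------------------------
  eqtls <- mapEqtl(geno_f, expression, genes, covariates,
                   fdr = config$fdr, cis_window_bp = config$cis_window_bp)
  cols <- c("variant_id", "gene_id", "beta", "se", "t_stat", "p_value",
            "q_value", "distance_bp")
  sig <- eqtls[which(eqtls$significant), ]
  write.table(sig[sig$eqtl_class == "cis", cols], fp("eqtls_cis.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sig[sig$eqtl_class == "trans", cols], fp("eqtls_trans.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  emit("map_eqtl", fp(c("eqtls_cis.tsv", "eqtls_trans.tsv")),
       list(n_cis = sum(sig$eqtl_class == "cis"),
            n_trans = sum(sig$eqtl_class == "trans")))

  ## stage 4: hotspots ---------------------------------------------------
  hs_seed <- .childSeed(config$seed, 11)
  hs <- callHotspots(eqtls, geno_f, n_perm = config$n_perm,
                     quantile = config$hotspot_quantile, seed = hs_seed,
                     r2_merge = config$r2_merge,
                     half_width_bp = config$hotspot_half_width_bp,
                     chrom_lengths = chrom_lengths)
  hs_tab <- hs$calls
  if (nrow(hs_tab)) {
    flat <- hs_tab
    flat$target_genes <- vapply(flat$target_genes, paste, "",
                                collapse = ",")
  } else flat <- data.frame()
  write.table(flat, fp("hotspots.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (nrow(hs_tab))
    writeRegionsBed(GenomicRanges::GRanges(
      hs_tab$chromosome,
      IRanges::IRanges(hs_tab$window_start, hs_tab$window_end)),
      fp("hotspot_windows.bed"))
  else writeLines(character(), fp("hotspot_windows.bed"))
  emit("hotspots", fp(c("hotspots.tsv", "hotspot_windows.bed")),
       list(threshold = hs$threshold, n_hotspots = nrow(hs_tab),
            seed = hs_seed))

  ## stage 5: overlap test -----------------------------------------------
  ov <- NULL
  if (nrow(hs_tab)) {
    windows <- GenomicRanges::GRanges(
      hs_tab$chromosome,
      IRanges::IRanges(hs_tab$window_start, hs_tab$window_end))
    ov_seed <- .childSeed(config$seed, 12)
    ov <- permutationOverlapTest(windows, regions, chrom_lengths,
                                 n_perm = config$overlap_n_perm,
                                 seed = ov_seed)
    jsonlite::write_json(unclass(ov), fp("overlap.json"),
                         auto_unbox = TRUE, digits = NA)
    emit("overlap", fp("overlap.json"),
         list(p_value = ov$p_value, seed = ov_seed))
  }

  ## stage 6: hotspot-phenotype ANOVA ------------------------------------
  assoc <- NULL
  if (nrow(hs_tab)) {
    assoc <- hotspotPhenotypeAssoc(hs_tab, geno_f, phenotypes, covariates)
    write.table(assoc, fp("hotspot_assoc.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    emit("assoc", fp("hotspot_assoc.tsv"),
         list(n_significant = sum(assoc$q_value <= config$fdr)))
  }

  ## stage 7: TFBS scan ---------------------------------------------------
  scan <- scanPromoters(pssm, promoters, config$tfbs_p_threshold)
  write.table(scan$hits, fp("tfbs_hits.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  gene_summary <- data.frame(gene_id = names(scan$gene_has_hit),
                             has_hit = scan$gene_has_hit)
  write.table(gene_summary, fp("tfbs_gene_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  hit_fraction <- NA_real_
  if (nrow(hs_tab) && length(hs_tab$target_genes[[1]]))
    hit_fraction <- targetHitFraction(scan$gene_has_hit,
                                      hs_tab$target_genes[[1]])
  emit("scan_tfbs", fp(c("tfbs_hits.tsv", "tfbs_gene_summary.tsv")),
       list(target_hit_fraction = hit_fraction))

  ## stage 8: stratified co-expression networks ---------------------------
  network <- NULL
  if (nrow(hs_tab)) {
    anchor <- hs_tab$anchor_variant[1]
    groups <- splitByGenotype(dosageMatrix(geno_f)[, anchor])
    # correlation-based stages run on covariate-adjusted expression and
    # covariate-adjusted phenotypes
    expr_net <- adjustExpression(expression, covariates)
    adj_traits <- phenotypes
    for (tr in setdiff(names(phenotypes), "sample_id"))
      adj_traits[[tr]] <- adjustPhenotype(phenotypes[[tr]], covariates)
    network <- list(anchor = anchor)
    ref_group <- if (length(groups$AA) >= length(groups$AB)) "AA" else "AB"
    nets <- list()
    for (gname in c("AA", "AB")) {
      ids <- groups[[gname]]
      if (length(ids) < 4) next
      nets[[gname]] <- buildNetwork(
        expr_net[, ids, drop = FALSE], config$soft_power,
        config$min_module_size, config$deep_split, config$merge_height)
    }
    # make the smaller group's TOM comparable to the reference group's
    if (length(nets) == 2) {
      small <- setdiff(c("AA", "AB"), ref_group)
      sc <- scaleTom(nets[[small]]$tom, nets[[ref_group]]$tom,
                     config$scale_quantile)
      nets[[small]]$tom_scaled <- sc$tom
      nets[[small]]$scale_exponent <- sc$exponent
    }
    files <- character()
    for (gname in names(nets)) {
      ms <- nets[[gname]]$modules
      ids <- groups[[gname]]
      lab_file <- fp(paste0("modules_", gname, ".tsv"))
      write.table(data.frame(gene_id = names(moduleLabels(ms)),
                             module = moduleLabels(ms)),
                  lab_file, sep = "\t", quote = FALSE, row.names = FALSE)
      ev_file <- fp(paste0("eigengenes_", gname, ".tsv"))
      write.table(data.frame(module = rownames(eigengenes(ms)),
                             eigengenes(ms), check.names = FALSE),
                  ev_file, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, lab_file, ev_file)
      tm <- as.matrix(adj_traits[match(ids, adj_traits$sample_id),
                                 setdiff(names(adj_traits), "sample_id")])
      if (nrow(eigengenes(ms)) >= 1 && length(ids) >= 4) {
        mtc <- moduleTraitCorrelation(ms, tm)
        mt_file <- fp(paste0("module_trait_", gname, ".tsv"))
        mt_tab <- data.frame(module = rep(rownames(mtc$r),
                                          ncol(mtc$r)),
                             trait = rep(colnames(mtc$r),
                                         each = nrow(mtc$r)),
                             r = as.vector(mtc$r), p = as.vector(mtc$p))
        write.table(mt_tab, mt_file, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        files <- c(files, mt_file)
        nets[[gname]]$module_trait <- mtc
        nets[[gname]]$selected <- selectTraitModules(
          mtc, config$module_min_traits, config$module_p_threshold)
      }
      hubs <- lapply(rownames(eigengenes(ms)), function(m) {
        members <- names(moduleLabels(ms))[moduleLabels(ms) == m]
        mm <- moduleMembership(expr_net[members, ids, drop = FALSE],
                               eigengenes(ms)[m, ])
        data.frame(module = m,
                   gene_id = selectHubGenes(mm, config$n_hubs))
      })
      hub_file <- fp(paste0("hubs_", gname, ".tsv"))
      write.table(do.call(rbind, hubs), hub_file, sep = "\t",
                  quote = FALSE, row.names = FALSE)
      files <- c(files, hub_file)
    }
    network$groups <- nets
    emit("network", files,
         list(anchor = anchor,
              n_modules = vapply(nets, function(x)
                nrow(eigengenes(x$modules)), 1L)))

    ## stage 9: enrichment -------------------------------------------------
    enr_rows <- list()
    for (gname in names(nets)) {
      sel <- nets[[gname]]$selected
      if (!length(sel)) next
      labs <- moduleLabels(nets[[gname]]$modules)
      er <- enrichModules(labs, sel, gene_sets, fdr = config$enrich_fdr)
      if (nrow(er)) er$genotype_group <- gname
      enr_rows[[gname]] <- er
    }
    enr <- do.call(rbind, enr_rows)
    if (!is.null(enr) && nrow(enr)) {
      write.table(enr, fp("enrichment.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      emit("enrich", fp("enrichment.tsv"),
           list(n_significant = sum(enr$significant)))
    }
    network$enrichment <- enr
  }

  manifest$results <- list(
    eqtls = eqtls, hotspots = hs, overlap = ov, assoc = assoc,
    tfbs_target_hit_fraction = hit_fraction, network = network,
    truth = if (isTRUE(config$simulate)) sim$truth else NULL)
  manifest$out_dir <- out_dir
  json_manifest <- list(
    config = unclass(config),
    stages = lapply(manifest$stages, function(s)
      s[setdiff(names(s), "files")]))
  jsonlite::write_json(json_manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
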