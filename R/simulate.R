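#' Simulation configuration
#'
#' Defines the synthetic study: a diploid cohort genotyped on LD-structured
#' biallelic variants, a gene expression matrix with planted cis effects and
#' one transcription-factor-mediated trans hotspot, categorical/numeric
#' covariates (contemporary group, sequencing lane, age), traits coupled to
#' the hotspot-target gene group, and promoter sequences with planted motif
#' occurrences. Defaults describe a desk-scale cohort: 300 samples, 3
#' chromosomes, 300 variants, 150 genes, cis effect 1 expression unit per
#' dosage unit against unit residual noise.
#'
#' @param n_samples number of diploid samples.
#' @param n_chromosomes number of autosomes.
#' @param chrom_length_bp chromosome length in bp (shared by all).
#' @param n_variants total number of variants (spread round-robin over
#'   chromosomes).
#' @param n_genes total number of genes.
#' @param maf_range interval in (0, 0.5] for alternate-allele frequencies.
#' @param ld_copy_prob probability that a haplotype copies its previous
#'   variant's allele (first-order Markov LD); 0 = linkage equilibrium.
#' @param n_cis_pairs number of planted cis variant-gene pairs.
#' @param cis_beta cis effect, expression units per dosage unit.
#' @param hotspot_n_targets number of genes regulated by the hotspot TF.
#' @param hotspot_beta effect of the hotspot variant on TF expression.
#' @param target_gamma target-gene response per (centred) TF expression unit.
#' @param noise_sd residual standard deviation of expression and traits.
#' @param n_contemporary_groups,n_lanes numbers of factor levels.
#' @param age_range age interval in years (uniform).
#' @param n_traits number of phenotypes.
#' @param trait_loading trait response per unit of the planted gene group's
#'   mean standardised expression.
#' @param motif_plant_fraction fraction of hotspot-target promoters that
#'   receive a planted motif occurrence.
#' @param seed master seed; child seeds for each generator are derived from
#'   it by fixed offsets, so every generator is a pure function of
#'   (config, seed).
#' @return A validated `SimConfig` list.
#' @export
simConfig <- function(n_samples = 300, n_chromosomes = 3,
                      chrom_length_bp = 1e7, n_variants = 300,
                      n_genes = 150, maf_range = c(0.1, 0.5),
                      ld_copy_prob = 0.9, n_cis_pairs = 20, cis_beta = 1,
                      hotspot_n_targets = 40, hotspot_beta = 1,
                      target_gamma = 1, noise_sd = 1,
                      n_contemporary_groups = 4, n_lanes = 3,
                      age_range = c(1.5, 3), n_traits = 15,
                      trait_loading = 2, motif_plant_fraction = 1,
                      seed = 1L) {
  cfg <- list(n_samples = n_samples, n_chromosomes = n_chromosomes,
              chrom_length_bp = chrom_length_bp, n_variants = n_variants,
              n_genes = n_genes, maf_range = maf_range,
              ld_copy_prob = ld_copy_prob, n_cis_pairs = n_cis_pairs,
              cis_beta = cis_beta, hotspot_n_targets = hotspot_n_targets,
              hotspot_beta = hotspot_beta, target_gamma = target_gamma,
              noise_sd = noise_sd,
              n_contemporary_groups = n_contemporary_groups,
              n_lanes = n_lanes, age_range = age_range,
              n_traits = n_traits, trait_loading = trait_loading,
              motif_plant_fraction = motif_plant_fraction,
              seed = as.integer(seed))
  counts <- c("n_samples", "n_chromosomes", "n_variants", "n_genes",
              "n_contemporary_groups", "n_lanes", "n_traits")
  for (nm in counts)
    if (length(cfg[[nm]]) != 1 || cfg[[nm]] < 1)
      stop("config field '", nm, "' must be a count >= 1")
  if (cfg$n_cis_pairs < 0 || cfg$hotspot_n_targets < 0)
    stop("planted-effect counts must be >= 0")
  for (nm in c("ld_copy_prob", "motif_plant_fraction"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop("config field '", nm, "' must be a probability in [0, 1]")
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must be an interval within (0, 0.5]")
  if (cfg$hotspot_n_targets > cfg$n_genes)
    stop("hotspot_n_targets must not exceed n_genes")
  class(cfg) <- "SimConfig"
  cfg
}

## child seeds: fixed offsets from the master seed, kept below 2^31
.childSeed <- function(seed, offset)
  as.integer((as.numeric(seed) + 77003 * offset) %% 2147483647)

#' Simulate variant and gene coordinates
#'
#' Variants and genes are spread round-robin over chromosomes; positions are
#' sampled without replacement, so positions are strictly increasing within
#' each chromosome. Gene spans are non-degenerate 1-based inclusive
#' intervals.
#'
#' @param config a [simConfig()] object.
#' @return list with `variants` (variant_id, chromosome, position, ref, alt)
#'   and `genes` (gene_id, chromosome, start, end, strand) data.frames.
#' @export
simulateGenome <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(.childSeed(config$seed, 1))
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  v_chr <- rep(chroms, length.out = config$n_variants)
  g_chr <- rep(chroms, length.out = config$n_genes)
  max_gene_len <- 5000L
  per_chrom_v <- table(factor(v_chr, levels = chroms))
  per_chrom_g <- table(factor(g_chr, levels = chroms))
  if (any(per_chrom_v > config$chrom_length_bp))
    stop("chromosome too short (", config$chrom_length_bp,
         " bp) to place ", max(per_chrom_v), " variants")
  if (any(per_chrom_g * max_gene_len > config$chrom_length_bp))
    stop("chromosome too short to place ", max(per_chrom_g), " genes")
  bases <- c("A", "C", "G", "T")
  variants <- do.call(rbind, lapply(chroms, function(ch) {
    n <- per_chrom_v[[ch]]
    if (n == 0) return(NULL)
    pos <- sort(sample.int(config$chrom_length_bp, n))
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
    data.frame(chromosome = ch, position = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  }))
  variants <- data.frame(
    variant_id = sprintf("rs%06d", seq_len(nrow(variants))),
    variants, stringsAsFactors = FALSE)
  genes <- do.call(rbind, lapply(chroms, function(ch) {
    n <- per_chrom_g[[ch]]
    if (n == 0) return(NULL)
    # place gene starts on a grid so spans never collide with chromosome end
    start <- sort(sample.int(config$chrom_length_bp - max_gene_len, n))
    len <- sample(500:max_gene_len, n, replace = TRUE)
    data.frame(chromosome = ch, start = start, end = start + len - 1L,
               strand = sample(c("+", "-"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  genes <- data.frame(gene_id = sprintf("gene%05d", seq_len(nrow(genes))),
                      genes, stringsAsFactors = FALSE)
  list(variants = variants, genes = genes)
}

#' Simulate genotype dosages with first-order Markov LD
#'
#' Two haplotypes per sample; along each chromosome a haplotype copies its
#' previous allele with probability `ld_copy_prob`, otherwise draws a fresh
#' Bernoulli(freq) allele. Haplotypes are independent, so genotype counts
#' satisfy Hardy-Weinberg proportions in expectation. Alternate-allele
#' frequencies are drawn uniformly from `maf_range`; the Markov marginal is
#' a convex combination of upstream frequencies and therefore stays inside
#' the configured range.
#'
#' @param variants variant table from [simulateGenome()].
#' @param config a [simConfig()] object.
#' @return A [GenotypeData-class] object.
#' @export
simulateGenotypes <- function(variants, config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(.childSeed(config$seed, 2))
  n <- config$n_samples
  freq <- runif(nrow(variants), config$maf_range[1], config$maf_range[2])
  hap <- function() {
    h <- matrix(0L, n, nrow(variants))
    for (ch in unique(variants$chromosome)) {
      idx <- which(variants$chromosome == ch)
      h[, idx[1]] <- rbinom(n, 1, freq[idx[1]])
      for (j in seq_along(idx)[-1]) {
        copy <- rbinom(n, 1, config$ld_copy_prob) == 1L
        fresh <- rbinom(n, 1, freq[idx[j]])
        h[, idx[j]] <- ifelse(copy, h[, idx[j - 1]], fresh)
      }
    }
    h
  }
  dosage <- hap() + hap()
  rownames(dosage) <- sprintf("sample%04d", seq_len(n))
  colnames(dosage) <- variants$variant_id
  af <- colMeans(dosage) / 2
  variants$maf <- pmin(af, 1 - af)
  variants$call_rate <- 1
  GenotypeData(dosage, variants)
}

#' Simulate expression with planted cis effects and a TF-mediated hotspot
#'
#' Per-gene baselines are N(8, 2^2) on an arbitrary log-like scale. For each
#' planted cis pair, the gene gains `cis_beta` x dosage of its paired
#' variant. One variant is chosen as the hotspot: a TF gene near it gains
#' `hotspot_beta` x dosage, and each of `hotspot_n_targets` trans target
#' genes responds to the centred TF expression with slope `target_gamma`.
#' Contemporary-group and lane effects (one N(0,1) draw per level) and a
#' linear age effect are added to every gene; all planted parameters are
#' returned in the truth bundle.
#'
#' @param geno [GenotypeData-class] from [simulateGenotypes()].
#' @param genes gene table from [simulateGenome()].
#' @param config a [simConfig()] object.
#' @return list with `expression` (genes x samples), `covariates`
#'   (data.frame: sample_id, contemporary_group, lane, age) and `truth`
#'   (planted parameters; see Details).
#' @details The truth bundle records `cis_truth` (variant_id, gene_id,
#'   beta), `hotspot_variant`, `tf_gene`, `hotspot_targets`,
#'   `covariate_effects` (per-level draws plus the age slope) and, once
#'   [simulatePhenotypes()] has run, per-trait loadings.
#' @export
simulateExpression <- function(geno, genes, config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(.childSeed(config$seed, 3))
  dosage <- dosageMatrix(geno)
  variants <- variantInfo(geno)
  n <- nrow(dosage)
  G <- nrow(genes)
  if (config$hotspot_n_targets > G)
    stop("hotspot_n_targets exceeds the number of available genes")

  samples <- rownames(dosage)
  covariates <- data.frame(
    sample_id = samples,
    contemporary_group = factor(sample(paste0("cg", seq_len(
      config$n_contemporary_groups)), n, replace = TRUE)),
    lane = factor(sample(paste0("lane", seq_len(config$n_lanes)),
                         n, replace = TRUE)),
    age = runif(n, config$age_range[1], config$age_range[2]),
    stringsAsFactors = FALSE)
  cg_eff <- setNames(rnorm(config$n_contemporary_groups),
                     levels(covariates$contemporary_group))
  lane_eff <- setNames(rnorm(config$n_lanes), levels(covariates$lane))
  age_eff <- rnorm(1)
  cov_shift <- cg_eff[as.character(covariates$contemporary_group)] +
    lane_eff[as.character(covariates$lane)] + age_eff * covariates$age

  baseline <- rnorm(G, 8, 2)
  expr <- matrix(rnorm(G * n, 0, config$noise_sd), G, n,
                 dimnames = list(genes$gene_id, samples))
  expr <- expr + baseline + rep(cov_shift, each = G)

  ## hotspot: pick the variant nearest its chromosome centre; TF gene = the
  ## gene nearest that variant; targets drawn from other chromosomes so all
  ## hotspot associations are trans
  hot_var <- NULL; tf_gene <- NULL; targets <- character()
  if (config$hotspot_n_targets > 0) {
    ch <- variants$chromosome[1]
    on_ch <- which(variants$chromosome == ch)
    hot_i <- on_ch[which.min(abs(variants$position[on_ch] -
                                   config$chrom_length_bp / 2))]
    hot_var <- variants$variant_id[hot_i]
    g_on <- which(genes$chromosome == ch)
    tf_i <- g_on[which.min(abs(genes$start[g_on] -
                                 variants$position[hot_i]))]
    tf_gene <- genes$gene_id[tf_i]
    pool <- which(genes$chromosome != ch)
    if (length(pool) < config$hotspot_n_targets)
      pool <- setdiff(seq_len(G), tf_i)
    targets <- genes$gene_id[sample(pool, config$hotspot_n_targets)]
    expr[tf_gene, ] <- expr[tf_gene, ] +
      config$hotspot_beta * dosage[, hot_var]
    tf_centred <- expr[tf_gene, ] - mean(expr[tf_gene, ])
    expr[targets, ] <- expr[targets, ] +
      config$target_gamma * rep(tf_centred, each = length(targets))
  }

  ## cis pairs: genes not already used, paired with the nearest same-
  ## chromosome variant (always << 1 Mb away at these densities)
  cis_truth <- data.frame(variant_id = character(), gene_id = character(),
                          beta = numeric(), stringsAsFactors = FALSE)
  if (config$n_cis_pairs > 0) {
    free <- setdiff(genes$gene_id, c(targets, tf_gene))
    free <- free[seq_len(min(config$n_cis_pairs, length(free)))]
    used <- if (is.null(hot_var)) character() else hot_var
    for (gid in free) {
      gi <- match(gid, genes$gene_id)
      vi <- which(variants$chromosome == genes$chromosome[gi] &
                    !(variants$variant_id %in% used))
      if (!length(vi)) next
      # nearest unused same-chromosome variant, within the 1 Mb cis window
      vi <- vi[which.min(abs(variants$position[vi] - genes$start[gi]))]
      if (abs(variants$position[vi] - genes$start[gi]) > 1e6) next
      vid <- variants$variant_id[vi]
      used <- c(used, vid)
      expr[gid, ] <- expr[gid, ] + config$cis_beta * dosage[, vid]
      cis_truth <- rbind(cis_truth, data.frame(
        variant_id = vid, gene_id = gid, beta = config$cis_beta,
        stringsAsFactors = FALSE))
    }
  }

  truth <- list(cis_truth = cis_truth, hotspot_variant = hot_var,
                tf_gene = tf_gene, hotspot_targets = targets,
                covariate_effects = list(contemporary_group = cg_eff,
                                         lane = lane_eff, age = age_eff),
                trait_loadings = NULL, trait_groups = NULL,
                motif_placements = NULL)
  list(expression = expr, covariates = covariates, truth = truth)
}

#' Simulate phenotypes coupled to the planted gene group
#'
#' Each trait is `trait_loading` x the mean standardised expression of the
#' hotspot-target gene group, plus the shared covariate effects and
#' N(0, noise_sd^2) noise. Group-trait pairings and per-trait loadings are
#' recorded in the truth bundle.
#'
#' @param expression genes x samples matrix from [simulateExpression()].
#' @param covariates covariate table from [simulateExpression()].
#' @param truth truth bundle from [simulateExpression()]; updated in the
#'   return value.
#' @param config a [simConfig()] object.
#' @return list with `phenotypes` (data.frame, sample_id + one column per
#'   trait) and the updated `truth`.
#' @export
simulatePhenotypes <- function(expression, covariates, truth, config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(.childSeed(config$seed, 4))
  n <- ncol(expression)
  group <- truth$hotspot_targets
  if (!length(group)) group <- rownames(expression)[seq_len(
    min(10, nrow(expression)))]
  gs <- colMeans(t(scale(t(expression[group, , drop = FALSE]))))
  cov_shift <- truth$covariate_effects$contemporary_group[
    as.character(covariates$contemporary_group)] +
    truth$covariate_effects$lane[as.character(covariates$lane)] +
    truth$covariate_effects$age * covariates$age
  loadings <- rep(config$trait_loading, config$n_traits)
  traits <- sapply(seq_len(config$n_traits), function(t)
    loadings[t] * gs + cov_shift + rnorm(n, 0, config$noise_sd))
  colnames(traits) <- sprintf("trait%02d", seq_len(config$n_traits))
  truth$trait_loadings <- setNames(loadings, colnames(traits))
  truth$trait_groups <- setNames(rep(list(group), config$n_traits),
                                 colnames(traits))
  phenotypes <- data.frame(sample_id = colnames(expression), traits,
                           stringsAsFactors = FALSE)
  list(phenotypes = phenotypes, truth = truth)
}

#' Simulate 1500 bp promoter sequences with planted motif occurrences
#'
#' Background bases are i.i.d. uniform. A `motif_plant_fraction` share of
#' the target genes' promoters receive one motif occurrence sampled from the
#' PSSM's per-position probabilities, inserted at a recorded offset on a
#' recorded strand (minus-strand plants insert the reverse complement).
#'
#' @param genes gene table (one promoter per gene).
#' @param pssm a [Pssm-class] (planting samples from `pssm@probs`).
#' @param config a [simConfig()] object.
#' @param target_genes gene ids eligible for planting (default: all genes).
#' @param promoter_length promoter length in bp (default 1500).
#' @return list with `promoters` (a [Biostrings::DNAStringSet]) and
#'   `placements` (data.frame: gene_id, offset (0-based), strand).
#' @export
simulatePromoters <- function(genes, pssm, config,
                              target_genes = genes$gene_id,
                              promoter_length = 1500L) {
  stopifnot(inherits(config, "SimConfig"), is(pssm, "Pssm"))
  set.seed(.childSeed(config$seed, 5))
  L <- motifLength(pssm)
  if (L > promoter_length)
    stop("motif (", L, " bp) longer than promoter (", promoter_length, " bp)")
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(nrow(genes)), function(i)
    paste(sample(bases, promoter_length, replace = TRUE), collapse = ""),
    "")
  names(seqs) <- genes$gene_id
  n_plant <- round(config$motif_plant_fraction * length(target_genes))
  planted <- if (n_plant > 0)
    sample(target_genes, n_plant) else character()
  placements <- data.frame(gene_id = character(), offset = integer(),
                           strand = character(), stringsAsFactors = FALSE)
  for (gid in planted) {
    occ <- vapply(seq_len(L), function(j)
      sample(bases, 1, prob = pssm@probs[, j]), "")
    strand <- sample(c("+", "-"), 1)
    ins <- paste(occ, collapse = "")
    if (strand == "-")
      ins <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(ins)))
    off <- sample.int(promoter_length - L + 1, 1) - 1L
    substr(seqs[gid], off + 1L, off + L) <- ins
    placements <- rbind(placements, data.frame(
      gene_id = gid, offset = off, strand = strand,
      stringsAsFactors = FALSE))
  }
  list(promoters = Biostrings::DNAStringSet(seqs), placements = placements)
}

#' Build a demonstration position frequency matrix
#'
#' A sharply peaked counts matrix (consensus base gets `depth` counts per
#' position, the rest one count each), convenient for planting and
#' recovering motif occurrences in synthetic promoters.
#'
#' @param width motif length.
#' @param depth counts on the consensus base.
#' @param seed RNG seed for the consensus sequence.
#' @return 4 x width counts matrix with rownames A, C, G, T.
#' @export
demoPfm <- function(width = 8L, depth = 50L, seed = 1L) {
  set.seed(seed)
  counts <- matrix(1, 4, width, dimnames = list(c("A", "C", "G", "T"), NULL))
  cons <- sample.int(4, width, replace = TRUE)
  counts[cbind(cons, seq_len(width))] <- depth
  counts
}

#' Simulate a full synthetic study
#'
#' Runs every generator with child seeds from the master seed and adds the
#' auxiliary inputs the downstream stages consume: a known-QTL region set
#' (one region overlapping the planted hotspot window plus random regions)
#' and gene sets (one set equal to the hotspot targets plus random sets).
#'
#' @param config a [simConfig()] object.
#' @param pfm counts matrix for the planted motif (default [demoPfm()]).
#' @return list with `genotypes`, `genes`, `expression`, `covariates`,
#'   `phenotypes`, `promoters`, `pssm`, `regions` (GRanges), `gene_sets`
#'   (named list) and `truth`.
#' @export
simulateStudy <- function(config = simConfig(), pfm = demoPfm()) {
  genome <- simulateGenome(config)
  geno <- simulateGenotypes(genome$variants, config)
  ex <- simulateExpression(geno, genome$genes, config)
  ph <- simulatePhenotypes(ex$expression, ex$covariates, ex$truth, config)
  truth <- ph$truth
  pssm <- pfmToPssm(pfm)
  prom <- simulatePromoters(genome$genes, pssm, config,
                            target_genes = truth$hotspot_targets)
  truth$motif_placements <- prom$placements

  set.seed(.childSeed(config$seed, 6))
  ## known-QTL regions: one spanning the hotspot window, plus decoys
  v <- variantInfo(geno)
  regs <- data.frame(
    chromosome = sample(unique(v$chromosome), 8, replace = TRUE),
    start = sample.int(config$chrom_length_bp - 500000L, 8))
  regs$end <- regs$start + sample(100000:500000, 8, replace = TRUE)
  if (!is.null(truth$hotspot_variant)) {
    hp <- v[v$variant_id == truth$hotspot_variant, ]
    regs <- rbind(data.frame(chromosome = hp$chromosome,
                             start = max(1, hp$position - 2e6),
                             end = min(config$chrom_length_bp,
                                       hp$position + 2e6)), regs)
  }
  regions <- GenomicRanges::GRanges(regs$chromosome,
                                    IRanges::IRanges(regs$start, regs$end))

  all_genes <- genome$genes$gene_id
  gene_sets <- list(planted_targets = truth$hotspot_targets)
  for (k in 1:5)
    gene_sets[[paste0("random_set", k)]] <-
      sample(all_genes, min(30, length(all_genes)))

  list(genotypes = geno, genes = genome$genes,
       expression = ex$expression, covariates = ex$covariates,
       phenotypes = ph$phenotypes, promoters = prom$promoters,
       pssm = pssm, regions = regions, gene_sets = gene_sets,
       truth = truth, config = config)
}
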