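#' Count distinct target genes per variant
#'
#' @param eqtls eQTL table from [mapEqtl()]; only rows flagged
#'   `significant` are counted.
#' @param scope `"trans"` (default) restricts to trans associations;
#'   `"all"` counts every significant association.
#' @return named integer vector, variant_id -> distinct significant target
#'   genes; empty when nothing is significant.
#' @export
countTargets <- function(eqtls, scope = c("trans", "all")) {
  scope <- match.arg(scope)
  sig <- eqtls[which(eqtls$significant), , drop = FALSE]
  if (scope == "trans")
    sig <- sig[sig$eqtl_class == "trans", , drop = FALSE]
  if (!nrow(sig)) return(setNames(integer(), character()))
  sig <- unique(sig[, c("variant_id", "gene_id")])
  counts <- table(sig$variant_id)
  setNames(as.integer(counts), names(counts))
}

#' Permutation null threshold for hotspot calling
#'
#' Each permutation reassigns every significant association to a variant
#' drawn uniformly (with replacement) from the tested variants and records
#' the maximum per-variant distinct-target-gene count; the threshold is the
#' ceiling of the empirical `quantile` of those maxima (family-wise control
#' of the most extreme variant). `null = "pooled"` instead takes the
#' quantile of all per-variant counts pooled across permutations.
#'
#' @param sig_eqtls data.frame of significant associations (columns
#'   `variant_id`, `gene_id`); duplicates are collapsed.
#' @param tested_variants character vector of all variant ids that entered
#'   the scan (the reassignment universe).
#' @param n_perm number of permutations (default 1000; < 100 warns).
#' @param quantile percentile of the null statistic (default 0.95).
#' @param seed RNG seed.
#' @param null `"max"` (default) or `"pooled"`.
#' @param exhaustive enumerate all `V^A` assignments instead of sampling
#'   (toy instances only).
#' @return list with `threshold` (integer), `stats` (the permutation maxima,
#'   or pooled counts), `n_perm`, `quantile`.
#' @export
hotspotThreshold <- function(sig_eqtls, tested_variants, n_perm = 1000,
                             quantile = 0.95, seed = 1L,
                             null = c("max", "pooled"),
                             exhaustive = FALSE) {
  null <- match.arg(null)
  assoc <- unique(sig_eqtls[, c("variant_id", "gene_id")])
  if (!nrow(assoc)) stop("no significant associations to permute")
  if (!exhaustive && n_perm < 100)
    warning("n_perm < 100 gives an unstable percentile estimate")
  A <- nrow(assoc)
  V <- length(tested_variants)
  gene_code <- as.integer(factor(assoc$gene_id))
  maxCount <- function(vind) {
    key <- (vind - 1) * (max(gene_code) + 1L) + gene_code
    vind <- vind[!duplicated(key)]
    max(tabulate(vind, V))
  }
  allCounts <- function(vind) {
    key <- (vind - 1) * (max(gene_code) + 1L) + gene_code
    vind <- vind[!duplicated(key)]
    tabulate(vind, V)
  }
  if (exhaustive) {
    if (V^A > 1e5) stop("exhaustive enumeration too large (V^A > 1e5)")
    grid <- as.matrix(expand.grid(rep(list(seq_len(V)), A)))
    stats <- apply(grid, 1, if (null == "max") maxCount else allCounts)
    stats <- as.vector(stats)
  } else {
    set.seed(seed)
    stats <- if (null == "max") {
      vapply(seq_len(n_perm), function(i)
        maxCount(sample.int(V, A, replace = TRUE)), 1)
    } else {
      as.vector(vapply(seq_len(n_perm), function(i)
        allCounts(sample.int(V, A, replace = TRUE)), integer(V)))
    }
  }
  thr <- as.integer(ceiling(stats::quantile(stats, quantile, type = 1)))
  list(threshold = thr, stats = stats,
       n_perm = if (exhaustive) length(stats) else n_perm,
       quantile = quantile)
}

#' Refine hotspot candidates by linkage disequilibrium
#'
#' Greedy merge: candidates are ranked by target count (ties broken by
#' minimum association p, then position); each accepted anchor absorbs any
#' remaining candidate whose dosage r-squared with it reaches `r2_merge`.
#' Absorbed candidates are recorded in `merged_from`; the anchor keeps its
#' own target list (no union).
#'
#' @param candidates data.frame with `variant_id` and `n_targets` (and
#'   optionally `p_min`); typically variants whose [countTargets()] count
#'   reached the [hotspotThreshold()].
#' @param geno [GenotypeData-class] containing the candidate variants.
#' @param targets named list, variant_id -> character vector of target
#'   genes.
#' @param threshold the hotspot threshold (stored on each call).
#' @param r2_merge r-squared at or above which candidates merge
#'   (default 0.5).
#' @param half_width_bp hotspot window half-width (default 2 Mb).
#' @param chrom_lengths named vector of chromosome lengths for window
#'   clipping.
#' @return data.frame of hotspot calls: anchor_variant, chromosome,
#'   position, n_targets, threshold, window_start, window_end,
#'   window_clipped, merged_from (comma-separated), target_genes
#'   (list column).
#' @export
refineHotspots <- function(candidates, geno, targets, threshold,
                           r2_merge = 0.5, half_width_bp = 2e6,
                           chrom_lengths = NULL) {
  stopifnot(nrow(candidates) > 0)
  v <- variantInfo(geno)
  dosage <- dosageMatrix(geno)
  cand <- candidates
  cand$position <- v$position[match(cand$variant_id, v$variant_id)]
  cand$chromosome <- v$chromosome[match(cand$variant_id, v$variant_id)]
  if (is.null(cand$p_min)) cand$p_min <- 0
  ord <- order(-cand$n_targets, cand$p_min, cand$position)
  cand <- cand[ord, , drop = FALSE]
  remaining <- cand$variant_id
  calls <- list()
  while (length(remaining)) {
    anchor <- remaining[1]
    remaining <- remaining[-1]
    r2 <- vapply(remaining, function(vid)
      ldR2(dosage[, anchor], dosage[, vid]), 1)
    absorbed <- remaining[r2 >= r2_merge]
    remaining <- setdiff(remaining, absorbed)
    row <- cand[cand$variant_id == anchor, ]
    win <- hotspotWindow(row$chromosome, row$position,
                         half_width_bp = half_width_bp,
                         chrom_lengths = chrom_lengths)
    calls[[anchor]] <- data.frame(
      anchor_variant = anchor, chromosome = row$chromosome,
      position = row$position, n_targets = row$n_targets,
      threshold = threshold, window_start = win$start,
      window_end = win$end, window_clipped = win$clipped,
      merged_from = paste(absorbed, collapse = ","),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out$target_genes <- targets[out$anchor_variant]
  out
}

#' 4 Mb hotspot window around an anchor variant
#'
#' `[pos - half_width, pos + half_width]`, clipped to `[1, chrom_length]`
#' when lengths are supplied; clipping is flagged.
#'
#' @param chromosome,position anchor coordinates.
#' @param half_width_bp half-width (default 2 Mb, i.e. a 4 Mb window).
#' @param chrom_lengths named numeric vector of chromosome lengths; if
#'   `NULL`, only the lower bound is clipped.
#' @return list with `chromosome`, `start`, `end`, `clipped`.
#' @export
hotspotWindow <- function(chromosome, position, half_width_bp = 2e6,
                          chrom_lengths = NULL) {
  start <- position - half_width_bp
  end <- position + half_width_bp
  clipped <- FALSE
  if (start < 1) { start <- 1; clipped <- TRUE }
  if (!is.null(chrom_lengths)) {
    if (!chromosome %in% names(chrom_lengths))
      stop("unknown chromosome length for ", chromosome)
    if (end > chrom_lengths[[chromosome]]) {
      end <- chrom_lengths[[chromosome]]
      clipped <- TRUE
    }
  }
  list(chromosome = chromosome, start = start, end = end, clipped = clipped)
}

#' Call trans-eQTL hotspots from an eQTL table
#'
#' Convenience wrapper: counts distinct trans targets per variant, derives
#' the permutation threshold, and refines the over-threshold candidates by
#' LD into hotspot calls with 4 Mb windows.
#'
#' @inheritParams hotspotThreshold
#' @inheritParams refineHotspots
#' @param eqtls full eQTL table from [mapEqtl()].
#' @param scope association scope passed to [countTargets()].
#' @return list with `calls` (data.frame, possibly 0 rows), `threshold`,
#'   `counts`.
#' @export
callHotspots <- function(eqtls, geno, n_perm = 1000, quantile = 0.95,
                         seed = 1L, r2_merge = 0.5, half_width_bp = 2e6,
                         chrom_lengths = NULL, scope = "trans",
                         null = "max") {
  counts <- countTargets(eqtls, scope = scope)
  empty <- list(calls = data.frame(), threshold = NA_integer_,
                counts = counts)
  if (!length(counts)) return(empty)
  sig <- eqtls[which(eqtls$significant), ]
  if (scope == "trans") sig <- sig[sig$eqtl_class == "trans", ]
  thr <- hotspotThreshold(sig, variantInfo(geno)$variant_id,
                          n_perm = n_perm, quantile = quantile,
                          seed = seed, null = null)
  over <- names(counts)[counts >= thr$threshold]
  if (!length(over))
    return(list(calls = data.frame(), threshold = thr$threshold,
                counts = counts))
  pmin_v <- vapply(over, function(vid)
    min(sig$p_value[sig$variant_id == vid]), 1)
  cand <- data.frame(variant_id = over, n_targets = counts[over],
                     p_min = pmin_v, stringsAsFactors = FALSE)
  targets <- lapply(over, function(vid)
    unique(sig$gene_id[sig$variant_id == vid]))
  names(targets) <- over
  calls <- refineHotspots(cand, geno, targets, thr$threshold,
                          r2_merge = r2_merge,
                          half_width_bp = half_width_bp,
                          chrom_lengths = chrom_lengths)
  list(calls = calls, threshold = thr$threshold, counts = counts)
}
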