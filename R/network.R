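## module label palette, assigned by decreasing module size
.moduleColors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta")

.colorName <- function(i)
  if (i <= length(.moduleColors)) .moduleColors[i] else paste0("module", i)

#' Split samples by genotype at an anchor variant
#'
#' Partitions samples into the homozygous reference (AA, dosage 0) and
#' heterozygous (AB, dosage 1) groups; the rare alternate homozygotes
#' (dosage 2) are excluded with their count reported.
#'
#' @param dosage dosage vector named by sample.
#' @param min_group minimum group size before a warning is raised (the
#'   analysis still proceeds, flagged).
#' @return list with `AA`, `AB` (sample id vectors), `n_excluded`,
#'   `flagged`.
#' @export
splitByGenotype <- function(dosage, min_group = 15) {
  if (length(unique(dosage[!is.na(dosage)])) < 2)
    stop("anchor variant is monomorphic; cannot stratify")
  ids <- names(dosage)
  if (is.null(ids)) ids <- as.character(seq_along(dosage))
  out <- list(AA = ids[which(dosage == 0)], AB = ids[which(dosage == 1)],
              n_excluded = sum(dosage == 2, na.rm = TRUE))
  out$flagged <- min(length(out$AA), length(out$AB)) < min_group
  if (out$flagged)
    warning("genotype group below ", min_group,
            " samples; results flagged")
  out
}

#' Signed-free soft-threshold adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^power` over samples, with a zero diagonal (the
#' unsigned network). Zero-variance genes must be removed first.
#'
#' @param expression genes x samples matrix.
#' @param soft_power soft-threshold power (default 6).
#' @return symmetric gene x gene adjacency in \[0, 1\], diagonal 0.
#' @export
adjacencyMatrix <- function(expression, soft_power = 6) {
  if (ncol(expression) < 3) stop("need at least 3 samples")
  v <- apply(expression, 1, var)
  if (any(v == 0)) stop("zero-variance gene(s): ",
                        paste(head(rownames(expression)[v == 0], 5),
                              collapse = ", "))
  a <- abs(cor(t(expression)))^soft_power
  diag(a) <- 0
  a
}

#' Scale-free topology fit index
#'
#' Bins the connectivities `k_i = sum_j a_ij` into 10 bins and reports the
#' squared Pearson correlation of log10(mean k per bin) against
#' log10(frequency per bin), together with the regression slope's sign.
#'
#' @param adjacency gene x gene adjacency (zero diagonal).
#' @param n_bins number of connectivity bins (default 10).
#' @return list with `r_squared`, `slope`.
#' @export
scaleFreeFit <- function(adjacency, n_bins = 10) {
  if (nrow(adjacency) < 20) stop("need at least 20 genes")
  k <- rowSums(adjacency)
  if (max(k) - min(k) < .Machine$double.eps^0.5)
    stop("all connectivities equal; fit undefined")
  bins <- cut(k, n_bins)
  mean_k <- tapply(k, bins, mean)
  freq <- tapply(k, bins, length) / length(k)
  ok <- !is.na(mean_k) & !is.na(freq) & mean_k > 0
  if (sum(ok) < 3) stop("too few occupied connectivity bins")
  x <- log10(mean_k[ok]); y <- log10(freq[ok])
  fit <- lm(y ~ x)
  list(r_squared = cor(x, y)^2, slope = unname(coef(fit)[2]))
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` and `k_i = sum_u a_iu`; the diagonal is 1.
#'
#' @param adjacency symmetric adjacency in \[0, 1\] with zero diagonal.
#' @return TOM matrix in \[0, 1\], diagonal 1.
#' @export
tomMatrix <- function(adjacency) {
  if (any(adjacency < 0 | adjacency > 1))
    stop("adjacency entries must lie in [0, 1]")
  L <- adjacency %*% adjacency     # diag(adjacency) = 0 excludes u = i, j
  k <- rowSums(adjacency)
  denom <- outer(k, k, pmin) + 1 - adjacency
  tom <- (L + adjacency) / denom
  diag(tom) <- 1
  tom
}

#' Module detection by adaptive tree cut
#'
#' Average-linkage hierarchical clustering of the dissimilarity (1 - TOM),
#' cut at a `deep_split`-controlled fraction of the maximum merge height
#' (0.99, 0.985, 0.98, 0.97, 0.96 for deep_split 0..4); branches with at
#' least `min_module_size` leaves become modules (labelled by decreasing
#' size with the conventional colour names), everything else is grey.
#'
#' @param dissimilarity square dissimilarity matrix (e.g. `1 - tomMatrix()`).
#' @param min_module_size minimum module size (default 30).
#' @param deep_split split aggressiveness, integer 0-4 (default 2).
#' @return named character vector of module labels per gene.
#' @export
detectModules <- function(dissimilarity, min_module_size = 30,
                          deep_split = 2) {
  stopifnot(nrow(dissimilarity) == ncol(dissimilarity))
  if (!deep_split %in% 0:4) stop("deep_split must be an integer in 0..4")
  genes <- rownames(dissimilarity)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(dissimilarity)))
  if (nrow(dissimilarity) < min_module_size) {
    warning("fewer genes than min_module_size; all grey")
    return(setNames(rep("grey", length(genes)), genes))
  }
  hc <- hclust(as.dist(dissimilarity), method = "average")
  frac <- c(0.99, 0.985, 0.98, 0.97, 0.96)[deep_split + 1]
  cl <- cutree(hc, h = frac * max(hc$height))
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_module_size]
  labels <- rep("grey", length(genes))
  if (length(big)) {
    ord <- big[order(-sizes[big])]
    for (i in seq_along(ord))
      labels[cl == as.integer(ord[i])] <- .colorName(i)
  }
  setNames(labels, genes)
}

#' Module eigengenes
#'
#' For each non-grey module, member genes are standardised over samples and
#' the eigengene is the first right-singular vector (unit norm over
#' samples), sign-oriented so its mean correlation with the members is
#' positive. Variance explained is the first squared singular value over
#' the total. Singleton modules use the standardised gene itself (flagged
#' by variance explained 1).
#'
#' @param expression genes x samples matrix.
#' @param labels module labels from [detectModules()].
#' @return A [ModuleSet-class] object.
#' @export
moduleEigengene <- function(expression, labels) {
  mods <- setdiff(unique(labels), "grey")
  mods <- mods[order(-table(labels)[mods])]
  samples <- colnames(expression)
  ev <- matrix(0, length(mods), ncol(expression),
               dimnames = list(mods, samples))
  vexp <- setNames(numeric(length(mods)), mods)
  for (m in mods) {
    members <- names(labels)[labels == m]
    X <- t(scale(t(expression[members, , drop = FALSE])))
    if (length(members) == 1) {
      e <- as.vector(X) / sqrt(sum(X^2))
      ev[m, ] <- e
      vexp[m] <- 1
      next
    }
    sv <- svd(X, nu = 0, nv = 1)
    e <- sv$v[, 1]
    if (mean(cor(e, t(X))) < 0) e <- -e
    ev[m, ] <- e
    vexp[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  new("ModuleSet", labels = labels, eigengenes = ev,
      varianceExplained = vexp,
      mergedHistory = data.frame(from = character(), into = character(),
                                 stringsAsFactors = FALSE))
}

#' Merge similar modules by eigengene correlation
#'
#' Clusters module eigengenes on dissimilarity `1 - cor`, merges clusters
#' joined below `merge_height` (0.25 corresponds to eigengene correlation
#' 0.75), recomputes eigengenes, and repeats to a fixed point. The merged
#' module keeps the larger member's label.
#'
#' @param expression genes x samples matrix.
#' @param labels module labels.
#' @param merge_height dendrogram cut height for merging (default 0.25).
#' @return A [ModuleSet-class] with merged labels, recomputed eigengenes
#'   and the merge history.
#' @export
mergeModules <- function(expression, labels, merge_height = 0.25) {
  history <- data.frame(from = character(), into = character(),
                        stringsAsFactors = FALSE)
  repeat {
    ms <- moduleEigengene(expression, labels)
    ev <- eigengenes(ms)
    if (nrow(ev) < 2) break
    diss <- 1 - cor(t(ev))
    hc <- hclust(as.dist(diss), method = "average")
    if (min(hc$height) >= merge_height) break
    cl <- cutree(hc, h = merge_height)
    merged <- FALSE
    for (grp in unique(cl)) {
      mods <- rownames(ev)[cl == grp]
      if (length(mods) < 2) next
      sizes <- table(labels)[mods]
      into <- mods[which.max(sizes)]
      from <- setdiff(mods, into)
      labels[labels %in% from] <- into
      history <- rbind(history, data.frame(from = from, into = into,
                                           stringsAsFactors = FALSE))
      merged <- TRUE
    }
    if (!merged) break
  }
  ms <- moduleEigengene(expression, labels)
  ms@mergedHistory <- history
  ms
}

#' Scale a TOM to a reference group's quantile
#'
#' Raises the smaller group's TOM elementwise to the power
#' `log(q_ref) / log(q_small)`, where the q's are the `scale_quantile`
#' quantiles of each TOM's off-diagonal entries, so that after scaling the
#' two quantiles agree. Entry ordering is preserved (power map on (0,1)).
#'
#' @param tom_small TOM of the group to rescale.
#' @param tom_reference TOM of the reference (larger) group.
#' @param scale_quantile quantile to match (default 0.95).
#' @return list with `tom` (scaled matrix, diagonal 1) and `exponent`.
#' @export
scaleTom <- function(tom_small, tom_reference, scale_quantile = 0.95) {
  off <- function(m) m[upper.tri(m)]
  # type-1 (order-statistic) quantiles commute with the monotone power
  # map, making the post-condition exact
  q_small <- stats::quantile(off(tom_small), scale_quantile,
                             names = FALSE, type = 1)
  q_ref <- stats::quantile(off(tom_reference), scale_quantile,
                           names = FALSE, type = 1)
  if (q_small <= 0 || q_small >= 1 || q_ref <= 0 || q_ref >= 1)
    stop("quantiles must lie strictly inside (0, 1)")
  expo <- log(q_ref) / log(q_small)
  out <- tom_small^expo
  diag(out) <- 1
  list(tom = out, exponent = expo)
}

#' Module-trait correlation with Student asymptotic p-values
#'
#' @param module_set A [ModuleSet-class].
#' @param traits samples x traits numeric matrix/data.frame (aligned to the
#'   eigengene samples).
#' @return list with `r` (modules x traits), `p` (same shape,
#'   `p = 2 P(T_{n-2} >= |r| sqrt(n-2) / sqrt(1-r^2))`), `n`.
#' @export
moduleTraitCorrelation <- function(module_set, traits) {
  ev <- eigengenes(module_set)
  traits <- as.matrix(traits)
  n <- ncol(ev)
  if (n < 4) stop("need at least 4 samples")
  if (nrow(traits) != n) stop("trait rows must match eigengene samples")
  r <- cor(t(ev), traits)
  t_stat <- abs(r) * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(t_stat, df = n - 2, lower.tail = FALSE)
  list(r = r, p = p, n = n)
}

#' Gene significance and module membership
#'
#' GS is the absolute gene-trait correlation; MM is the signed correlation
#' of a gene's profile with a module eigengene.
#'
#' @param expression genes x samples matrix.
#' @param trait numeric trait vector over samples.
#' @return `geneSignificance`: named GS vector.
#' @export
geneSignificance <- function(expression, trait) {
  if (sd(trait) == 0) stop("zero-variance trait")
  gs <- abs(as.vector(cor(t(expression), trait)))
  setNames(gs, rownames(expression))
}

#' @rdname geneSignificance
#' @param eigengene eigengene vector over samples.
#' @return `moduleMembership`: named signed MM vector.
#' @export
moduleMembership <- function(expression, eigengene) {
  if (sd(eigengene) == 0) stop("zero-variance eigengene")
  setNames(as.vector(cor(t(expression), eigengene)), rownames(expression))
}

#' Select hub genes by module membership
#'
#' Top `k` genes of a module by |MM|, ties broken by gene id; `k` is capped
#' at the module size.
#'
#' @param mm named MM vector for the module's genes.
#' @param k number of hubs (default 20).
#' @return character vector of hub gene ids, deterministic order.
#' @export
selectHubGenes <- function(mm, k = 20) {
  if (!length(mm)) stop("empty module")
  ord <- order(-abs(mm), names(mm))
  names(mm)[ord][seq_len(min(k, length(mm)))]
}

#' Select trait-associated modules
#'
#' Modules (grey excluded) whose module-trait correlation has `p <
#' p_threshold` for at least `min_traits` distinct traits.
#'
#' @param mtc result of [moduleTraitCorrelation()].
#' @param min_traits minimum number of associated traits (default 3).
#' @param p_threshold per-cell p threshold (default 0.1).
#' @return character vector of module names.
#' @export
selectTraitModules <- function(mtc, min_traits = 3, p_threshold = 0.1) {
  hits <- rowSums(mtc$p < p_threshold)
  sel <- names(hits)[hits >= min_traits]
  setdiff(sel, "grey")
}

#' Build a co-expression network for one expression group
#'
#' Convenience wrapper: removes zero-variance genes, computes the unsigned
#' soft-power adjacency and TOM, detects modules on 1 - TOM, and merges
#' similar modules.
#'
#' @param expression genes x samples matrix for one genotype group.
#' @param soft_power soft threshold power (default 6).
#' @param min_module_size minimum module size (default 30).
#' @param deep_split tree-cut aggressiveness 0-4 (default 2).
#' @param merge_height eigengene merge height (default 0.25).
#' @param tom optional precomputed (e.g. scaled) TOM; when supplied the
#'   adjacency step is skipped.
#' @return list with `modules` (a [ModuleSet-class]), `tom`, `adjacency`,
#'   `scale_free` (fit index of the adjacency).
#' @export
buildNetwork <- function(expression, soft_power = 6, min_module_size = 30,
                         deep_split = 2, merge_height = 0.25, tom = NULL) {
  v <- apply(expression, 1, var)
  if (any(v == 0)) {
    message(sum(v == 0), " zero-variance gene(s) removed")
    expression <- expression[v > 0, , drop = FALSE]
  }
  adj <- NULL; sf <- NULL
  if (is.null(tom)) {
    adj <- adjacencyMatrix(expression, soft_power)
    sf <- tryCatch(scaleFreeFit(adj), error = function(e) NULL)
    tom <- tomMatrix(adj)
  }
  labels <- detectModules(1 - tom, min_module_size, deep_split)
  ms <- mergeModules(expression, labels, merge_height)
  list(modules = ms, tom = tom, adjacency = adj, scale_free = sf)
}
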