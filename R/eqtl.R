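#' Filter variants by call rate, MAF and chromosome
#'
#' Removes variants whose call rate or minor allele frequency is at or below
#' the threshold (a variant survives only if strictly greater), variants on
#' sex chromosomes, and unmapped variants (missing chromosome or position).
#'
#' @param geno A [GenotypeData-class] object.
#' @param min_call_rate call-rate threshold; variants with
#'   `call_rate <= min_call_rate` are removed (default 0.95).
#' @param min_maf MAF threshold; variants with `maf <= min_maf` are removed
#'   (default 0.05).
#' @param drop_sex_chroms drop variants on `sex_chroms`.
#' @param sex_chroms chromosome names treated as sex chromosomes.
#' @param drop_unmapped drop variants with missing coordinates.
#' @return Filtered [GenotypeData-class]; a warning (not an error) is
#'   emitted when nothing survives.
#' @export
filterVariants <- function(geno, min_call_rate = 0.95, min_maf = 0.05,
                           drop_sex_chroms = TRUE,
                           sex_chroms = c("X", "Y", "chrX", "chrY"),
                           drop_unmapped = TRUE) {
  v <- variantInfo(geno)
  keep <- v$call_rate > min_call_rate & v$maf > min_maf
  if (drop_sex_chroms) keep <- keep & !(v$chromosome %in% sex_chroms)
  if (drop_unmapped)
    keep <- keep & !is.na(v$chromosome) & !is.na(v$position) &
      nzchar(v$chromosome)
  keep[is.na(keep)] <- FALSE
  if (!any(keep))
    warning("no variants survive filtering; returning an empty panel")
  subsetVariants(geno, keep)
}

.covariateDesign <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1,
                                         dimnames = list(NULL, "(Intercept)")))
  covariates <- as.data.frame(covariates)
  covariates$sample_id <- NULL
  for (nm in names(covariates))
    if (is.character(covariates[[nm]]))
      covariates[[nm]] <- factor(covariates[[nm]])
  X <- model.matrix(~ ., data = covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[-(qrX$pivot[seq_len(qrX$rank)])]
    message("dropping collinear covariate column(s): ",
            paste(drop, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  X
}

#' Additive single-variant association fit
#'
#' Ordinary least squares of an expression (or trait) vector on an
#' intercept, dummy-coded covariate factors, numeric covariates, and the
#' dosage vector; the returned test is the two-sided Student t for the
#' dosage slope with residual degrees of freedom.
#'
#' @param y response vector.
#' @param g dosage vector (missing values mean-imputed).
#' @param covariates optional data.frame of covariates (factors and
#'   numerics; a `sample_id` column is ignored).
#' @return list with `beta`, `se`, `t_stat`, `p_value`, `df`, or with NAs
#'   and a `reason` when `g` is constant.
#' @export
fitAdditiveModel <- function(y, g, covariates = NULL) {
  if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
  if (var(g) == 0)
    return(list(beta = NA_real_, se = NA_real_, t_stat = NA_real_,
                p_value = NA_real_, df = NA_integer_,
                reason = "constant dosage"))
  X <- .covariateDesign(covariates, length(y))
  fit <- lm.fit(cbind(X, g = g), y)
  df <- length(y) - fit$rank
  if (df < 1)
    stop("not enough samples for the model (residual df < 1)")
  rss <- sum(fit$residuals^2)
  XtXinv_gg <- chol2inv(qr.R(qr(cbind(X, g = g))))[fit$rank, fit$rank]
  beta <- fit$coefficients["g"]
  sigma2 <- rss / df
  se <- sqrt(sigma2 * XtXinv_gg)
  t_stat <- if (se > 0) beta / se else sign(beta) * Inf
  p <- 2 * pt(-abs(t_stat), df)
  list(beta = unname(beta), se = unname(se), t_stat = unname(t_stat),
       p_value = unname(p), df = df)
}

#' Classify variant-gene pairs as cis or trans
#'
#' Distance is 0 when the variant lies inside the gene span, else the
#' distance to the nearest span boundary. A pair is cis when the variant is
#' on the gene's chromosome and within `window_bp` (inclusive: a distance of
#' exactly 1 Mb is cis); different chromosomes are always trans, with
#' distance `NA`.
#'
#' @param variant_chrom,variant_pos variant coordinates (vectorised).
#' @param gene_chrom,gene_start,gene_end gene span (1-based inclusive).
#' @param window_bp cis window (default 1 Mb).
#' @return data.frame with `eqtl_class` ("cis"/"trans") and `distance_bp`.
#' @export
classifyCisTrans <- function(variant_chrom, variant_pos, gene_chrom,
                             gene_start, gene_end, window_bp = 1e6) {
  same <- variant_chrom == gene_chrom
  inside <- same & variant_pos >= gene_start & variant_pos <= gene_end
  dist <- ifelse(inside, 0,
                 pmin(abs(variant_pos - gene_start),
                      abs(variant_pos - gene_end)))
  dist[!same] <- NA_real_
  cls <- ifelse(same & dist <= window_bp, "cis", "trans")
  cls[!same] <- "trans"
  data.frame(eqtl_class = cls, distance_bp = dist)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH adjusted p-values in input order, capped at 1. `NA`/`NaN`
#' entries propagate with a warning.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return vector of q-values.
#' @export
bhFdr <- function(p) {
  if (anyNA(p)) warning("NA p-values propagated through BH adjustment")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Rank-based inverse normal transform
#' @param x numeric vector.
#' @return transformed vector (Blom offsets, c = 3/8).
#' @export
inverseNormal <- function(x) {
  qnorm((rank(x, na.last = "keep") - 3 / 8) / (sum(!is.na(x)) + 1 / 4))
}

#' Genome-wide eQTL scan
#'
#' Tests every variant x gene pair with the additive covariate-adjusted
#' model, classifies pairs as cis or trans, and applies BH-FDR separately
#' within each class (or pooled). The scan residualises the expression
#' matrix and the (mean-imputed) dosage matrix on the covariate design once
#' and recovers per-pair OLS slope, SE, t and p from cross-products --
#' numerically identical to fitting each pair separately.
#'
#' @param geno A [GenotypeData-class] object (typically after
#'   [filterVariants()]).
#' @param expression genes x samples matrix; column names must match the
#'   dosage rownames.
#' @param genes gene table (gene_id, chromosome, start, end).
#' @param covariates optional covariate data.frame with a `sample_id`
#'   column aligned to samples (order is checked by id).
#' @param fdr significance threshold on the class-wise q-value.
#' @param cis_window_bp cis window (default 1 Mb).
#' @param pooled_fdr apply BH over all pairs instead of per class.
#' @param inverse_normal rank-inverse-normal transform each gene first.
#' @return data.frame with one row per tested pair: variant_id, gene_id,
#'   beta, se, t_stat, p_value, q_value, eqtl_class, distance_bp,
#'   significant.
#' @export
mapEqtl <- function(geno, expression, genes, covariates = NULL,
                    fdr = 0.05, cis_window_bp = 1e6, pooled_fdr = FALSE,
                    inverse_normal = FALSE) {
  dosage <- dosageMatrix(geno)
  v <- variantInfo(geno)
  samples <- rownames(dosage)
  if (!identical(sort(samples), sort(colnames(expression))))
    stop("sample ids differ between genotypes and expression: ",
         paste(head(c(setdiff(samples, colnames(expression)),
                      setdiff(colnames(expression), samples)), 5),
               collapse = ", "))
  expression <- expression[, samples, drop = FALSE]
  if (!is.null(covariates)) {
    if (!"sample_id" %in% names(covariates))
      stop("covariates need a sample_id column")
    if (!identical(sort(covariates$sample_id), sort(samples)))
      stop("sample ids differ between genotypes and covariates")
    covariates <- covariates[match(samples, covariates$sample_id), ]
  }
  genes <- genes[genes$gene_id %in% rownames(expression), , drop = FALSE]
  expression <- expression[genes$gene_id, , drop = FALSE]
  if (inverse_normal)
    expression <- t(apply(expression, 1, inverseNormal))

  n <- length(samples)
  X <- .covariateDesign(covariates, n)
  Q <- qr.Q(qr(X))
  # mean-impute missing dosages per variant, then residualise on covariates
  if (anyNA(dosage)) {
    mu <- colMeans(dosage, na.rm = TRUE)
    idx <- which(is.na(dosage), arr.ind = TRUE)
    dosage[idx] <- mu[idx[, 2]]
  }
  keep_v <- apply(dosage, 2, var) > 0
  if (any(!keep_v))
    message(sum(!keep_v), " constant variant(s) skipped")
  dosage <- dosage[, keep_v, drop = FALSE]
  v <- v[keep_v, , drop = FALSE]

  E <- expression - tcrossprod(expression %*% Q, Q)   # genes x samples
  G <- dosage - Q %*% crossprod(Q, dosage)            # samples x variants
  df <- n - ncol(X) - 1
  if (df < 1) stop("not enough samples for the model (residual df < 1)")
  C <- E %*% G                                        # genes x variants
  gss <- colSums(G^2)
  yss <- rowSums(E^2)
  beta <- sweep(C, 2, gss, "/")
  rss <- pmax(outer(yss, rep(1, length(gss))) - sweep(C^2, 2, gss, "/"), 0)
  se <- sqrt(sweep(rss / df, 2, gss, "/"))
  t_stat <- beta / se
  p <- 2 * pt(-abs(t_stat), df)

  out <- data.frame(
    variant_id = rep(v$variant_id, each = nrow(E)),
    gene_id = rep(rownames(E), times = ncol(G)),
    beta = as.vector(beta), se = as.vector(se),
    t_stat = as.vector(t_stat), p_value = as.vector(p),
    stringsAsFactors = FALSE)
  gi <- match(out$gene_id, genes$gene_id)
  vi <- match(out$variant_id, v$variant_id)
  cls <- classifyCisTrans(v$chromosome[vi], v$position[vi],
                          genes$chromosome[gi], genes$start[gi],
                          genes$end[gi], cis_window_bp)
  out$eqtl_class <- cls$eqtl_class
  out$distance_bp <- cls$distance_bp
  out$q_value <- NA_real_
  if (pooled_fdr) {
    out$q_value <- bhFdr(out$p_value)
  } else {
    for (k in c("cis", "trans")) {
      sel <- out$eqtl_class == k
      if (any(sel)) out$q_value[sel] <- bhFdr(out$p_value[sel])
    }
  }
  out$significant <- out$q_value <= fdr
  out
}
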