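#' ANOVA for a hotspot genotype effect on a phenotype
#'
#' Fits trait ~ covariates + genotype by OLS with the genotype entered last
#' and reports the sequential-SS F test for the genotype factor. Genotype is
#' an unordered factor over dosage classes (AA/AB/BB); levels with fewer
#' than `min_level_n` observations are dropped (with a message) before
#' fitting.
#'
#' @param trait numeric phenotype vector.
#' @param dosage dosage vector (0/1/2), converted to AA/AB/BB.
#' @param covariates optional covariate data.frame (a `sample_id` column is
#'   ignored).
#' @param min_level_n minimum observations per retained genotype level.
#' @return list with `f_stat`, `p_value`, `df_genotype`, `df_residual`,
#'   `n_used`, `exact_fit` (TRUE when the residual SS is numerically zero,
#'   in which case `p_value` is reported below machine floor).
#' @export
anovaGenotypeEffect <- function(trait, dosage, covariates = NULL,
                                min_level_n = 2) {
  geno <- factor(c("AA", "AB", "BB")[dosage + 1], levels = c("AA", "AB", "BB"))
  keep_lvl <- names(which(table(geno) >= min_level_n))
  if (length(keep_lvl) < 2)
    stop("need at least two genotype levels with >= ", min_level_n,
         " observations")
  sel <- geno %in% keep_lvl
  if (any(!sel))
    message(sum(!sel), " sample(s) in sparse genotype level(s) dropped")
  geno <- droplevels(geno[sel])
  trait <- trait[sel]
  dat <- data.frame(.trait = trait, .geno = geno)
  form <- .trait ~ .geno
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)[sel, , drop = FALSE]
    covariates$sample_id <- NULL
    dat <- cbind(dat, covariates)
    form <- stats::as.formula(paste(".trait ~",
      paste(c(names(covariates), ".geno"), collapse = " + ")))
  }
  fit <- lm(form, data = dat)
  atab <- anova(fit)
  gi <- which(rownames(atab) == ".geno")
  ri <- which(rownames(atab) == "Residuals")
  ss_res <- atab[ri, "Sum Sq"]
  exact <- is.finite(ss_res) && ss_res < 1e-10 * sum(trait^2)
  f <- atab[gi, "F value"]
  p <- atab[gi, "Pr(>F)"]
  if (exact || !is.finite(f)) {
    f <- Inf
    p <- .Machine$double.xmin
  }
  list(f_stat = f, p_value = p,
       df_genotype = atab[gi, "Df"], df_residual = atab[ri, "Df"],
       n_used = sum(sel), exact_fit = exact)
}

#' BH correction across traits within one hotspot
#'
#' @param p_values vector of per-trait ANOVA p-values for one hotspot.
#' @return q-values (shared [bhFdr()] implementation).
#' @export
fdrAcrossTraits <- function(p_values) bhFdr(p_values)

#' Covariate-adjust a phenotype by fixed-effects residualisation
#'
#' Residuals of OLS of the trait on an intercept, dummy-coded factors and
#' numeric covariates; samples with missing covariates are dropped (NA in
#' the output, with a message).
#'
#' @param trait numeric phenotype vector.
#' @param covariates covariate data.frame (a `sample_id` column is ignored).
#' @return residual vector (mean ~ 0), same length/order as `trait`.
#' @export
adjustPhenotype <- function(trait, covariates) {
  covariates <- as.data.frame(covariates)
  covariates$sample_id <- NULL
  ok <- complete.cases(covariates) & !is.na(trait)
  if (any(!ok)) message(sum(!ok), " sample(s) with missing values dropped")
  X <- .covariateDesign(covariates[ok, , drop = FALSE], sum(ok))
  out <- rep(NA_real_, length(trait))
  out[ok] <- qr.resid(qr(X), trait[ok])
  out
}

#' Covariate-adjust an expression matrix
#'
#' Applies the [adjustPhenotype()] residualisation to every gene, removing
#' shared technical/structural variation (contemporary group, lane, age)
#' before correlation-based analyses such as the co-expression network.
#'
#' @param expression genes x samples matrix.
#' @param covariates covariate data.frame aligned to the columns.
#' @return residualised matrix of the same shape.
#' @export
adjustExpression <- function(expression, covariates) {
  covariates <- as.data.frame(covariates)
  covariates$sample_id <- NULL
  X <- .covariateDesign(covariates, ncol(expression))
  qrX <- qr(X)
  t(qr.resid(qrX, t(expression)))
}

#' Hotspot-by-trait association table
#'
#' Runs [anovaGenotypeEffect()] for every hotspot anchor against every
#' phenotype and applies BH across traits within each hotspot (the
#' per-hotspot FDR layout; `global_fdr = TRUE` pools all hotspot x trait
#' tests instead).
#'
#' @param hotspots hotspot calls (data.frame with `anchor_variant`).
#' @param geno [GenotypeData-class] containing the anchors.
#' @param phenotypes data.frame: `sample_id` plus one numeric column per
#'   trait, aligned to the genotype samples by id.
#' @param covariates optional covariate data.frame with `sample_id`.
#' @param global_fdr pool BH across all hotspots and traits.
#' @return data.frame: anchor_variant, trait, f_stat, p_value, q_value,
#'   df_genotype, df_residual.
#' @export
hotspotPhenotypeAssoc <- function(hotspots, geno, phenotypes,
                                  covariates = NULL, global_fdr = FALSE) {
  dosage <- dosageMatrix(geno)
  samples <- rownames(dosage)
  phenotypes <- phenotypes[match(samples, phenotypes$sample_id), ]
  if (anyNA(phenotypes$sample_id)) stop("phenotype sample ids do not match")
  if (!is.null(covariates))
    covariates <- covariates[match(samples, covariates$sample_id), ]
  traits <- setdiff(names(phenotypes), "sample_id")
  rows <- list()
  for (hv in hotspots$anchor_variant) {
    for (tr in traits) {
      a <- anovaGenotypeEffect(phenotypes[[tr]], dosage[, hv], covariates)
      rows[[paste(hv, tr)]] <- data.frame(
        anchor_variant = hv, trait = tr, f_stat = a$f_stat,
        p_value = a$p_value, df_genotype = a$df_genotype,
        df_residual = a$df_residual, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q_value <- NA_real_
  if (global_fdr) {
    out$q_value <- bhFdr(out$p_value)
  } else {
    for (hv in unique(out$anchor_variant)) {
      sel <- out$anchor_variant == hv
      out$q_value[sel] <- fdrAcrossTraits(out$p_value[sel])
    }
  }
  out
}
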