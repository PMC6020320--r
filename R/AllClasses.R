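#' @import methods
#' @import stats
#' @importFrom utils read.table write.table head modifyList
NULL

#' GenotypeData: sample-by-variant dosages plus a variant table
#'
#' Container for a biallelic genotype panel. The dosage matrix counts copies
#' of the alternate allele (0, 1, 2; `NA` = missing call) with samples in
#' rows and variants in columns. The variant table carries one row per
#' variant with its genomic coordinates, alleles, minor allele frequency and
#' call rate, in the same column order as the dosage matrix.
#'
#' Coordinates are 1-based throughout the package; only BED input/output
#' converts to/from the 0-based half-open convention.
#'
#' @slot dosage numeric matrix, samples x variants, entries in {0,1,2,NA}.
#' @slot variants data.frame with columns `variant_id`, `chromosome`,
#'   `position`, `ref`, `alt`, `maf`, `call_rate`.
#'
#' @export
setClass("GenotypeData",
  representation(dosage = "matrix", variants = "data.frame")
)

setValidity("GenotypeData", function(object) {
  msg <- character()
  v <- object@variants
  need <- c("variant_id", "chromosome", "position", "ref", "alt",
            "maf", "call_rate")
  if (!all(need %in% names(v)))
    msg <- c(msg, paste("variant table must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (ncol(object@dosage) != nrow(v))
      msg <- c(msg, "ncol(dosage) must equal nrow(variants)")
    if (anyDuplicated(v$variant_id))
      msg <- c(msg, "variant ids must be unique")
    if (any(v$position <= 0))
      msg <- c(msg, "positions must be positive (1-based)")
    if (any(v$maf < 0 | v$maf > 0.5, na.rm = TRUE))
      msg <- c(msg, "maf must lie in [0, 0.5]")
    if (any(v$call_rate < 0 | v$call_rate > 1, na.rm = TRUE))
      msg <- c(msg, "call_rate must lie in [0, 1]")
  }
  ok <- object@dosage %in% c(0, 1, 2) | is.na(object@dosage)
  if (!all(ok)) msg <- c(msg, "dosage entries must be 0, 1, 2 or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param dosage samples x variants dosage matrix with sample rownames and
#'   variant colnames.
#' @param variants variant table (see [GenotypeData-class]). `maf` and
#'   `call_rate` are recomputed from the dosages when missing.
#' @return A [GenotypeData-class] object.
#' @export
GenotypeData <- function(dosage, variants) {
  dosage <- as.matrix(dosage)
  if (is.null(colnames(dosage))) colnames(dosage) <- variants$variant_id
  if (is.null(variants$call_rate))
    variants$call_rate <- colMeans(!is.na(dosage))
  if (is.null(variants$maf)) {
    af <- colMeans(dosage, na.rm = TRUE) / 2
    variants$maf <- pmin(af, 1 - af)
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  rownames(variants) <- NULL
  new("GenotypeData", dosage = dosage, variants = variants)
}

#' @describeIn GenotypeData-class dosage matrix accessor
#' @param object,x a `GenotypeData` object
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))

#' @rdname GenotypeData-class
#' @export
setMethod("dosageMatrix", "GenotypeData", function(x) x@dosage)

#' @rdname GenotypeData-class
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname GenotypeData-class
#' @export
setMethod("variantInfo", "GenotypeData", function(x) x@variants)

#' @rdname GenotypeData-class
#' @export
setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object@dosage), "samples x",
      ncol(object@dosage), "variants on",
      length(unique(object@variants$chromosome)), "chromosome(s)\n")
  cat("  MAF range:",
      paste(signif(range(object@variants$maf, na.rm = TRUE), 3),
            collapse = " - "), "\n")
})

#' Subset a GenotypeData panel by variant
#'
#' @param x GenotypeData
#' @param keep logical or integer index over variants
#' @return GenotypeData restricted to the selected variants.
#' @export
subsetVariants <- function(x, keep) {
  new("GenotypeData", dosage = x@dosage[, keep, drop = FALSE],
      variants = x@variants[keep, , drop = FALSE])
}

#' Pssm: position-specific scoring matrix
#'
#' Probability and log-odds representation of a position frequency matrix.
#' Columns are motif positions; rows are bases A, C, G, T. `probs` columns
#' sum to one; `logOdds` is log2(probs / background).
#'
#' @slot probs 4 x L probability matrix.
#' @slot logOdds 4 x L log2-odds matrix (bits).
#' @slot background length-4 base composition, sums to one.
#' @slot pseudocount pseudocount added per cell when normalising counts.
#' @export
setClass("Pssm",
  representation(probs = "matrix", logOdds = "matrix",
                 background = "numeric", pseudocount = "numeric")
)

setValidity("Pssm", function(object) {
  msg <- character()
  if (nrow(object@probs) != 4 || nrow(object@logOdds) != 4)
    msg <- c(msg, "probs and logOdds must have 4 rows (A, C, G, T)")
  if (ncol(object@probs) != ncol(object@logOdds))
    msg <- c(msg, "probs and logOdds must have the same number of columns")
  if (any(abs(colSums(object@probs) - 1) > 1e-12))
    msg <- c(msg, "probs columns must sum to 1")
  if (length(object@background) != 4 ||
      abs(sum(object@background) - 1) > 1e-12)
    msg <- c(msg, "background must be 4 probabilities summing to 1")
  if (!all(is.finite(object@logOdds)))
    msg <- c(msg, "logOdds must be finite (use a positive pseudocount)")
  if (length(msg)) msg else TRUE
})

#' @rdname Pssm-class
#' @param x a `Pssm` object
#' @export
setGeneric("motifLength", function(x) standardGeneric("motifLength"))

#' @rdname Pssm-class
#' @export
setMethod("motifLength", "Pssm", function(x) ncol(x@probs))

#' @rdname Pssm-class
#' @param object a `Pssm` object
#' @export
setMethod("show", "Pssm", function(object) {
  cat("Pssm of length", ncol(object@probs), "| pseudocount",
      object@pseudocount, "\n")
  cons <- c("A", "C", "G", "T")[apply(object@probs, 2, which.max)]
  cat("  consensus:", paste(cons, collapse = ""), "\n")
})

#' ModuleSet: co-expression module assignment and eigengenes
#'
#' Result of module detection on one expression group. Genes not assigned
#' to any module carry the reserved label `"grey"`; grey is excluded from
#' eigengene summaries and trait testing.
#'
#' @slot labels named character vector, gene -> module label.
#' @slot eigengenes modules x samples matrix; each row is the unit-norm
#'   first right-singular vector of the module's standardised expression.
#' @slot varianceExplained named numeric, fraction of module variance
#'   captured by the eigengene.
#' @slot mergedHistory data.frame of merge events (`from`, `into`).
#' @export
setClass("ModuleSet",
  representation(labels = "character", eigengenes = "matrix",
                 varianceExplained = "numeric", mergedHistory = "data.frame")
)

setValidity("ModuleSet", function(object) {
  msg <- character()
  mods <- setdiff(unique(object@labels), "grey")
  if (length(mods) && !all(mods %in% rownames(object@eigengenes)))
    msg <- c(msg, "every non-grey module needs an eigengene row")
  if (nrow(object@eigengenes)) {
    nrm <- sqrt(rowSums(object@eigengenes^2))
    if (any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "eigengene rows must be unit-norm over samples")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname ModuleSet-class
#' @param x a `ModuleSet` object
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))

#' @rdname ModuleSet-class
#' @export
setMethod("moduleLabels", "ModuleSet", function(x) x@labels)

#' @rdname ModuleSet-class
#' @export
setGeneric("eigengenes", function(x) standardGeneric("eigengenes"))

#' @rdname ModuleSet-class
#' @export
setMethod("eigengenes", "ModuleSet", function(x) x@eigengenes)

#' @rdname ModuleSet-class
#' @export
setGeneric("varianceExplained", function(x) standardGeneric("varianceExplained"))

#' @rdname ModuleSet-class
#' @export
setMethod("varianceExplained", "ModuleSet", function(x) x@varianceExplained)

#' @rdname ModuleSet-class
#' @param object a `ModuleSet` object
#' @export
setMethod("show", "ModuleSet", function(object) {
  tab <- sort(table(object@labels), decreasing = TRUE)
  cat("ModuleSet:", sum(names(tab) != "grey"), "modules over",
      length(object@labels), "genes (",
      sum(object@labels == "grey"), "grey )\n")
  print(utils::head(tab, 10))
})
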