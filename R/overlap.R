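#' Basewise overlap between two region sets, in Mb
#'
#' Each set is reduced to its union first so overlapping intervals within a
#' set are not double-counted; the result is the total number of bases in
#' the intersection of the two unions, divided by 1e6.
#'
#' @param setA,setB `GRanges` region sets (1-based inclusive).
#' @return overlap in Mb.
#' @export
basewiseOverlap <- function(setA, setB) {
  inter <- GenomicRanges::intersect(GenomicRanges::reduce(setA),
                                    GenomicRanges::reduce(setB),
                                    ignore.strand = TRUE)
  sum(as.numeric(GenomicRanges::width(inter))) / 1e6
}

#' Sample random regions matched in size and chromosome
#'
#' One random interval per template interval, with the same length on the
#' same chromosome; the start is uniform over all valid placements. Sampled
#' intervals may overlap each other (no rejection).
#'
#' @param template `GRanges` to match.
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param no_self_overlap if `TRUE`, resample intervals that would overlap
#'   an already placed interval (up to 100 tries each).
#' @return `GRanges` of matched random regions.
#' @export
sampleMatchedRegions <- function(template, chrom_lengths,
                                 no_self_overlap = FALSE) {
  chr <- as.character(GenomicRanges::seqnames(template))
  w <- GenomicRanges::width(template)
  if (!all(chr %in% names(chrom_lengths)))
    stop("missing chromosome length for: ",
         paste(setdiff(chr, names(chrom_lengths)), collapse = ", "))
  len <- chrom_lengths[chr]
  if (any(w > len))
    stop("template interval longer than its chromosome")
  nplace <- len - w + 1
  start <- vapply(nplace, function(k) sample.int(k, 1), 1L)
  gr <- GenomicRanges::GRanges(chr, IRanges::IRanges(start, width = w))
  if (no_self_overlap) {
    for (i in seq_along(gr)) {
      tries <- 0
      while (i > 1 &&
             length(GenomicRanges::findOverlaps(gr[i], gr[seq_len(i - 1)])) &&
             tries < 100) {
        GenomicRanges::start(gr)[i] <- sample.int(nplace[i], 1)
        GenomicRanges::end(gr)[i] <- GenomicRanges::start(gr)[i] + w[i] - 1
        tries <- tries + 1
      }
    }
  }
  gr
}

## basewise overlap (bp) between interval set a (any order, may overlap)
## and a merged, sorted interval set b, on one chromosome
.overlapBp <- function(a_start, a_end, b_start, b_end) {
  if (!length(a_start) || !length(b_start)) return(0)
  o <- order(a_start)
  a_start <- a_start[o]; a_end <- cummax(a_end[o])
  # merge a: an interval starts a new block when it begins after the
  # running max end of everything before it
  new_blk <- c(TRUE, a_start[-1] > a_end[-length(a_end)] + 1)
  blk <- cumsum(new_blk)
  ms <- a_start[new_blk]
  me <- tapply(a_end, blk, max)
  total <- 0
  for (i in seq_along(ms)) {
    j <- which(b_end >= ms[i] & b_start <= me[i])
    if (length(j))
      total <- total + sum(pmin(b_end[j], me[i]) -
                             pmax(b_start[j], ms[i]) + 1)
  }
  total
}

#' Permutation test for region-set overlap
#'
#' The observed statistic is [basewiseOverlap()] between `setA` and `setB`;
#' the null resamples `setA` with size- and chromosome-matched random
#' regions. The p-value uses the add-one estimator
#' `(1 + #{perm >= obs}) / (1 + n_perm)` for `alternative = "greater"`
#' (mirrored for `"less"`), so `1/(n_perm+1) <= p <= 1`.
#'
#' @param setA,setB `GRanges` region sets.
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param n_perm number of permutations (>= 20 required).
#' @param seed RNG seed.
#' @param alternative `"greater"` (enrichment, default) or `"less"`.
#' @return object of class `overlapTest`: observed_mb, perm_mean_mb,
#'   perm_sd_mb, z, p_value, n_perm, alternative.
#' @export
permutationOverlapTest <- function(setA, setB, chrom_lengths,
                                   n_perm = 1000, seed = 1L,
                                   alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (n_perm < 20) stop("n_perm must be >= 20 for usable p resolution")
  set.seed(seed)
  obs <- basewiseOverlap(setA, setB)
  # plain-integer fast path for the permutation loop: per chromosome,
  # resample starts for the template widths and sweep the merged
  # intervals against the (pre-merged) reference set
  chrA <- as.character(GenomicRanges::seqnames(setA))
  wA <- GenomicRanges::width(setA)
  if (!all(chrA %in% names(chrom_lengths)))
    stop("missing chromosome length for: ",
         paste(setdiff(chrA, names(chrom_lengths)), collapse = ", "))
  if (any(wA > chrom_lengths[chrA]))
    stop("template interval longer than its chromosome")
  redB <- GenomicRanges::reduce(setB)
  chrB <- as.character(GenomicRanges::seqnames(redB))
  b_by_chr <- lapply(unique(chrA), function(ch) {
    sel <- chrB == ch
    list(start = GenomicRanges::start(redB)[sel],
         end = GenomicRanges::end(redB)[sel])
  })
  names(b_by_chr) <- unique(chrA)
  w_by_chr <- split(wA, chrA)
  perm <- vapply(seq_len(n_perm), function(i) {
    total <- 0
    for (ch in names(w_by_chr)) {
      w <- w_by_chr[[ch]]
      s <- floor(runif(length(w)) * (chrom_lengths[[ch]] - w + 1)) + 1
      total <- total + .overlapBp(s, s + w - 1,
                                  b_by_chr[[ch]]$start, b_by_chr[[ch]]$end)
    }
    total / 1e6
  }, 1)
  hits <- if (alternative == "greater") sum(perm >= obs) else sum(perm <= obs)
  p <- (1 + hits) / (1 + n_perm)
  s <- sd(perm)
  res <- list(observed_mb = obs, perm_mean_mb = mean(perm),
              perm_sd_mb = s,
              z = if (s > 0) (obs - mean(perm)) / s else NA_real_,
              p_value = p, n_perm = n_perm, alternative = alternative)
  class(res) <- "overlapTest"
  res
}

#' @export
print.overlapTest <- function(x, ...) {
  cat("Region-overlap permutation test (alternative:", x$alternative, ")\n")
  cat(sprintf("  observed %.4g Mb | null %.4g +/- %.4g Mb | z = %.3g | p = %.4g (%d perms)\n",
              x$observed_mb, x$perm_mean_mb, x$perm_sd_mb,
              ifelse(is.na(x$z), NaN, x$z), x$p_value, x$n_perm))
  invisible(x)
}

#' Classify an overlapping interval pair
#'
#' Exactly one of four categories: `AinB` (a contained in b, including
#' a == b), `BinA` (b strictly contained in a), `AleftB` (a overhangs b's
#' left end), `ArightB` (a overhangs b's right end).
#'
#' @param a_start,a_end,b_start,b_end 1-based inclusive interval bounds;
#'   the pair must overlap by at least 1 bp.
#' @return one of "AinB", "BinA", "AleftB", "ArightB".
#' @export
classifyOverlap <- function(a_start, a_end, b_start, b_end) {
  if (a_end < b_start || b_end < a_start)
    stop("intervals do not overlap")
  if (a_start >= b_start && a_end <= b_end) return("AinB")
  if (b_start >= a_start && b_end <= a_end) return("BinA")
  if (a_start < b_start) "AleftB" else "ArightB"
}

#' Per-pair overlap categories between two region sets
#'
#' Finds every overlapping pair between the unmerged inputs and tabulates
#' the four [classifyOverlap()] categories.
#'
#' @param setA,setB `GRanges` region sets.
#' @return data.frame with one row per overlapping pair: indices, category.
#' @export
overlapCategories <- function(setA, setB) {
  hits <- GenomicRanges::findOverlaps(setA, setB, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (!length(qi))
    return(data.frame(a = integer(), b = integer(),
                      category = character()))
  cat <- mapply(classifyOverlap,
                GenomicRanges::start(setA)[qi], GenomicRanges::end(setA)[qi],
                GenomicRanges::start(setB)[si], GenomicRanges::end(setB)[si])
  data.frame(a = qi, b = si, category = cat, stringsAsFactors = FALSE)
}
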