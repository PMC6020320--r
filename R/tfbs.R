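#' Convert a position frequency matrix to a PSSM
#'
#' `probs[b, j] = (counts[b, j] + pseudocount) / (colsum_j + 4 pseudocount)`;
#' `logOdds = log2(probs / background)`. A zero pseudocount is allowed only
#' when no column is all-zero, and produces -Inf log-odds for zero-count
#' cells (accepted for consensus-only matrices used in closed-form checks:
#' validity is relaxed there by clamping to a large negative score).
#'
#' @param counts 4 x L non-negative counts (rows A, C, G, T).
#' @param pseudocount per-cell pseudocount (default 0.25).
#' @param background length-4 base composition (default uniform).
#' @return A [Pssm-class] object.
#' @export
pfmToPssm <- function(counts, pseudocount = 0.25,
                      background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("counts must have 4 rows (A, C, G, T)")
  if (any(counts < 0)) stop("counts must be non-negative")
  cs <- colSums(counts)
  if (pseudocount == 0 && any(cs == 0))
    stop("all-zero column needs a positive pseudocount")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  probs <- sweep(counts + pseudocount, 2, cs + 4 * pseudocount, "/")
  lo <- log2(sweep(probs, 1, background, "/"))
  # consensus-only matrices (pseudocount 0) carry zero-probability cells;
  # clamp their log-odds so downstream arithmetic stays finite
  lo[probs == 0] <- -1e6
  dimnames(probs) <- dimnames(lo) <- list(c("A", "C", "G", "T"), NULL)
  new("Pssm", probs = probs, logOdds = lo,
      background = background, pseudocount = pseudocount)
}

#' Reverse-complement a PSSM
#' @param pssm A [Pssm-class].
#' @return The reverse-complemented [Pssm-class].
#' @export
reverseComplementPssm <- function(pssm) {
  rc <- function(m) m[4:1, rev(seq_len(ncol(m))), drop = FALSE]
  p <- rc(pssm@probs); l <- rc(pssm@logOdds)
  dimnames(p) <- dimnames(l) <- list(c("A", "C", "G", "T"), NULL)
  new("Pssm", probs = p, logOdds = l,
      background = pssm@background[4:1], pseudocount = pssm@pseudocount)
}

.baseCodes <- function(x) {
  code <- match(strsplit(toupper(x), "")[[1]], c("A", "C", "G", "T"))
  code[is.na(code)] <- 5L  # N and any ambiguity code: background-neutral
  code
}

#' Score one sequence window against a PSSM
#'
#' Sum of per-position log2-odds; `N` contributes the background-expected
#' value 0.
#'
#' @param pssm A [Pssm-class].
#' @param window character string over A, C, G, T, N of the motif's length.
#' @return log-odds score in bits.
#' @export
scoreWindow <- function(pssm, window) {
  L <- motifLength(pssm)
  code <- .baseCodes(window)
  if (length(code) != L)
    stop("window length ", length(code), " != motif length ", L)
  lo <- rbind(pssm@logOdds, 0)
  sum(lo[cbind(code, seq_len(L))])
}

## score distribution of a random background L-mer.
## Exact branch: DP over positions keeping every attainable sum (duplicates
## within 1e-12 merged); used while the state count stays enumerable.
## Long motifs fall back to a discretised grid (bin width <= 1e-3 bits).
.scoreDistribution <- function(pssm, grid = 1e-3, exact_limit = 3e5) {
  lo <- pssm@logOdds
  bg <- pssm@background
  L <- ncol(lo)
  if (4^L <= exact_limit) {
    vals <- 0; probs <- 1
    for (j in seq_len(L)) {
      vals <- rep(vals, each = 4) + lo[, j]
      probs <- rep(probs, each = 4) * bg
      o <- order(vals)
      vals <- vals[o]; probs <- probs[o]
      grp <- cumsum(c(TRUE, diff(vals) > 1e-12))
      probs <- as.vector(tapply(probs, grp, sum))
      vals <- vals[!duplicated(grp)]
    }
  } else {
    k <- round(lo / grid)
    offset <- sum(apply(k, 2, min))
    width <- sum(apply(k, 2, max) - apply(k, 2, min)) + 1L
    pv <- numeric(width); pv[1] <- 1
    at <- 0L
    for (j in seq_len(L)) {
      kj <- k[, j] - min(k[, j])
      acc <- numeric(width)
      for (b in 1:4)
        if (bg[b] > 0)
          acc[(kj[b] + 1):width] <- acc[(kj[b] + 1):width] +
            bg[b] * pv[1:(width - kj[b])]
      pv <- acc
    }
    nz <- which(pv > 0)
    vals <- (nz - 1 + offset) * grid
    probs <- pv[nz]
  }
  tail <- rev(cumsum(rev(probs)))
  list(values = vals, probs = probs, tail = tail)
}

#' Exact p-value of a PSSM score
#'
#' `P(score(W) >= s)` for a random L-mer `W` drawn from the PSSM's
#' background, by dynamic-programming convolution of the per-position score
#' distributions (exact for enumerable motifs; discretised at <= 1e-3 bits
#' for long ones).
#'
#' @param pssm A [Pssm-class].
#' @param score query score (finite).
#' @return p-value in \[0, 1\]; decreasing in `score`.
#' @export
exactScorePvalue <- function(pssm, score) {
  if (!is.finite(score)) stop("score must be finite")
  d <- .scoreDistribution(pssm)
  i <- findInterval(score - 1e-9, d$values) + 1L
  if (i > length(d$values)) return(0)
  d$tail[i]
}

#' Scan promoters for significant PSSM hits
#'
#' Scores every window of every promoter on both strands, converts scores
#' to exact background p-values, and reports hits with `p <= p_threshold`.
#' Offsets are 0-based within the forward-strand promoter; a minus-strand
#' hit at offset `o` covers forward positions `o+1 .. o+L`.
#'
#' @param pssm A [Pssm-class].
#' @param promoters named character vector or [Biostrings::DNAStringSet].
#' @param p_threshold per-window p-value threshold (default 0.05; 0 yields
#'   no hits). Per-window p-values are not multiplicity-corrected within a
#'   promoter; `bonferroni = TRUE` divides the threshold by the number of
#'   scanned windows per promoter.
#' @param bonferroni apply a per-promoter Bonferroni correction.
#' @return list with `hits` (data.frame: gene_id, offset, strand, score,
#'   p_value) and `gene_has_hit` (named logical over all scanned genes);
#'   genes shorter than the motif are skipped with a warning.
#' @export
scanPromoters <- function(pssm, promoters, p_threshold = 0.05,
                          bonferroni = FALSE) {
  if (is(promoters, "DNAStringSet"))
    promoters <- setNames(as.character(promoters), names(promoters))
  L <- motifLength(pssm)
  d <- .scoreDistribution(pssm)
  pOf <- function(s) {
    i <- findInterval(s - 1e-9, d$values) + 1L
    ifelse(i > length(d$values), 0, d$tail[i])
  }
  lo_ext <- rbind(pssm@logOdds, 0)
  scanOne <- function(codes) {
    W <- length(codes) - L + 1L
    s <- numeric(W)
    for (j in seq_len(L))
      s <- s + lo_ext[cbind(codes[j:(j + W - 1L)], j)]
    s
  }
  hits <- list()
  has <- logical(0)
  for (g in names(promoters)) {
    seqch <- promoters[[g]]
    if (nchar(seqch) < L) {
      warning("promoter of ", g, " shorter than the motif; skipped")
      next
    }
    thr <- if (bonferroni)
      p_threshold / (2 * (nchar(seqch) - L + 1)) else p_threshold
    fw <- scanOne(.baseCodes(seqch))
    rcch <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seqch)))
    rv <- scanOne(.baseCodes(rcch))
    pf <- pOf(fw); pr <- pOf(rv)
    sel_f <- which(thr > 0 & pf <= thr)
    sel_r <- which(thr > 0 & pr <= thr)
    gh <- data.frame(gene_id = character(), offset = integer(),
                     strand = character(), score = numeric(),
                     p_value = numeric(), stringsAsFactors = FALSE)
    if (length(sel_f))
      gh <- rbind(gh, data.frame(gene_id = g, offset = sel_f - 1L,
                                 strand = "+", score = fw[sel_f],
                                 p_value = pf[sel_f],
                                 stringsAsFactors = FALSE))
    if (length(sel_r))
      gh <- rbind(gh, data.frame(
        gene_id = g, offset = nchar(seqch) - L - (sel_r - 1L),
        strand = "-", score = rv[sel_r], p_value = pr[sel_r],
        stringsAsFactors = FALSE))
    hits[[g]] <- gh
    has[g] <- nrow(gh) > 0
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(gene_id = character(), offset = integer(),
               strand = character(), score = numeric(), p_value = numeric())
  rownames(hits) <- NULL
  list(hits = hits, gene_has_hit = has)
}

#' Fraction of target-gene promoters with a significant site
#'
#' @param gene_has_hit named logical from [scanPromoters()].
#' @param target_genes character vector of target gene ids (must be
#'   non-empty and covered by the indicators).
#' @return fraction in \[0, 1\].
#' @export
targetHitFraction <- function(gene_has_hit, target_genes) {
  if (!length(target_genes)) stop("empty target gene list")
  missing <- setdiff(target_genes, names(gene_has_hit))
  if (length(missing))
    stop("no scan result for target gene(s): ",
         paste(head(missing, 5), collapse = ", "))
  mean(gene_has_hit[target_genes])
}
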