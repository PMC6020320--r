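#' Linkage disequilibrium r-squared between two variants
#'
#' Squared Pearson correlation of allele dosages.
#'
#' @param g1,g2 dosage vectors of equal length.
#' @return r-squared in \[0, 1\].
#' @export
ldR2 <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("dosage vectors differ in length")
  if (var(g1, na.rm = TRUE) == 0 || var(g2, na.rm = TRUE) == 0)
    stop("LD undefined for a monomorphic variant")
  cor(g1, g2, use = "complete.obs")^2
}

#' Normalised linkage disequilibrium D-prime via EM haplotype phasing
#'
#' Estimates the four haplotype frequencies from unphased genotype dosages
#' by expectation-maximisation over the 3 x 3 genotype table (only
#' double-heterozygotes carry phase ambiguity), then computes
#' `D = p_AB - p_A p_B` and `D' = |D| / D_max`, where `D_max` is
#' `min(p_A p_b, p_a p_B)` for positive D and `min(p_A p_B, p_a p_b)`
#' otherwise.
#'
#' @param g1,g2 dosage vectors (0/1/2 alternate-allele counts).
#' @param max_iter,tol EM stopping rule (100 iterations or change < 1e-10).
#' @return list with `d_prime`, `d`, `haplotype_freqs` (pAB, pAb, paB, pab).
#' @export
ldDprime <- function(g1, g2, max_iter = 100, tol = 1e-10) {
  if (length(g1) != length(g2)) stop("dosage vectors differ in length")
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  if (var(g1) == 0 || var(g2) == 0)
    stop("D' undefined unless both variants are polymorphic")
  n <- length(g1)
  tab <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) tab[i + 1, j + 1] <- sum(g1 == i & g2 == j)
  pA <- mean(g1) / 2          # alt-allele frequency at locus 1 ("A")
  pB <- mean(g2) / 2
  pAB <- pA * pB              # start at linkage equilibrium
  for (it in seq_len(max_iter)) {
    pAb <- pA - pAB; paB <- pB - pAB; pab <- 1 - pA - pB + pAB
    # expected share of AB/ab phase among double heterozygotes
    denom <- pAB * pab + pAb * paB
    w <- if (denom > 0) pAB * pab / denom else 0.5
    nAB <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3] + w * tab[2, 2]
    new_pAB <- nAB / (2 * n)
    if (abs(new_pAB - pAB) < tol) { pAB <- new_pAB; break }
    pAB <- new_pAB
  }
  pAb <- pA - pAB; paB <- pB - pAB; pab <- 1 - pA - pB + pAB
  D <- pAB - pA * pB
  Dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (Dmax > 0) abs(D) / Dmax else 0
  list(d_prime = dprime, d = D,
       haplotype_freqs = c(pAB = pAB, pAb = pAb, paB = paB, pab = pab))
}
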