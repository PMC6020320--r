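consensusPssm2 <- function() {
  counts <- matrix(0, 4, 2, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts["A", 1] <- 10
  counts["C", 2] <- 10
  pfmToPssm(counts, pseudocount = 0)
}

test_that("PSSM construction follows the pseudocount formula", {
  pssm <- consensusPssm2()
  expect_equal(pssm@probs[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(scoreWindow(pssm, "AC"), 2 * log2(1 / 0.25))  # 4 bits

  flat <- pfmToPssm(matrix(5, 4, 3), pseudocount = 0.25)
  expect_true(all(abs(flat@logOdds) < 1e-12))

  rich <- pfmToPssm(demoPfm(8), pseudocount = 0.25)
  expect_true(all(is.finite(rich@logOdds)))
  expect_true(all(abs(colSums(rich@probs) - 1) < 1e-12))
  expect_equal(motifLength(rich), 8)

  expect_error(pfmToPssm(matrix(1, 3, 2)), "4 rows")
  expect_error(pfmToPssm(matrix(-1, 4, 2)), "non-negative")
  expect_error(pfmToPssm(matrix(0, 4, 2), pseudocount = 0), "all-zero")
})

test_that("window scoring handles N and strand symmetry", {
  pssm <- pfmToPssm(demoPfm(4, seed = 5))
  expect_equal(scoreWindow(pssm, "NNNN"), 0)
  expect_error(scoreWindow(pssm, "ACG"), "length")

  rc <- reverseComplementPssm(pssm)
  set.seed(2)
  for (i in 1:10) {
    w <- paste(sample(c("A", "C", "G", "T"), 4, TRUE), collapse = "")
    wrc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(w)))
    expect_equal(scoreWindow(pssm, w), scoreWindow(rc, wrc),
                 tolerance = 1e-12)
  }
})

test_that("exact score p-values match full enumeration for L <= 6", {
  expect_equal(exactScorePvalue(consensusPssm2(), 4), 1 / 16)

  set.seed(7)
  for (L in 2:6) {
    counts <- matrix(rpois(4 * L, 5), 4, L)
    pssm <- pfmToPssm(counts, pseudocount = 0.25)
    d_min <- min(pssm@logOdds) * L
    expect_equal(exactScorePvalue(pssm, d_min), 1)
    for (q in c(0.2, 0.5, 0.9)) {
      s <- sum(apply(pssm@logOdds, 2, quantile, q))
      expect_equal(exactScorePvalue(pssm, s), enumScorePvalue(pssm, s),
                   tolerance = 1e-9)
    }
  }

  # non-uniform background
  bg <- c(0.4, 0.1, 0.1, 0.4)
  pssm_bg <- pfmToPssm(matrix(rpois(16, 4), 4, 4), background = bg)
  s <- median(pssm_bg@logOdds) * 4
  expect_equal(exactScorePvalue(pssm_bg, s), enumScorePvalue(pssm_bg, s),
               tolerance = 1e-9)
})

test_that("grid DP for long motifs stays close to the exact branch", {
  set.seed(11)
  counts <- matrix(rpois(4 * 6, 5), 4, 6)
  pssm <- pfmToPssm(counts)
  s <- sum(apply(pssm@logOdds, 2, median))
  exact <- exactScorePvalue(pssm, s)
  grid <- eqtlHotspots:::.scoreDistribution(pssm, exact_limit = 1)
  i <- findInterval(s - 1e-9, grid$values) + 1L
  approx_p <- if (i > length(grid$values)) 0 else grid$tail[i]
  expect_equal(approx_p, exact, tolerance = 1e-3)
})

test_that("promoter scanning reports planted hits and respects thresholds", {
  set.seed(3)
  pssm <- pfmToPssm(demoPfm(8, depth = 100, seed = 4))
  cons <- paste(c("A", "C", "G", "T")[apply(pssm@probs, 2, which.max)],
                collapse = "")
  bases <- c("A", "C", "G", "T")
  prom <- vapply(1:5, function(i)
    paste(sample(bases, 300, TRUE), collapse = ""), "")
  names(prom) <- paste0("g", 1:5)
  substr(prom["g2"], 101, 108) <- cons

  scan <- scanPromoters(pssm, prom, p_threshold = 1e-4)
  hit2 <- scan$hits[scan$hits$gene_id == "g2", ]
  expect_true(any(hit2$offset == 100 & hit2$strand == "+"))

  none <- scanPromoters(pssm, prom, p_threshold = 0)
  expect_equal(nrow(none$hits), 0)
  expect_true(all(!none$gene_has_hit))

  # monotonicity: larger threshold never removes hits
  loose <- scanPromoters(pssm, prom, p_threshold = 0.05)
  key <- function(h) paste(h$gene_id, h$offset, h$strand)
  expect_true(all(key(scan$hits) %in% key(loose$hits)))

  short <- c(prom, tiny = "ACGT")
  expect_warning(res <- scanPromoters(pssm, short, 0.05), "shorter")
  expect_false("tiny" %in% names(res$gene_has_hit))
})

test_that("strand symmetry: reverse-complemented scan mirrors hits", {
  set.seed(5)
  pssm <- pfmToPssm(matrix(rpois(4 * 5, 3), 4, 5))
  seqch <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  fw <- scanPromoters(pssm, c(g = seqch), 0.05)$hits
  rcseq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seqch)))
  rv <- scanPromoters(reverseComplementPssm(pssm), c(g = rcseq), 0.05)$hits
  # double reverse-complement: hits mirror in offset, strand is preserved
  expect_equal(nrow(fw), nrow(rv))
  mirrored <- data.frame(offset = 200 - 5 - rv$offset, strand = rv$strand)
  expect_setequal(paste(fw$offset, fw$strand),
                  paste(mirrored$offset, mirrored$strand))
  expect_equal(sort(fw$score), sort(rv$score), tolerance = 1e-12)
})

test_that("null hit fraction matches the closed-form approximation", {
  set.seed(17)
  pssm <- pfmToPssm(matrix(rpois(4 * 6, 5), 4, 6))
  # realised per-window significance level at the 0.05 cut
  d <- eqtlHotspots:::.scoreDistribution(pssm)
  p_site <- max(d$tail[d$tail <= 0.05])
  bases <- c("A", "C", "G", "T")
  prom <- vapply(1:300, function(i)
    paste(sample(bases, 1500, TRUE), collapse = ""), "")
  names(prom) <- paste0("g", 1:300)
  scan <- scanPromoters(pssm, prom, 0.05)
  expected <- 1 - (1 - p_site)^(2 * (1500 - 6 + 1))
  expect_lt(abs(mean(scan$gene_has_hit) - expected), 0.05)
})

test_that("target hit fraction summarises indicators", {
  ind <- c(g1 = TRUE, g2 = FALSE, g3 = TRUE, g4 = TRUE)
  expect_equal(targetHitFraction(ind, c("g1", "g3")), 1)
  expect_equal(targetHitFraction(ind, c("g1", "g2")), 0.5)
  expect_error(targetHitFraction(ind, character()), "empty")
  expect_error(targetHitFraction(ind, "g9"), "no scan result")
})
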