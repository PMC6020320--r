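# shared fixture builders (everything generated in code, no files)

# two planted co-expression blocks plus independent noise genes
makeBlockExpression <- function(n_samples = 200, block_size = 50,
                                n_noise = 40, signal_sd = 1,
                                noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  f1 <- rnorm(n_samples, 0, signal_sd)
  f2 <- rnorm(n_samples, 0, signal_sd)
  blk1 <- t(sapply(seq_len(block_size), function(i)
    f1 + rnorm(n_samples, 0, noise_sd)))
  blk2 <- t(sapply(seq_len(block_size), function(i)
    f2 + rnorm(n_samples, 0, noise_sd)))
  noise <- matrix(rnorm(n_noise * n_samples), n_noise, n_samples)
  x <- rbind(blk1, blk2, noise)
  rownames(x) <- sprintf("g%03d", seq_len(nrow(x)))
  colnames(x) <- sprintf("s%03d", seq_len(ncol(x)))
  truth <- rep(c("block1", "block2", "noise"),
               c(block_size, block_size, n_noise))
  list(expression = x, truth = setNames(truth, rownames(x)))
}

# brute-force topological overlap via explicit triple sum
bruteForceTom <- function(a) {
  n <- nrow(a)
  tom <- diag(n)
  k <- rowSums(a)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# enumeration oracle: exact tail probability of a PSSM score over all
# background L-mers
enumScorePvalue <- function(pssm, score) {
  L <- motifLength(pssm)
  grid <- expand.grid(rep(list(c("A", "C", "G", "T")), L),
                      stringsAsFactors = FALSE)
  scores <- apply(grid, 1, function(w)
    scoreWindow(pssm, paste(w, collapse = "")))
  probs <- apply(grid, 1, function(w)
    prod(pssm@background[match(w, c("A", "C", "G", "T"))]))
  sum(probs[scores >= score - 1e-9])
}

# minimal genotype panel from an explicit dosage matrix
makeGeno <- function(dosage, chrom = "chr1",
                     pos = seq_len(ncol(dosage)) * 1000L) {
  colnames(dosage) <- sprintf("v%03d", seq_len(ncol(dosage)))
  rownames(dosage) <- sprintf("s%03d", seq_len(nrow(dosage)))
  GenotypeData(dosage, data.frame(
    variant_id = colnames(dosage),
    chromosome = rep(chrom, length.out = ncol(dosage)),
    position = pos, ref = "A", alt = "G", stringsAsFactors = FALSE))
}
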