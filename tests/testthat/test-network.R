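test_that("genotype split partitions AA/AB and excludes BB", {
  d <- setNames(c(0, 0, 1, 1, 2), paste0("s", 1:5))
  sp <- splitByGenotype(d, min_group = 1)
  expect_equal(sp$AA, c("s1", "s2"))
  expect_equal(sp$AB, c("s3", "s4"))
  expect_equal(sp$n_excluded, 1)
  expect_error(splitByGenotype(rep(0, 10)), "monomorphic")
  expect_warning(splitByGenotype(setNames(c(0, rep(1, 20)), 1:21)),
                 "flagged")
})

test_that("adjacency follows |cor|^power with zero diagonal", {
  set.seed(1)
  x <- matrix(rnorm(5 * 30), 5, 30,
              dimnames = list(paste0("g", 1:5), NULL))
  x[2, ] <- x[1, ]
  a <- adjacencyMatrix(x, soft_power = 6)
  expect_equal(a[1, 2], 1)
  expect_equal(diag(a), rep(0, 5), ignore_attr = TRUE)
  expect_equal(a, t(a))
  expect_equal(a[3, 4], abs(cor(x[3, ], x[4, ]))^6, tolerance = 1e-12)
  expect_equal(0.5^6, 0.015625)   # the power map at cor = 0.5

  a1 <- adjacencyMatrix(x, soft_power = 1)
  expect_equal(a1[3, 5], abs(cor(x[3, ], x[5, ])), tolerance = 1e-12)

  x[3, ] <- 1
  expect_error(adjacencyMatrix(x), "zero-variance")
})

test_that("scale-free fit index detects planted power-law degrees", {
  set.seed(2)
  n <- 600
  # expected configuration-model adjacency: row sums follow the planted
  # power-law degree sequence k_i (a_ij = k_i k_j / sum k)
  k <- (runif(n)^(-1 / 1.5))            # Pareto tail, gamma = 2.5
  k <- pmin(k, 60)
  a <- outer(k, k) / sum(k)
  diag(a) <- 0
  fit <- scaleFreeFit(a)
  expect_gte(fit$r_squared, 0.9)
  expect_lt(fit$slope, 0)

  expect_error(scaleFreeFit(matrix(0.5, 30, 30) - diag(30) * 0.5),
               "equal")
  expect_error(scaleFreeFit(matrix(0, 5, 5)), "20 genes")

  perm <- sample.int(n)
  expect_equal(scaleFreeFit(a[perm, perm])$r_squared, fit$r_squared,
               tolerance = 1e-12)
})

test_that("TOM matches the closed forms and the brute-force oracle", {
  # 3-node clique with unit adjacency
  a3 <- matrix(1, 3, 3) - diag(3)
  t3 <- tomMatrix(a3)
  expect_equal(t3[1, 2], 1)
  expect_equal(diag(t3), rep(1, 3))

  # two isolated nodes with a single 0.5 edge
  a2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  expect_equal(tomMatrix(a2)[1, 2], 0.5)

  set.seed(3)
  for (rep in 1:3) {
    x <- matrix(rnorm(20 * 40), 20, 40)
    a <- adjacencyMatrix(x, 6)
    expect_equal(tomMatrix(a), bruteForceTom(a), tolerance = 1e-12)
  }
  expect_error(tomMatrix(matrix(2, 3, 3)), "\\[0, 1\\]")

  a <- adjacencyMatrix(matrix(rnorm(30 * 25), 30, 25), 6)
  tom <- tomMatrix(a)
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_equal(tom, t(tom), tolerance = 1e-12)
})

test_that("module detection recovers planted blocks and leaves noise grey", {
  fx <- makeBlockExpression(n_samples = 150, block_size = 40,
                            n_noise = 30, seed = 4)
  tom <- tomMatrix(adjacencyMatrix(fx$expression, 6))
  labels <- detectModules(1 - tom, min_module_size = 30, deep_split = 2)
  blocks <- fx$truth != "noise"
  ari <- mclust::adjustedRandIndex(labels[blocks], fx$truth[blocks])
  expect_gte(ari, 0.9)
  expect_gt(mean(labels[fx$truth == "noise"] == "grey"), 0.5)

  # block smaller than the minimum size stays grey
  small <- makeBlockExpression(n_samples = 100, block_size = 10,
                               n_noise = 40, seed = 5)
  tom_s <- tomMatrix(adjacencyMatrix(small$expression, 6))
  lab_s <- detectModules(1 - tom_s, min_module_size = 30, deep_split = 2)
  expect_true(all(lab_s[small$truth == "block1"] == "grey"))

  # pure noise: mostly grey
  noise <- matrix(rnorm(80 * 100), 80, 100,
                  dimnames = list(paste0("g", 1:80), NULL))
  tom_n <- tomMatrix(adjacencyMatrix(noise, 6))
  lab_n <- detectModules(1 - tom_n, 30, 2)
  expect_gte(mean(lab_n == "grey"), 0.8)

  expect_warning(detectModules(matrix(0, 5, 5), 30), "all grey")
})

test_that("module eigengene equals the leading singular vector", {
  fx <- makeBlockExpression(n_samples = 80, block_size = 35, n_noise = 0,
                            seed = 6)
  labels <- setNames(ifelse(fx$truth == "block1", "blue", "red"),
                     names(fx$truth))
  ms <- moduleEigengene(fx$expression, labels)
  ev <- eigengenes(ms)
  expect_equal(sqrt(rowSums(ev^2)), c(blue = 1, red = 1))

  X <- t(scale(t(fx$expression[labels == "blue", ])))
  v1 <- svd(X)$v[, 1]
  expect_lt(min(sum((ev["blue", ] - v1)^2),
                sum((ev["blue", ] + v1)^2)), 1e-20)
  # sign convention: positive mean member correlation
  expect_gt(mean(cor(ev["blue", ], t(X))), 0)

  # module of identical genes: variance fully explained
  ident <- matrix(rep(rnorm(50), 3), 3, byrow = TRUE,
                  dimnames = list(paste0("g", 1:3), NULL))
  ms2 <- moduleEigengene(ident + rnorm(150) * 1e-12,
                         setNames(rep("m1", 3), rownames(ident)))
  expect_equal(unname(varianceExplained(ms2)["m1"]), 1, tolerance = 1e-6)
})

test_that("module merging joins correlated eigengenes and is idempotent", {
  set.seed(8)
  n <- 120
  f <- rnorm(n)
  # two modules driven by the same factor (ME cor ~ 0.95) plus one
  # independent module
  x <- rbind(
    t(sapply(1:35, function(i) f + rnorm(n, 0, 0.3))),
    t(sapply(1:35, function(i) f + rnorm(n, 0, 0.35))),
    t(sapply(1:35, function(i) rnorm(n))))
  rownames(x) <- paste0("g", seq_len(nrow(x)))
  labels <- setNames(rep(c("blue", "red", "green"), each = 35),
                     rownames(x))
  merged <- mergeModules(x, labels, merge_height = 0.25)
  labs <- moduleLabels(merged)
  expect_equal(labs[["g1"]], labs[["g40"]])       # blue and red merged
  expect_false(labs[["g1"]] == labs[["g80"]])     # green stays apart
  expect_gt(nrow(merged@mergedHistory), 0)

  again <- mergeModules(x, labs, merge_height = 0.25)
  expect_identical(moduleLabels(again), labs)
})

test_that("TOM scaling matches the closed-form exponent", {
  expect_equal(log(0.5) / log(0.25), 0.5)
  set.seed(9)
  t1 <- tomMatrix(adjacencyMatrix(matrix(rnorm(40 * 30), 40, 30), 6))
  t2 <- tomMatrix(adjacencyMatrix(matrix(rnorm(40 * 200), 40, 200), 6))
  sc <- scaleTom(t1, t2, 0.95)
  off <- function(m) m[upper.tri(m)]
  expect_equal(quantile(off(sc$tom), 0.95, names = FALSE, type = 1),
               quantile(off(t2), 0.95, names = FALSE, type = 1),
               tolerance = 1e-6)
  # identity when the quantiles already agree
  sc_id <- scaleTom(t1, t1, 0.95)
  expect_equal(sc_id$exponent, 1, tolerance = 1e-12)
  expect_equal(sc_id$tom, t1, tolerance = 1e-12)
  # order preservation
  o1 <- order(off(t1)); o2 <- order(off(sc$tom))
  expect_identical(o1, o2)
})

test_that("module-trait correlation uses the Student transform", {
  fx <- makeBlockExpression(n_samples = 60, block_size = 30, n_noise = 0,
                            seed = 10)
  labels <- setNames(ifelse(fx$truth == "block1", "blue", "red"),
                     names(fx$truth))
  ms <- moduleEigengene(fx$expression, labels)
  traits <- cbind(t1 = eigengenes(ms)["blue", ],
                  t2 = rnorm(60))
  mtc <- moduleTraitCorrelation(ms, traits)
  expect_equal(mtc$r["blue", "t1"], 1, tolerance = 1e-12)
  expect_lt(mtc$p["blue", "t1"], 1e-12)
  # p matches the closed-form transform of r
  r <- mtc$r["red", "t2"]
  t_ref <- abs(r) * sqrt(58) / sqrt(1 - r^2)
  expect_equal(mtc$p["red", "t2"], 2 * pt(t_ref, 58, lower.tail = FALSE),
               tolerance = 1e-12)
  # worked value: r = 0.444 at n = 20 sits at the 5% boundary
  t20 <- 0.444 * sqrt(18) / sqrt(1 - 0.444^2)
  expect_equal(2 * pt(t20, 18, lower.tail = FALSE), 0.05, tolerance = 0.01)
  expect_error(moduleTraitCorrelation(ms, traits[1:3, ]), "match")
})

test_that("GS and MM follow their definitions and symmetries", {
  set.seed(11)
  x <- matrix(rnorm(4 * 50), 4, 50, dimnames = list(paste0("g", 1:4), NULL))
  trait <- x[2, ]
  gs <- geneSignificance(x, trait)
  expect_equal(unname(gs["g2"]), 1)
  expect_equal(gs, geneSignificance(x, -trait))   # GS is |cor|

  e <- x[1, ]
  mm <- moduleMembership(x, e)
  expect_equal(unname(mm["g1"]), 1)
  expect_equal(moduleMembership(x, -e), -mm)      # MM is signed
  expect_error(geneSignificance(x, rep(1, 50)), "zero-variance")
})

test_that("hub selection is capped, ranked by |MM| and deterministic", {
  mm <- setNames(c(0.9, -0.95, 0.2, 0.5), paste0("g", 1:4))
  expect_equal(selectHubGenes(mm, 2), c("g2", "g1"))
  expect_equal(selectHubGenes(mm, 20), c("g2", "g1", "g4", "g3"))
  perm <- mm[c(3, 1, 4, 2)]
  expect_equal(selectHubGenes(perm, 20), selectHubGenes(mm, 20))
  tie <- setNames(c(0.5, 0.5), c("gB", "gA"))
  expect_equal(selectHubGenes(tie, 1), "gA")
  expect_error(selectHubGenes(numeric()), "empty")
})

test_that("trait-module selection needs three traits below p = 0.1", {
  p <- rbind(blue = c(0.05, 0.05, 0.05, 0.9),
             red = c(0.05, 0.05, 0.5, 0.9),
             grey = c(0.01, 0.01, 0.01, 0.01))
  mtc <- list(p = p, r = p)
  expect_equal(selectTraitModules(mtc), "blue")
  expect_false("grey" %in% selectTraitModules(mtc))
})
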