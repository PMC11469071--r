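# Diversity statistics, windows, LD, PCA and rank tests.

test_that("Watterson's theta follows S / (a_{n-1} L)", {
  expect_equal(wattersonTheta(5, 2, 100), 0.05)
  expect_equal(wattersonTheta(3, 4, 1), 18 / 11)
  expect_equal(wattersonTheta(0, 10, 100), 0)
  expect_error(wattersonTheta(3, 4, 0), "length")
})

test_that("nucleotide diversity uses pairwise differences over accessible sites", {
  # 2 haplotypes (1 diploid would be degenerate; use 1 het individual x2):
  # emulate 2 haplotypes with one individual per haplotype is not possible
  # diploid-wise, so check the n = 4 identity instead and the 2-hap formula
  # through the site-term oracle
  dos <- matrix(c(1, 1), nrow = 2, ncol = 1)  # n = 4 haplotypes, c = 2
  gm <- make_gm(dos)
  pi <- nucleotideDiversity(gm, nAccessible = 1)
  expect_equal(as.numeric(pi), 2 * 2 * 2 / (4 * 3))  # 2/3
  # brute-force pairwise oracle over all 6 haplotype pairs
  haps <- c(1, 0, 1, 0)  # dosages (1,1) as two het individuals
  diffs <- combn(4, 2, function(ix) haps[ix[1]] != haps[ix[2]])
  expect_equal(as.numeric(pi), mean(diffs))
  # divisor linearity: halving the accessible length doubles pi
  expect_equal(as.numeric(nucleotideDiversity(gm, 2)) * 2,
               as.numeric(nucleotideDiversity(gm, 1)))
  # 3 differing sites of 100 accessible
  dos2 <- matrix(c(1, 1, 1), nrow = 1, ncol = 3)  # one het individual: n=2
  gm2 <- make_gm(dos2)
  expect_equal(as.numeric(nucleotideDiversity(gm2, 100)), 0.03)
})

test_that("pi computed from the SFS equals pi from pairwise differences", {
  set.seed(21)
  for (rep in 1:100) {
    nInd <- sample(3:8, 1)
    nSite <- sample(5:40, 1)
    dos <- matrix(sample(0:2, nInd * nSite, replace = TRUE), nrow = nInd)
    gm <- make_gm(dos, pos = seq_len(nSite) * 7L)
    sfs <- unfoldedSFS(gm)
    expect_equal(piFromSFS(sfs), sum(.pi_terms_for_test(dos)),
                 tolerance = 1e-9)
  }
})

test_that("Tajima's D is zero at the neutral identity and positive for doubleton excess", {
  # construct an SFS with pi_total exactly S/a1
  n <- 4; a1 <- sum(1 / (1:3))
  # neutral-shaped SFS xi_i = C/i gives pi = S/a1 by identity
  xi <- 12 / (1:3)
  expect_equal(tajimasD(SFS1D(xi, n)), 0, tolerance = 1e-12)
  # all doubletons: intermediate-frequency excess, D > 0 (checked against
  # the brute-force formula)
  xiD <- c(0, 10, 0)
  S <- 10
  piT <- piFromSFS(SFS1D(xiD, 4))
  a2 <- sum(1 / (1:3)^2)
  b1 <- 5 / 9; b2 <- 2 * (16 + 4 + 3) / (9 * 4 * 3)
  c1 <- b1 - 1 / a1; c2 <- b2 - 6 / (a1 * 4) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  Dref <- (piT - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  D <- tajimasD(SFS1D(xiD, 4))
  expect_gt(D, 0)
  expect_equal(D, Dref)
  expect_error(tajimasD(SFS1D(c(0, 0, 0), 4)), "S = 0")
})

test_that("windowed statistics tile accessible sites and match hand counts", {
  # 1 chromosome of 200 positions, all accessible; windows of 100 sites
  mask <- list(chr1 = rep(TRUE, 200))
  set.seed(22)
  dos <- matrix(sample(0:2, 10 * 20, replace = TRUE), nrow = 10)
  pos <- sort(sample(1:200, 20))
  gm <- make_gm(dos, pos = pos)
  ws <- windowedStats(gm, mask, windowSize = 100)
  expect_equal(nrow(ws), 2L)
  expect_equal(ws$n_accessible, c(100L, 100L))
  # S per window matches a hand count of polymorphic variants in each half
  nc <- 2 * colSums(!is.na(dos)); alt <- colSums(dos)
  poly <- alt > 0 & alt < nc
  expect_equal(ws$S, c(sum(poly & pos <= 100), sum(poly & pos > 100)))
  # uniform fixture: per-window pi equals global pi
  expect_equal(sum(ws$pi * ws$n_accessible) / 200,
               sum(.pi_terms_for_test(dos)) / 200)
  # masking out half the sites halves the accessible denominator
  mask2 <- list(chr1 = c(rep(TRUE, 100), rep(FALSE, 100)))
  ws2 <- windowedStats(gm, mask2, windowSize = 100)
  expect_equal(nrow(ws2), 1L)
  # window boundaries never split a site: each variant lands in one window
  expect_equal(sum(ws$S), sum(poly))
})

test_that("piN/piS responds to the generator's purifying-selection thinning", {
  expect_equal(pinpsRatio(0.001, 0.001), 1)
  expect_error(pinpsRatio(0.001, 0), "undefined")
  d0 <- data.frame(pi = c(0.5e-3, 0.7e-3))
  d4 <- data.frame(pi = c(1.0e-3, 1.4e-3))
  expect_equal(pinpsRatio(d0, d4), 0.5)
})

test_that("genotype r2 equals the brute-force dosage correlation", {
  a <- c(0, 1, 2, 0, 1, 2)
  expect_equal(ldR2(a, a), 1)
  b <- rev(a)
  expect_equal(ldR2(a, b), ldR2(b, a))        # symmetry
  set.seed(23)
  x <- sample(0:2, 6, replace = TRUE); y <- sample(0:2, 6, replace = TRUE)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ldR2(x, y), (num / den)^2)
  expect_true(is.na(ldR2(rep(1, 6), y)))      # zero variance undefined
})

test_that("LD decay is flat at the finite-sample baseline for unlinked loci", {
  set.seed(24)
  nInd <- 25
  freqs <- runif(400, 0.2, 0.8)
  dos <- vapply(freqs, function(f) rbinom(nInd, 2, f), numeric(nInd))
  gm <- make_gm(dos, pos = sort(sample(1:9e4, 400)))
  curve <- ldDecayCurve(gm, maxDist = 1e5, binWidth = 2e4)
  got <- curve$mean_r2[curve$n_pairs > 200]
  # E[r2] ~ 1/n for independent sites
  expect_true(all(abs(got - 1 / nInd) < 0.03))
  # singleton exclusion: with mafMin set, no singleton enters any pair
  dos2 <- cbind(dos, c(1L, rep(0L, nInd - 1)))
  gm2 <- make_gm(dos2, pos = c(siteInfo(gm)$pos, 99999L))
  c1 <- ldDecayCurve(gm2, maxDist = 1e5, binWidth = 2e4)
  expect_equal(sum(c1$n_pairs), sum(curve$n_pairs))
})

test_that("block-correlated fixtures yield decaying LD and prune correctly", {
  set.seed(25)
  nInd <- 30
  freqs <- runif(150, 0.3, 0.7)
  dos <- vapply(freqs, function(f) rbinom(nInd, 2, f), numeric(nInd))
  gm <- make_gm(dos, pos = sort(sample(1:3e4, 150)))
  gmLD <- generateBlockLD(gm, blockBp = 1000, rho = 0.9, seed = 1)
  curve <- ldDecayCurve(gmLD, maxDist = 6000, binWidth = 1500)
  ok <- which(curve$n_pairs > 30)
  # monotone non-increasing fitted trend: near bins exceed far bins
  expect_gt(curve$mean_r2[ok[1]], curve$mean_r2[ok[length(ok)]])
})

test_that("greedy LD pruning matches the exhaustive-pass oracle and audits clean", {
  set.seed(26)
  for (rep in 1:5) {
    nInd <- 20
    base <- rbinom(nInd, 2, 0.5)
    dos <- vapply(1:10, function(j) {
      flip <- runif(nInd) < 0.3
      out <- base; out[flip] <- sample(0:2, sum(flip), replace = TRUE)
      out
    }, numeric(nInd))
    gm <- make_gm(dos, pos = sort(sample(1:4e4, 10)))
    got <- ldPrune(gm, windowBp = 50000, stepBp = 10000, r2Max = 0.1)
    oracle <- brute_ld_prune(gm, 50000, 10000, 0.1)
    expect_equal(got, oracle)
    # post-condition audit: no surviving pair with r2 > 0.1 in any window
    cl <- calls(gm)[, got, drop = FALSE]
    if (length(got) > 1) {
      pr <- combn(length(got), 2, function(ix) ldR2(cl[, ix[1]], cl[, ix[2]]))
      expect_true(all(is.na(pr) | pr <= 0.1))
    }
  }
  # duplicate sites 100 bp apart: the later one is removed
  dup <- make_gm(cbind(c(0, 1, 2, 1, 0), c(0, 1, 2, 1, 0)),
                 pos = c(100L, 200L))
  expect_equal(ldPrune(dup), 1L)
  # all pairwise r2 <= threshold: identity
  set.seed(27)
  ind <- vapply(1:5, function(j) rbinom(40, 2, 0.5), numeric(40))
  gmi <- make_gm(ind, pos = (1:5) * 1000L)
  expect_equal(ldPrune(gmi, r2Max = 0.5), 1:5)
})

test_that("PCA separates diverged demes and behaves under permutation", {
  ev <- data.frame(time_gen = 20000, type = "split", pop = "b", dest = "a",
                   Ne = 2000, stringsAsFactors = FALSE)
  m <- DemographicModel(c("a", "b"), c(2000, 2000), ev, mu = 1e-6)
  g <- simulateGenotypes(m, sampleConfig(c(a = 20, b = 20), L = 5e4),
                         nLoci = 40, seed = 31)
  # drop singletons as in the standard protocol
  cnt <- colSums(calls(g)); n <- 2 * nrow(calls(g))
  g <- subsetGenotypes(g, j = cnt > 1 & cnt < n - 1)
  pca <- genotypePCA(g, nPC = 3)
  expect_gt(pca$varianceFraction[1], 0.5)
  grpMean <- tapply(pca$coords[, 1], sampleInfo(g)$population, mean)
  expect_gt(abs(diff(grpMean)),
            3 * max(tapply(pca$coords[, 1], sampleInfo(g)$population, sd)))
  # variance fractions are non-increasing
  expect_true(all(diff(pca$varianceFraction) <= 1e-12))
  # permuting individuals permutes coordinate rows
  perm <- sample(nrow(calls(g)))
  g2 <- GenotypeMatrix(calls(g)[perm, ], sampleInfo(g)[perm, ], siteInfo(g))
  pca2 <- genotypePCA(g2, nPC = 3)
  expect_equal(abs(pca2$coords[, 1]), abs(pca$coords[perm, 1]),
               tolerance = 1e-6)
})

test_that("rank tests agree with their closed-form identities", {
  expect_equal(spearmanTest(c(1, 2, 3), c(2, 4, 6))$rho, 1)
  expect_equal(spearmanTest(c(1, 2, 3), c(6, 4, 2))$rho, -1)
  expect_error(spearmanTest(c(1, 1, 1), c(1, 2, 3)), "constant")
  # two-group Kruskal-Wallis chi-square equals the squared standardized
  # Wilcoxon statistic (no ties, no continuity correction)
  set.seed(32)
  a <- sample(1:100, 12); b <- sample(101:200, 15)  # tie-free by construction
  kw <- kruskalTest(c(a, b), rep(c("x", "y"), c(12, 15)))
  W <- wilcoxonRankSum(a, b)$W
  z <- (W - 12 * 15 / 2) / sqrt(12 * 15 * (12 + 15 + 1) / 12)
  expect_equal(kw$chisq, z^2, tolerance = 1e-10)
  expect_equal(kw$df, 1)
  # Bonferroni multiplies and caps at 1
  expect_equal(bonferroni(c(0.01, 0.4, 0.9)), pmin(1, c(0.01, 0.4, 0.9) * 3))
})
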