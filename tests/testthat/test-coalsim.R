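# Structured-coalescent simulator: analytic neutral expectations, event
# handling, mutation dropping and the inbreeding device.

test_that("years convert to generations by the generation time", {
  m <- DemographicModel("p", 1000, generationTime = 2)
  expect_equal(yearsToGenerations(79000, m), 39500)
  expect_equal(yearsToGenerations(0, m), 0)
  expect_equal(yearsToGenerations(100, m), 50)
})

test_that("single-deme coalescence times match analytic expectations", {
  m <- DemographicModel("p", 1000)
  s2 <- simulateGenealogies(m, sampleConfig(c(p = 2)), nReps = 8000,
                            seed = 11)
  # E[T2] = 2N; 3 standard errors of the Monte-Carlo mean
  se <- stats::sd(s2$tmrca) / sqrt(length(s2$tmrca))
  expect_lt(abs(mean(s2$tmrca) - 2000), 3 * se)
  # E[total length] = 4N * sum(1/i), n = 5
  s5 <- simulateGenealogies(m, sampleConfig(c(p = 5)), nReps = 8000,
                            seed = 12)
  se5 <- stats::sd(s5$totalLength) / sqrt(length(s5$totalLength))
  expect_lt(abs(mean(s5$totalLength) - 4000 * sum(1 / (1:4))), 3 * se5)
})

test_that("a split into a huge ancestral deme stops coalescence beyond the split", {
  ev <- data.frame(time_gen = 500, type = "split", pop = "b", dest = "a",
                   Ne = 1e9, stringsAsFactors = FALSE)
  m <- DemographicModel(c("a", "b"), c(1e9, 1e9), ev)
  s <- simulateGenealogies(m, sampleConfig(c(a = 2, b = 2)), nReps = 400,
                           seed = 13)
  # with N ~ 1e9 essentially no coalescence happens within 50,000
  # generations of the split
  expect_gt(mean(s$tmrca > 50000), 0.99)
})

test_that("mutation dropping follows the branch-length Poisson law", {
  m <- DemographicModel("p", 1000, mu = 0)
  g0 <- simulateGenotypes(m, sampleConfig(c(p = 4), L = 1000), nLoci = 5,
                          seed = 21)
  expect_equal(nSites(g0), 0L)  # mu = 0 -> no segregating sites
  # neutral SFS shape: mean per-genealogy xi_i equals theta/i within 3 SE
  # (sites sharing a genealogy are correlated, so the unit of replication is
  # the locus, not the site)
  N <- 2000; muL <- 1e-6 * 5e4; nLoci <- 2000
  m2 <- DemographicModel("p", N, mu = 1e-6)
  g <- simulateGenotypes(m2, sampleConfig(c(p = 4), L = 5e4), nLoci = nLoci,
                         seed = 22)
  cnt <- colSums(calls(g))
  locus <- siteInfo(g)$chrom
  theta <- 4 * N * muL
  for (i in 1:3) {
    perLocus <- tabulate(match(locus[cnt == i], paste0("chr", 1:nLoci)),
                         nLoci)
    se <- stats::sd(perLocus) / sqrt(nLoci)
    expect_lt(abs(mean(perLocus) - theta / i), 3 * se)
  }
  # all site positions valid within locus
  sites <- siteInfo(g)
  expect_true(all(sites$pos >= 1 & sites$pos <= 5e4))
})

test_that("expected joint SFS is normalized, seed-stable and neutral-correct", {
  m <- DemographicModel("p", 5000)
  e1 <- expectedJointSFS(m, sampleConfig(c(p = 4)), nReps = 4000, seed = 31)
  e2 <- expectedJointSFS(m, sampleConfig(c(p = 4)), nReps = 4000, seed = 31)
  expect_identical(e1@counts, e2@counts)
  expect_equal(sum(e1@counts), 1)
  # 1D marginal proportional to [1, 1/2, 1/3]
  marg <- sfsCounts(marginalSFS(e1, "p"))
  expect_equal(marg / marg[1], 1 / (1:3), tolerance = 0.08)
  # two demes split extremely long ago: polymorphism is private
  ev <- data.frame(time_gen = 5e6, type = "split", pop = "b", dest = "a",
                   Ne = NA, stringsAsFactors = FALSE)
  m2 <- DemographicModel(c("a", "b"), c(1000, 1000), ev)
  e3 <- expectedJointSFS(m2, sampleConfig(c(a = 4, b = 4)), nReps = 2000,
                         seed = 32)
  shared <- e3@counts[2:4, 2:4]
  expect_lt(sum(shared), 0.01)
})

test_that("sample-label exchangeability holds within a deme", {
  # permuting individuals within the deme leaves SFS summaries invariant
  m <- DemographicModel("p", 2000, mu = 1e-6)
  g <- simulateGenotypes(m, sampleConfig(c(p = 10), L = 5e4), nLoci = 50,
                         seed = 41)
  perm <- sample(nrow(calls(g)))
  g2 <- GenotypeMatrix(calls(g)[perm, ], sampleInfo(g)[perm, ], siteInfo(g))
  expect_equal(sfsCounts(unfoldedSFS(g)), sfsCounts(unfoldedSFS(g2)))
})

test_that("neutral diversity matches theta = 4 N mu and Tajima's D centers on zero", {
  N <- 2000; mu <- 1e-6; L <- 5e4
  m <- DemographicModel("p", N, mu = mu)
  g <- simulateGenotypes(m, sampleConfig(c(p = 10), L = L), nLoci = 200,
                         seed = 51)
  theta <- 4 * N * mu
  piHat <- sum(.pi_terms_for_test(calls(g))) / (200 * L)
  sfs <- unfoldedSFS(g)
  thetaW <- wattersonTheta(segregatingSites(sfs), 10, 200 * L)
  expect_equal(piHat, theta, tolerance = 0.1)
  expect_equal(thetaW, theta, tolerance = 0.1)
})

test_that("full inbreeding drives observed heterozygosity to zero", {
  m <- DemographicModel("p", 2000, mu = 1e-6)
  g <- simulateGenotypes(m, sampleConfig(c(p = 10), L = 5e4, F = 1),
                         nLoci = 30, seed = 61)
  expect_gt(nSites(g), 0)
  expect_equal(mean(calls(g) == 1L), 0)
})

test_that("simulator agrees with an independent coalescent oracle on a split model", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  ok <- tryCatch({
    system2("python", c("-c", shQuote("import msprime")),
            stdout = NULL, stderr = NULL) == 0
  }, error = function(e) FALSE)
  skip_if(!ok, "msprime not importable")
  script <- tempfile(fileext = ".py")
  out <- tempfile(fileext = ".txt")
  writeLines(c(
    "import msprime, numpy as np",
    "dem = msprime.Demography()",
    "dem.add_population(name='a', initial_size=1000)",
    "dem.add_population(name='b', initial_size=500)",
    "dem.add_population(name='anc', initial_size=2000)",
    "dem.add_population_split(time=800, derived=['a','b'], ancestral='anc')",
    "reps = msprime.sim_ancestry(samples={'a':3,'b':3}, demography=dem,",
    "    ploidy=2, num_replicates=4000, random_seed=7)",
    "acc = np.zeros((7,7))",
    "for ts in reps:",
    "    acc += ts.allele_frequency_spectrum(",
    "        sample_sets=[ts.samples(population=0), ts.samples(population=1)],",
    "        mode='branch', polarised=True, span_normalise=False)",
    "acc /= acc.sum()",
    sprintf("np.savetxt(%s, acc)", deparse(out))), script)
  st <- system2("python", script, stdout = NULL, stderr = NULL)
  skip_if(st != 0, "oracle run failed")
  oracle <- as.matrix(read.table(out))
  ev <- data.frame(time_gen = 800, type = "split", pop = "b", dest = "a",
                   Ne = 2000, stringsAsFactors = FALSE)
  m <- DemographicModel(c("a", "b"), c(1000, 500), ev)
  e <- expectedJointSFS(m, sampleConfig(c(a = 6, b = 6)), nReps = 4000,
                        seed = 71)
  ours <- e@counts / sum(e@counts)
  # compare cell-by-cell on polymorphic cells at Monte-Carlo resolution
  expect_lt(max(abs(ours - oracle)), 0.015)
  expect_lt(sum(abs(ours - oracle)), 0.06)
})
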