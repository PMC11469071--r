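# Composite likelihood, optimizer, model selection, bootstrap machinery and
# the single-population epoch fitter.

test_that("composite log-likelihood matches hand arithmetic and pools small cells", {
  # 2x2 polymorphic toy (dims 2x2: one corner is (1,1), other (2,2))
  obs <- JointSFS(array(c(0, 30, 50, 0), dim = c(2, 2)), c("A", "B"))
  p <- JointSFS(array(c(0, 0.25, 0.75, 0), dim = c(2, 2)), c("A", "B"))
  expect_equal(compositeLogLik(obs, p, minEntry = 0),
               30 * log(0.25) + 50 * log(0.75))
  # saturated value is the maximum
  expect_gte(saturatedLogLik(obs, minEntry = 0),
             compositeLogLik(obs, p, minEntry = 0))
  # pooling: three cells of count 3 lump into one pooled cell of 9
  obs2 <- JointSFS(array(c(0, 3, 3, 3, 40, 0), dim = c(2, 3)), c("A", "B"))
  p2 <- JointSFS(array(c(0, .1, .2, .1, .6, 0), dim = c(2, 3)), c("A", "B"))
  expect_equal(compositeLogLik(obs2, p2, minEntry = 10),
               40 * log(0.6) + 9 * log(0.4))
  # invariance under a consistent permutation of cells
  set.seed(41)
  m <- c(0, 12, 25, 40, 7, 0); q <- c(0, .1, .3, .4, .2, 0)
  perm <- c(1, sample(2:5), 6)
  l1 <- compositeLogLik(JointSFS(array(m, c(2, 3)), c("A", "B")),
                        JointSFS(array(q, c(2, 3)), c("A", "B")), 0)
  l2 <- compositeLogLik(JointSFS(array(m[perm], c(2, 3)), c("A", "B")),
                        JointSFS(array(q[perm], c(2, 3)), c("A", "B")), 0)
  expect_equal(l1, l2)
})

test_that("AIC identity holds and ranking lumps overlapping models", {
  f1 <- new("FitResult", modelId = "m1", par = c(a = 1, b = 2, c = 3, d = 4,
                                                 e = 5),
            logLik = -100, aic = 2 * 5 - 2 * (-100), nRuns = 3L,
            runLogLik = c(-100, -101, -102), ci = NULL, converged = TRUE)
  expect_equal(modelAIC(f1), 210)
  expect_error(new("FitResult", modelId = "bad", par = c(a = 1),
                   logLik = -10, aic = 0, nRuns = 1L, runLogLik = -10,
                   ci = NULL, converged = TRUE), "AIC")
  f2 <- new("FitResult", modelId = "m2", par = c(a = 1), logLik = -101,
            aic = 2 - 2 * (-101), nRuns = 3L,
            runLogLik = c(-101, -101.5, -103), ci = NULL, converged = TRUE)
  f3 <- new("FitResult", modelId = "m3", par = c(a = 1), logLik = -300,
            aic = 2 - 2 * (-300), nRuns = 3L,
            runLogLik = c(-300, -301, -302), ci = NULL, converged = TRUE)
  rank <- modelSelect(list(f1, f2, f3))
  expect_equal(rank$model[1], "m2")
  expect_true(rank$selected[rank$model == "m1"])   # ranges overlap
  expect_false(rank$selected[rank$model == "m3"])
  # identical fits are tied
  rank2 <- modelSelect(list(f2, f2))
  expect_true(all(rank2$selected))
})

test_that("two-epoch truth is recovered within a factor of 1.5 and fits are seed-stable", {
  # truth: N_anc = 10,000 contracted to N_cur = 1,000 at 500 generations.
  # Absolute scale is identified through the Poisson likelihood (the relative
  # SFS is invariant to a joint rescaling of sizes and times). For a recent
  # bottleneck the single-population SFS identifies the ancestral size and
  # the bottleneck intensity T / (2 N_cur), but not T and N_cur separately
  # (the likelihood is flat to < 1 unit along that ridge at 4e5 simulations
  # per evaluation), so the template is parameterized in, and recovery is
  # asserted for, those identifiable coordinates.
  mu <- 1e-6
  truth <- DemographicModel("pop", 1000, data.frame(
    time_gen = 500, type = "size", pop = "pop", dest = NA_character_,
    Ne = 10000, stringsAsFactors = FALSE), mu = mu)
  trueI <- 500 / (2 * 1000)
  cfg <- sampleConfig(c(pop = 10), L = 1e5)
  pnames <- c("Nanc", "intensity", "dT1")
  tpl <- modelTemplate(
    "twoepoch",
    par = setNames(c(5000, 0.1, 1000), pnames),
    lower = setNames(c(50, 0.001, 10), pnames),
    upper = setNames(c(1e6, 10, 1e5), pnames),
    build = function(par) DemographicModel(
      "pop", par[["dT1"]] / (2 * par[["intensity"]]),
      data.frame(time_gen = par[["dT1"]], type = "size", pop = "pop",
                 dest = NA_character_, Ne = par[["Nanc"]],
                 stringsAsFactors = FALSE), mu = mu))
  nrep <- 4; hits <- 0
  for (r in seq_len(nrep)) {
    obs <- simulateJointSFS(truth, cfg, nReps = 20000, seed = 100 + r,
                            mode = "poisson")
    fit <- fitModel(tpl, obs, cfg, nRuns = 4, nCycles = 22,
                    simsPerEval = 8000, seed = 200 + r, minEntry = 5,
                    likelihood = "poisson", startAtDefaults = TRUE,
                    stepShrink = 0.88)
    est <- fittedPar(fit)
    ok <- est[["Nanc"]] / 10000 < 1.5 && est[["Nanc"]] / 10000 > 1 / 1.5 &&
      est[["intensity"]] / trueI < 1.5 && est[["intensity"]] / trueI > 1 / 1.5
    hits <- hits + ok
  }
  expect_gte(hits, ceiling(0.6 * nrep))
  # same seed gives an identical FitResult
  obs <- simulateJointSFS(truth, cfg, nReps = 10000, seed = 7,
                          mode = "poisson")
  fA <- fitModel(tpl, obs, cfg, nRuns = 2, nCycles = 8, simsPerEval = 1000,
                 seed = 99, likelihood = "poisson")
  fB <- fitModel(tpl, obs, cfg, nRuns = 2, nCycles = 8, simsPerEval = 1000,
                 seed = 99, likelihood = "poisson")
  expect_identical(fittedPar(fA), fittedPar(fB))
  expect_identical(fA@logLik, fB@logLik)
})

test_that("likelihood at truth beats perturbed parameter values", {
  truth <- DemographicModel("pop", 2000, data.frame(
    time_gen = 800, type = "size", pop = "pop", dest = NA_character_,
    Ne = 20000, stringsAsFactors = FALSE))
  cfg <- sampleConfig(c(pop = 10))
  wins <- 0
  for (r in 1:5) {
    obs <- simulateJointSFS(truth, cfg, nSnps = 8000, nReps = 20000,
                            seed = 300 + r)
    e_true <- expectedJointSFS(truth, cfg, nReps = 20000, seed = 400 + r)
    llT <- compositeLogLik(obs, e_true, minEntry = 5)
    pert <- DemographicModel("pop", 2000 * 3, data.frame(
      time_gen = 800, type = "size", pop = "pop", dest = NA_character_,
      Ne = 20000 / 3, stringsAsFactors = FALSE))
    e_p <- expectedJointSFS(pert, cfg, nReps = 20000, seed = 400 + r)
    llP <- compositeLogLik(obs, e_p, minEntry = 5)
    wins <- wins + (llT >= llP)
  }
  expect_gte(wins, 4)
})

test_that("epoch-count selection favors the true history", {
  cfg <- sampleConfig(c(pop = 10))
  # constant-size truth: k = 1 wins in the majority of replicates
  const <- DemographicModel("pop", 5000)
  k1wins <- 0
  for (r in 1:3) {
    sfs <- marginalSFS(simulateJointSFS(const, cfg, nSnps = 4000,
                                        nReps = 20000, seed = 500 + r),
                       "pop")
    fit <- fitSinglePopEpochs(sfs, kEpochs = 1:2, nRuns = 4, nCycles = 12,
                              simsPerEval = 2000, seed = 600 + r,
                              likelihood = "multinomial")
    k1wins <- k1wins + (fit$k == 1)
  }
  expect_gte(k1wins, 2)
  # strong recent 10x bottleneck: fitted recent size below ancestral size
  bott <- DemographicModel("pop", 500, data.frame(
    time_gen = 300, type = "size", pop = "pop", dest = NA_character_,
    Ne = 5000, stringsAsFactors = FALSE))
  ok <- 0
  for (r in 1:3) {
    sfs <- marginalSFS(simulateJointSFS(bott, cfg, nSnps = 4000,
                                        nReps = 20000, seed = 700 + r),
                       "pop")
    fit <- fitSinglePopEpochs(sfs, kEpochs = 2, nRuns = 4, nCycles = 15,
                              simsPerEval = 2000, seed = 800 + r,
                              likelihood = "multinomial")
    est <- fittedPar(fit$best)
    ok <- ok + (est[["N1"]] < est[["N2"]])
  }
  expect_gte(ok, 3)
})

test_that("bootstrap CIs are ordered and respond to the degenerate zero-noise limit", {
  mu <- 1e-6
  truth <- DemographicModel("pop", 1000, data.frame(
    time_gen = 500, type = "size", pop = "pop", dest = NA_character_,
    Ne = 10000, stringsAsFactors = FALSE), mu = mu)
  cfg <- sampleConfig(c(pop = 8), L = 1e5)
  pnames <- c("N1", "N2", "dT1")
  tpl <- modelTemplate(
    "twoepoch",
    par = setNames(c(1000, 10000, 500), pnames),
    lower = setNames(c(50, 50, 10), pnames),
    upper = setNames(c(1e6, 1e6, 1e5), pnames),
    build = function(par) DemographicModel("pop", par[["N1"]], data.frame(
      time_gen = par[["dT1"]], type = "size", pop = "pop",
      dest = NA_character_, Ne = par[["N2"]], stringsAsFactors = FALSE),
      mu = mu))
  obs <- simulateJointSFS(truth, cfg, nReps = 20000, seed = 17,
                          mode = "poisson")
  fit <- fitModel(tpl, obs, cfg, nRuns = 3, nCycles = 12, simsPerEval = 1500,
                  seed = 18, startAtDefaults = TRUE, likelihood = "poisson")
  fitCI <- parametricBootstrapCI(fit, tpl, cfg, nBoot = 10,
                                 runsPerBoot = 1, nCycles = 6,
                                 simsPerEval = 800, seed = 19,
                                 likelihood = "poisson")
  ci <- fitCI@ci
  expect_true(all(ci[, "lo"] <= ci[, "hi"]))
  draws <- attr(ci, "draws")
  expect_true(all(apply(draws, 2, min) <= ci[, "lo"] + 1e-9))
})
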