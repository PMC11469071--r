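# Composite-likelihood demographic inference on the joint SFS: model
# templates, ECM-style multi-run optimization, AIC selection, parametric
# bootstrap.

#' Multinomial composite log-likelihood of an observed joint SFS
#'
#' Treats polymorphic SFS cells as independent multinomial categories
#' (monomorphic corner cells are excluded: the observed SNP total is fixed).
#' Before evaluation, every cell whose observed count is below
#' \code{minEntry} is pooled into a single lumped cell (observed and expected
#' mass summed), which stabilizes the likelihood for sparse spectra. Expected
#' proportions are floored at \code{eps} to avoid -Inf.
#'
#' @param obs observed \linkS4class{JointSFS} of counts
#' @param expected expected \linkS4class{JointSFS}: proportions (multinomial
#'   mode) or absolute expected counts (Poisson mode, see
#'   \code{\link{expectedJointSFS}} with \code{counts = TRUE})
#' @param minEntry pooling threshold on observed counts
#' @param eps probability floor
#' @param likelihood \code{"multinomial"} conditions on the observed SNP
#'   total (scale-free: only relative sizes and times are identified unless
#'   the model is anchored); \code{"poisson"} treats cells as independent
#'   Poisson counts with the absolute expectation, identifying the overall
#'   scale through mu and the sequence length
#' @return composite log-likelihood
#' @export
compositeLogLik <- function(obs, expected, minEntry = 10, eps = 1e-12,
                            likelihood = c("multinomial", "poisson")) {
  likelihood <- match.arg(likelihood)
  m <- as.vector(obs@counts)
  p <- as.vector(expected@counts)
  if (length(m) != length(p)) stop("observed/expected dimensions differ")
  dims <- dim(obs@counts)
  corner <- c(1L, prod(dims))
  poly <- setdiff(seq_along(m), corner)
  m <- m[poly]; p <- p[poly]
  if (likelihood == "multinomial") p <- p / sum(p)
  small <- m < minEntry
  if (any(small)) {
    m <- c(m[!small], sum(m[small]))
    p <- c(p[!small], sum(p[small]))
  }
  if (likelihood == "poisson")
    return(sum(m * log(pmax(p, eps)) - p))
  use <- m > 0
  if (eps == 0 && any(use & p <= 0))
    warning("observed mass where expected mass is zero")
  sum(m[use] * log(pmax(p[use], eps)))
}

#' Saturated multinomial log-likelihood (upper bound) of an observed SFS
#' @param obs observed \linkS4class{JointSFS}
#' @param minEntry pooling threshold, as in \code{\link{compositeLogLik}}
#' @export
saturatedLogLik <- function(obs, minEntry = 10) {
  compositeLogLik(obs, JointSFS(obs@counts / sum(obs@counts),
                                obs@populations), minEntry = minEntry)
}

#' Define a demographic model template with free parameters
#'
#' A template couples named free parameters (with box bounds; optimization is
#' on the log scale) to a builder that turns a parameter vector into a
#' \linkS4class{DemographicModel}. Event-time ordering is respected by
#' expressing later times as positive increments where needed. The optional
#' \code{report} function maps fitted parameters to derived quantities (e.g.
#' split times in years).
#'
#' @param id model label
#' @param par named numeric defaults for the free parameters
#' @param lower,upper named bounds (same names as \code{par})
#' @param build function(par) returning a \linkS4class{DemographicModel}
#' @param report optional function(par) returning a named numeric of derived
#'   quantities
#' @return an object of class \code{"modelTemplate"}
#' @export
modelTemplate <- function(id, par, lower, upper, build, report = NULL) {
  stopifnot(all(names(lower) == names(par)), all(names(upper) == names(par)),
            all(lower > 0), all(lower <= par), all(par <= upper))
  structure(list(id = id, par = par, lower = lower, upper = upper,
                 build = build, report = report), class = "modelTemplate")
}

.template_loglik <- function(template, par, obs, config, simsPerEval,
                             simSeed, minEntry, likelihood = "multinomial") {
  model <- template$build(par)
  exp_sfs <- expectedJointSFS(model, config, nReps = simsPerEval,
                              seed = simSeed,
                              counts = likelihood == "poisson")
  compositeLogLik(obs, exp_sfs, minEntry = minEntry, likelihood = likelihood)
}

#' Fit a demographic model template to an observed joint SFS
#'
#' Multi-run ECM-style optimization: each run draws a random start uniform in
#' log-parameter space within the bounds, then performs \code{nCycles} of
#' cyclic coordinate-wise improvement with geometrically shrinking
#' multiplicative steps. The expected SFS for each evaluation is the
#' Monte-Carlo branch-length expectation over \code{simsPerEval} genealogies;
#' within a run the same simulation seed is reused for every evaluation
#' (common random numbers), making the objective deterministic in the
#' parameters and the search well-behaved despite Monte-Carlo noise. The best
#' run is returned; the fit is flagged non-converged if no run improved on
#' its starting value.
#'
#' @param template a \code{\link{modelTemplate}}
#' @param obs observed \linkS4class{JointSFS} of counts
#' @param config \code{\link{sampleConfig}} matching \code{obs} dimensions
#' @param nRuns independent optimizer runs
#' @param nCycles coordinate cycles per run
#' @param simsPerEval coalescent simulations per likelihood evaluation
#' @param seed integer seed governing starts and simulation seeds
#' @param minEntry pooling threshold for the composite likelihood
#' @param stepInit initial multiplicative step; shrinks by \code{stepShrink}
#'   per cycle
#' @param stepShrink geometric shrink factor per cycle
#' @param startAtDefaults start run 1 at the template defaults
#' @param likelihood \code{"multinomial"} (relative SFS, the default) or
#'   \code{"poisson"} (absolute scale through mu and sequence length); see
#'   \code{\link{compositeLogLik}}
#' @return a \linkS4class{FitResult}
#' @export
fitModel <- function(template, obs, config, nRuns = 50, nCycles = 40,
                     simsPerEval = 2000, seed = NULL, minEntry = 10,
                     stepInit = 1.6, stepShrink = 0.93,
                     startAtDefaults = FALSE,
                     likelihood = c("multinomial", "poisson")) {
  likelihood <- match.arg(likelihood)
  stopifnot(inherits(template, "modelTemplate"))
  .with_seed(seed, {
    k <- length(template$par)
    llo <- log(template$lower); lup <- log(template$upper)
    runSeeds <- sample.int(2^31 - 2, nRuns)
    best <- NULL; runLL <- numeric(nRuns); improved <- logical(nRuns)
    for (r in seq_len(nRuns)) {
      lpar <- if (r == 1 && startAtDefaults) log(template$par)
              else llo + stats::runif(k) * (lup - llo)
      names(lpar) <- names(template$par)
      objective <- function(lp)
        .template_loglik(template, exp(lp), obs, config, simsPerEval,
                         runSeeds[r], minEntry, likelihood)
      ll <- objective(lpar)
      ll0 <- ll
      step <- stepInit
      for (cyc in seq_len(nCycles)) {
        for (j in seq_len(k)) {
          for (dir in c(1, -1)) {
            cand <- lpar
            cand[j] <- min(lup[j], max(llo[j], lpar[j] + dir * log(step)))
            if (cand[j] == lpar[j]) next
            llc <- objective(cand)
            if (llc > ll) { lpar <- cand; ll <- llc; break }
          }
        }
        step <- max(1.01, 1 + (step - 1) * stepShrink)
      }
      runLL[r] <- ll
      improved[r] <- ll > ll0
      if (is.null(best) || ll > best$ll)
        best <- list(par = exp(lpar), ll = ll)
    }
    new("FitResult", modelId = template$id, par = best$par,
        logLik = best$ll, aic = 2 * k - 2 * best$ll,
        nRuns = as.integer(nRuns), runLogLik = runLL, ci = NULL,
        converged = any(improved))
  })
}

#' Rank fitted models by AIC with overlap-based tie lumping
#'
#' Models are ranked by AIC; models whose per-run log-likelihood ranges
#' overlap the best model's range are lumped into the selected tie group.
#'
#' @param results list of \linkS4class{FitResult}s fitted to the same data
#' @return data.frame ranked by AIC with a \code{selected} flag for the
#'   lowest-AIC tie group
#' @export
modelSelect <- function(results) {
  stopifnot(length(results) >= 2)
  df <- data.frame(
    model = vapply(results, function(x) x@modelId, character(1)),
    k = vapply(results, function(x) length(x@par), numeric(1)),
    logLik = vapply(results, function(x) x@logLik, numeric(1)),
    AIC = vapply(results, function(x) x@aic, numeric(1)),
    llMin = vapply(results, function(x) min(x@runLogLik), numeric(1)),
    llMax = vapply(results, function(x) max(x@runLogLik), numeric(1)),
    stringsAsFactors = FALSE)
  df <- df[order(df$AIC), , drop = FALSE]
  df$selected <- df$llMax >= df$llMin[1] & df$llMin <= df$llMax[1]
  df$selected[1] <- TRUE
  rownames(df) <- NULL
  df
}

#' Parametric-bootstrap percentile confidence intervals
#'
#' Simulates \code{nBoot} SFSs from the fitted model (each with the observed
#' number of polymorphic sites), re-fits each starting from the point
#' estimate (plus \code{runsPerBoot - 1} random-start runs), and reports the
#' empirical 2.5 and 97.5 percentiles per parameter. Non-converged bootstrap
#' replicates are excluded and counted in the \code{"nonConverged"}
#' attribute.
#'
#' @param fit a \linkS4class{FitResult}
#' @param template the \code{\link{modelTemplate}} that produced it
#' @param config the \code{\link{sampleConfig}} used
#' @param nSnps polymorphic sites per simulated SFS (use the observed S)
#' @param nBoot bootstrap replicates
#' @param runsPerBoot optimizer runs per replicate
#' @param nCycles,simsPerEval optimizer settings per replicate
#' @param seed integer seed
#' @param minEntry pooling threshold
#' @param likelihood passed to \code{\link{fitModel}}
#' @param stepInit,stepShrink refit step schedule; the default is much finer
#'   than \code{\link{fitModel}}'s because each refit starts at the point
#'   estimate and only needs to track the bootstrap perturbation
#' @return the \linkS4class{FitResult} with its \code{ci} slot filled
#'   (rows = parameters, columns \code{lo}, \code{hi})
#' @export
parametricBootstrapCI <- function(fit, template, config, nSnps = NULL,
                                  nBoot = 100, runsPerBoot = 20,
                                  nCycles = 15, simsPerEval = 1000,
                                  seed = NULL, minEntry = 10,
                                  likelihood = c("multinomial", "poisson"),
                                  stepInit = 1.15, stepShrink = 0.85) {
  likelihood <- match.arg(likelihood)
  .with_seed(seed, {
    model <- template$build(fit@par)
    bootSeeds <- sample.int(2^31 - 2, nBoot)
    tplBoot <- template
    tplBoot$par <- pmin(template$upper, pmax(template$lower, fit@par))
    draws <- matrix(NA_real_, nBoot, length(fit@par),
                    dimnames = list(NULL, names(fit@par)))
    nonconv <- 0L
    for (b in seq_len(nBoot)) {
      sfs_b <- simulateJointSFS(model, config, nSnps, nReps = 4000,
                                seed = bootSeeds[b],
                                mode = if (likelihood == "poisson")
                                  "poisson" else "conditional")
      fb <- fitModel(tplBoot, sfs_b, config, nRuns = runsPerBoot,
                     nCycles = nCycles, simsPerEval = simsPerEval,
                     seed = bootSeeds[b] %% 1000003L + b,
                     minEntry = minEntry, startAtDefaults = TRUE,
                     likelihood = likelihood,
                     stepInit = stepInit, stepShrink = stepShrink)
      if (fb@converged || runsPerBoot == 1) draws[b, ] <- fb@par
      else nonconv <- nonconv + 1L
    }
    ok <- stats::complete.cases(draws)
    ci <- t(apply(draws[ok, , drop = FALSE], 2, stats::quantile,
                  probs = c(0.025, 0.975), names = FALSE))
    colnames(ci) <- c("lo", "hi")
    out <- fit
    out@ci <- ci
    attr(out@ci, "nonConverged") <- nonconv
    attr(out@ci, "draws") <- draws[ok, , drop = FALSE]
    out
  })
}

#' Piecewise-constant single-population history by composite likelihood
#'
#' Fits a k-epoch constant-size history to a 1D unfolded SFS for each k in
#' \code{kEpochs}, selecting k by AIC. Parameters are epoch sizes N_1..N_k
#' (present to past) and boundary times as positive increments. A model-based
#' summary of the same information a stairway-type analysis extracts.
#'
#' @param sfs an unfolded \linkS4class{SFS1D}
#' @param kEpochs epoch counts to try
#' @param config optional \code{\link{sampleConfig}}; defaults to the SFS
#'   sample size. In Poisson mode \code{config$L} must be the accessible
#'   length the SFS was ascertained over.
#' @param nRuns,nCycles,simsPerEval optimizer settings
#' @param seed integer seed
#' @param mu mutation rate per site per generation used by the epoch models
#' @param likelihood \code{"poisson"} (default) identifies absolute sizes and
#'   times through mu and L; \code{"multinomial"} fits the SFS shape only
#'   (sizes and times then identified up to a common scale)
#' @return list: \code{best} (\linkS4class{FitResult}), \code{byK} (list of
#'   fits), \code{k} (selected epoch count)
#' @export
fitSinglePopEpochs <- function(sfs, kEpochs = 1:4, config = NULL,
                               nRuns = 8, nCycles = 20, simsPerEval = 2000,
                               seed = NULL, mu = 1.23e-8,
                               likelihood = c("poisson", "multinomial")) {
  likelihood <- match.arg(likelihood)
  stopifnot(is(sfs, "SFS1D"), !sfs@folded)
  n <- sfs@n
  if (n - 1 < 2 * max(kEpochs) - 1)
    stop("SFS too small for the requested number of epochs")
  if (is.null(config)) config <- sampleConfig(n, L = 1e5)
  obs <- JointSFS(array(c(0, sfs@counts, 0), dim = n + 1L), "pop")
  .with_seed(seed, {
    seeds <- sample.int(2^31 - 2, length(kEpochs))
    fits <- list()
    for (i in seq_along(kEpochs)) {
      k <- kEpochs[i]
      pnames <- c(paste0("N", seq_len(k)),
                  if (k > 1) paste0("dT", seq_len(k - 1)))
      par <- c(rep(10000, k), rep(1000, max(0, k - 1)))
      lower <- c(rep(50, k), rep(10, max(0, k - 1)))
      upper <- c(rep(1e6, k), rep(1e5, max(0, k - 1)))
      names(par) <- names(lower) <- names(upper) <- pnames
      build <- local({
        k <- k; mu <- mu
        function(par) {
          if (k == 1) return(DemographicModel("pop", par[["N1"]], mu = mu))
          times <- cumsum(par[paste0("dT", seq_len(k - 1))])
          ev <- data.frame(time_gen = times, type = "size", pop = "pop",
                           dest = NA_character_,
                           Ne = par[paste0("N", 2:k)],
                           stringsAsFactors = FALSE)
          DemographicModel("pop", par[["N1"]], ev, mu = mu)
        }
      })
      tpl <- modelTemplate(paste0("epochs", k), par, lower, upper, build)
      fits[[i]] <- fitModel(tpl, obs, config, nRuns = nRuns,
                            nCycles = nCycles, simsPerEval = simsPerEval,
                            seed = seeds[i], minEntry = 1,
                            likelihood = likelihood)
    }
    aics <- vapply(fits, modelAIC, numeric(1))
    best <- which.min(aics)
    list(best = fits[[best]], byK = fits, k = kEpochs[best])
  })
}
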