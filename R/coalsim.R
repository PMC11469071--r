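# Structured-coalescent simulation: R interface over the C++ core.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(seed)
    return(expr)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Per-population sampling configuration for coalescent simulation
#'
#' @param nHap named integer vector of haploid sample sizes, names matching the
#'   model's populations (diploid individuals contribute 2 haplotypes each)
#' @param L sequence length in sites (used when mutations are dropped)
#' @param F per-population inbreeding coefficient in [0,1]; with probability F
#'   an individual's two haplotypes are copies (a pragmatic stand-in for
#'   partial selfing). Scalar recycled across populations.
#' @return a list of class \code{"sampleConfig"}
#' @export
sampleConfig <- function(nHap, L = 1e5, F = 0) {
  nHap <- as.integer(nHap)
  stopifnot(all(nHap >= 0), sum(nHap) >= 2, L >= 1)
  Fv <- rep_len(F, length(nHap))
  stopifnot(all(Fv >= 0), all(Fv <= 1))
  structure(list(nHap = nHap, L = L, F = Fv), class = "sampleConfig")
}

#' Convert years to generations under a model's generation time
#'
#' @param years time in years
#' @param model a \linkS4class{DemographicModel} (or a numeric generation time)
#' @return time in generations
#' @export
yearsToGenerations <- function(years, model) {
  stopifnot(all(years >= 0))
  g <- if (is(model, "DemographicModel")) model@generationTime else model
  years / g
}

# encode a DemographicModel for the C++ simulator
.encode_model <- function(model, config) {
  pops <- model@populations
  nh <- config$nHap
  if (!is.null(names(nh))) {
    stopifnot(all(names(nh) %in% pops))
    full <- setNames(integer(length(pops)), pops)
    full[names(nh)] <- nh
    nh <- full
  } else stopifnot(length(nh) == length(pops))
  ev <- model@events
  list(sizes = model@Ne,
       ev_time = as.numeric(ev$time_gen),
       ev_type = as.integer(ifelse(ev$type == "split", 0L, 1L)),
       ev_a = as.integer(match(ev$pop, pops) - 1L),
       ev_b = as.integer(ifelse(is.na(ev$dest), -1L,
                                match(ev$dest, pops) - 1L)),
       ev_n = as.numeric(ifelse(is.na(ev$Ne), -1, ev$Ne)),
       nsam = as.integer(unname(nh)))
}

#' Simulate coalescent genealogies and summarize them
#'
#' Runs the structured coalescent under \code{model} with the samples in
#' \code{config} and returns per-replicate TMRCA and total branch length plus
#' the accumulated branch-length joint frequency spectrum (branch length
#' subtending each joint derived-count cell, summed over replicates).
#'
#' @param model a \linkS4class{DemographicModel}
#' @param config a \code{\link{sampleConfig}}
#' @param nReps number of independent genealogies
#' @param seed optional integer seed
#' @return list with \code{tmrca}, \code{totalLength} (numeric vectors) and
#'   \code{branchSFS} (array, dims nHap+1 per population)
#' @export
simulateGenealogies <- function(model, config, nReps = 1000, seed = NULL) {
  stopifnot(is(model, "DemographicModel"), nReps >= 1)
  validObject(model)
  enc <- .encode_model(model, config)
  if (sum(enc$nsam) < 2) stop("need at least 2 sampled lineages")
  res <- .with_seed(seed,
    .coal_simulate(enc$sizes, enc$ev_time, enc$ev_type, enc$ev_a, enc$ev_b,
                   enc$ev_n, enc$nsam, as.integer(nReps), 0, FALSE))
  dims <- enc$nsam + 1L
  list(tmrca = res$tmrca, totalLength = res$total_length,
       branchSFS = array(res$branch_sfs, dim = dims))
}

#' Monte-Carlo expected joint site frequency spectrum
#'
#' Averages branch-length-weighted entry probabilities over \code{nReps}
#' genealogies; under the infinite-sites model the expected share of SNPs in a
#' joint-frequency cell is proportional to the expected branch length
#' subtending it. Entries are normalized to sum to 1 over polymorphic cells;
#' the monomorphic corner cells are 0.
#'
#' @inheritParams simulateGenealogies
#' @param counts if TRUE, return expected SNP counts per cell (mean branch
#'   length times mu times L) instead of proportions; this absolute scale is
#'   what the Poisson likelihood mode consumes
#' @return a \linkS4class{JointSFS} of expected proportions (or counts)
#' @export
expectedJointSFS <- function(model, config, nReps = 2000, seed = NULL,
                             counts = FALSE) {
  sim <- simulateGenealogies(model, config, nReps, seed)
  a <- if (counts) sim$branchSFS / nReps * model@mu * config$L
       else sim$branchSFS / sum(sim$branchSFS)
  JointSFS(a, model@populations)
}

#' Simulate an observed joint SFS of a fixed number of SNPs
#'
#' Draws a multinomial sample of \code{nSnps} sites from the Monte-Carlo
#' expected joint SFS (conditioning on the observed number of polymorphic
#' sites, as composite-likelihood SFS methods do).
#'
#' @inheritParams simulateGenealogies
#' @param nSnps number of polymorphic sites to draw (conditional mode)
#' @param nReps genealogies used for the underlying expectation
#' @param mode \code{"conditional"} draws a multinomial sample of
#'   \code{nSnps} sites from the expected proportions;  \code{"poisson"}
#'   draws independent Poisson counts around the absolute expectation
#'   mu * L * E[branch length] per cell (the infinite-sites law for a
#'   sequence of length \code{config$L})
#' @return a \linkS4class{JointSFS} of counts
#' @export
simulateJointSFS <- function(model, config, nSnps = NULL, nReps = 20000,
                             seed = NULL,
                             mode = c("conditional", "poisson")) {
  mode <- match.arg(mode)
  .with_seed(seed, {
    if (mode == "conditional") {
      stopifnot(!is.null(nSnps))
      p <- expectedJointSFS(model, config, nReps)
      counts <- as.vector(stats::rmultinom(1, nSnps, as.vector(p@counts)))
    } else {
      lam <- expectedJointSFS(model, config, nReps, counts = TRUE)
      counts <- stats::rpois(length(lam@counts), as.vector(lam@counts))
      p <- lam
    }
    JointSFS(array(counts, dim = dim(p@counts)), p@populations)
  })
}

#' Simulate diploid genotypes under the infinite-sites model
#'
#' Simulates \code{nLoci} independent genealogies (standing in for unlinked
#' windows; recombination is not modeled), drops Poisson(mu * L * branch
#' length) mutations on each, and pairs consecutive haplotypes within each
#' population into diploid individuals. With inbreeding coefficient F > 0 an
#' individual's second haplotype is replaced by a copy of its first with
#' probability F before pairing.
#'
#' @inheritParams simulateGenealogies
#' @param nLoci number of independent loci, each of length \code{config$L}
#' @param chromPrefix chromosome label prefix (one chromosome per locus)
#' @return a \linkS4class{GenotypeMatrix}; the derived allele is the alternate
#'   allele (ref = ancestral "A", alt = derived "T")
#' @export
simulateGenotypes <- function(model, config, nLoci = 1, seed = NULL,
                              chromPrefix = "chr") {
  stopifnot(is(model, "DemographicModel"))
  validObject(model)
  enc <- .encode_model(model, config)
  nhap <- sum(enc$nsam)
  if (any(enc$nsam %% 2 != 0))
    stop("haploid sample sizes must be even to form diploids")
  .with_seed(seed, {
    res <- .coal_simulate(enc$sizes, enc$ev_time, enc$ev_type, enc$ev_a,
                          enc$ev_b, enc$ev_n, enc$nsam, as.integer(nLoci),
                          model@mu * config$L, TRUE)
    nmut <- length(res$carriers)
    hap <- matrix(0L, nrow = nhap, ncol = nmut)
    for (k in seq_len(nmut)) hap[res$carriers[[k]], k] <- 1L
    # selfing stand-in: copy haplotype 1 over haplotype 2 within an individual
    pops <- rep(model@populations, times = enc$nsam)
    ind_pop <- pops[seq(1, nhap, by = 2)]
    Fv <- setNames(rep_len(config$F, length(model@populations)),
                   model@populations)
    selfed <- stats::runif(nhap / 2) < Fv[ind_pop]
    for (i in which(selfed)) hap[2 * i, ] <- hap[2 * i - 1, ]
    dos <- hap[seq(1, nhap, 2), , drop = FALSE] +
           hap[seq(2, nhap, 2), , drop = FALSE]
    # positions: uniform within each locus, unique, sorted
    keep <- order(res$mut_rep)
    dos <- dos[, keep, drop = FALSE]
    repid <- res$mut_rep[keep]
    pos <- integer(length(repid)); chrom <- character(length(repid))
    for (r in unique(repid)) {
      idx <- which(repid == r)
      pos[idx] <- sort(sample.int(config$L, length(idx)))
      chrom[idx] <- paste0(chromPrefix, r)
    }
    samples <- data.frame(
      id = paste0(ind_pop, "_", stats::ave(seq_along(ind_pop), ind_pop,
                                           FUN = seq_along)),
      population = ind_pop, morph = NA_character_,
      stringsAsFactors = FALSE)
    sites <- data.frame(chrom = chrom, pos = pos,
                        ref = rep("A", length(pos)),
                        alt = rep("T", length(pos)),
                        stringsAsFactors = FALSE)
    GenotypeMatrix(dos, samples, sites)
  })
}
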