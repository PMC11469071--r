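#' @useDynLib primrose, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' GenotypeMatrix: diploid dosage calls for individuals at biallelic sites
#'
#' The substrate of all downstream statistics. Rows are individuals (with
#' population and floral-morph labels), columns are biallelic SNP sites.
#' Dosages count copies of the alternate allele: 0 (hom-ref), 1 (het),
#' 2 (hom-alt) or \code{NA} (missing).
#'
#' @slot calls integer matrix, individuals x sites, values in \{0,1,2,NA\}
#' @slot samples data.frame with columns \code{id}, \code{population},
#'   \code{morph} (one of \code{"S"}, \code{"L"}, \code{"H"} or \code{NA})
#' @slot sites data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt}
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(calls = "matrix", samples = "data.frame", sites = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (nrow(object@calls) != nrow(object@samples))
    msg <- c(msg, "nrow(calls) must equal nrow(samples)")
  if (ncol(object@calls) != nrow(object@sites))
    msg <- c(msg, "ncol(calls) must equal nrow(sites)")
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(object@sites)))
    msg <- c(msg, "sites needs columns chrom, pos, ref, alt")
  if (!all(c("id", "population") %in% names(object@samples)))
    msg <- c(msg, "samples needs columns id, population")
  v <- object@calls[!is.na(object@calls)]
  if (length(v) && (any(v < 0) || any(v > 2)))
    msg <- c(msg, "calls must lie in {0,1,2,NA}")
  if (nrow(object@sites) > 1) {
    bad <- unlist(lapply(split(object@sites$pos, object@sites$chrom),
                         function(p) any(diff(p) <= 0)))
    if (any(bad))
      msg <- c(msg, "positions must be strictly increasing within chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param calls individuals x sites matrix of dosages in \{0,1,2,NA\}
#' @param samples data.frame with \code{id}, \code{population} and optionally
#'   \code{morph}
#' @param sites data.frame with \code{chrom}, \code{pos}, \code{ref}, \code{alt}
#' @return a \linkS4class{GenotypeMatrix}
#' @export
GenotypeMatrix <- function(calls, samples, sites) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(samples$morph)) samples$morph <- NA_character_
  new("GenotypeMatrix", calls = calls,
      samples = as.data.frame(samples, stringsAsFactors = FALSE),
      sites = as.data.frame(sites, stringsAsFactors = FALSE))
}

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@calls), "individuals x",
      ncol(object@calls), "sites\n")
  cat("  populations:",
      paste(names(table(object@samples$population)), collapse = ", "), "\n")
  cat("  missingness:",
      sprintf("%.2f%%", 100 * mean(is.na(object@calls))), "\n")
})

#' @describeIn GenotypeMatrix dosage matrix accessor
#' @param x a GenotypeMatrix
#' @export
calls <- function(x) x@calls

#' @describeIn GenotypeMatrix sample table accessor
#' @export
sampleInfo <- function(x) x@samples

#' @describeIn GenotypeMatrix site table accessor
#' @export
siteInfo <- function(x) x@sites

#' @describeIn GenotypeMatrix number of sites
#' @export
nSites <- function(x) ncol(x@calls)

#' Subset a GenotypeMatrix by individuals and/or sites
#'
#' @param x a GenotypeMatrix
#' @param i individual index (logical/integer)
#' @param j site index (logical/integer)
#' @export
subsetGenotypes <- function(x, i = NULL, j = NULL) {
  if (is.null(i)) i <- seq_len(nrow(x@calls))
  if (is.null(j)) j <- seq_len(ncol(x@calls))
  GenotypeMatrix(x@calls[i, j, drop = FALSE],
                 x@samples[i, , drop = FALSE],
                 x@sites[j, , drop = FALSE])
}

#' SFS1D: one-dimensional site frequency spectrum
#'
#' Counts of polymorphic sites by derived-allele (unfolded) or minor-allele
#' (folded) count in a sample of \code{n} haploid genomes. Unfolded spectra
#' hold entries xi_1..xi_(n-1); folded spectra eta_1..eta_floor(n/2).
#'
#' @slot n haploid sample size
#' @slot counts spectrum entries (may be non-integer after projection)
#' @slot folded logical flag
#' @slot monomorphic counts of invariant ancestral/derived sites (NA if unknown)
#' @exportClass SFS1D
setClass("SFS1D", representation(n = "integer", counts = "numeric",
                                 folded = "logical", monomorphic = "numeric"))

setValidity("SFS1D", function(object) {
  msg <- character()
  want <- if (object@folded) floor(object@n / 2) else object@n - 1L
  if (length(object@counts) != want)
    msg <- c(msg, sprintf("counts must have length %d", want))
  if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
  if (object@n < 2) msg <- c(msg, "n must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Construct an SFS1D
#' @param counts spectrum entries
#' @param n haploid sample size
#' @param folded logical
#' @param monomorphic length-2 numeric (ancestral, derived invariant counts)
#' @return an \linkS4class{SFS1D}
#' @export
SFS1D <- function(counts, n, folded = FALSE,
                  monomorphic = c(NA_real_, NA_real_)) {
  new("SFS1D", n = as.integer(n), counts = as.numeric(counts),
      folded = folded, monomorphic = as.numeric(monomorphic))
}

setMethod("show", "SFS1D", function(object) {
  cat(if (object@folded) "Folded" else "Unfolded",
      "SFS, n =", object@n, "haplotypes, S =",
      format(sum(object@counts)), "\n")
})

#' @describeIn SFS1D spectrum entries
#' @param x an SFS1D or JointSFS
#' @export
sfsCounts <- function(x) x@counts

#' @describeIn SFS1D total polymorphic sites
#' @export
segregatingSites <- function(x) sum(x@counts)

#' @describeIn SFS1D haploid sample size
#' @export
sampleSizeHap <- function(x) x@n

#' JointSFS: multidimensional site frequency spectrum
#'
#' Array of site counts over joint derived-allele counts across populations;
#' cell (c_1, ..., c_k) counts sites with derived count c_p in population p.
#' The two corner cells (all-ancestral, all-derived) are monomorphic.
#'
#' @slot counts numeric array with dim n_p + 1 per population
#' @slot populations population labels
#' @exportClass JointSFS
setClass("JointSFS", representation(counts = "array", populations = "character"))

setValidity("JointSFS", function(object) {
  msg <- character()
  if (length(dim(object@counts)) != length(object@populations))
    msg <- c(msg, "one dimension per population required")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a JointSFS
#' @param counts array (dim n_p + 1 per population)
#' @param populations labels, one per dimension
#' @return a \linkS4class{JointSFS}
#' @export
JointSFS <- function(counts, populations) {
  if (is.null(dim(counts))) dim(counts) <- length(counts)
  new("JointSFS", counts = counts, populations = as.character(populations))
}

setMethod("show", "JointSFS", function(object) {
  cat("JointSFS over", paste(object@populations, collapse = ", "),
      "| dims:", paste(dim(object@counts), collapse = " x "),
      "| S =", format(polymorphicMass(object)), "\n")
})

#' Polymorphic mass of a JointSFS (total minus the two monomorphic corners)
#' @param x a JointSFS
#' @export
polymorphicMass <- function(x) {
  a <- x@counts
  idx0 <- matrix(1L, 1, length(dim(a)))
  idxN <- matrix(dim(a), 1, length(dim(a)))
  sum(a) - a[idx0] - a[idxN]
}

#' DemographicModel: populations, sizes and dated demographic events
#'
#' Encodes a rooted multi-population history: present-day diploid effective
#' sizes plus a time-ordered backward-in-time event list. A \code{"split"}
#' event merges the lineages of \code{pop} into \code{dest} (forward in time,
#' \code{pop} descends from \code{dest}) and may reset \code{dest}'s size; a
#' \code{"size"} event sets a new size for \code{pop} from that time onward
#' (into the past).
#'
#' @slot populations labels
#' @slot Ne present-day diploid effective sizes, one per population
#' @slot events data.frame: \code{time_gen}, \code{type} ("split"/"size"),
#'   \code{pop}, \code{dest} (NA for size changes), \code{Ne}
#' @slot mu mutation rate per site per generation
#' @slot generationTime years per generation
#' @slot neUnits "diploid" (coalescence rate k(k-1)/(4Ne)) -- made explicit
#'   because SFS tools differ in whether printed sizes are gene copies
#' @exportClass DemographicModel
setClass("DemographicModel",
  representation(populations = "character", Ne = "numeric",
                 events = "data.frame", mu = "numeric",
                 generationTime = "numeric", neUnits = "character"))

setValidity("DemographicModel", function(object) {
  msg <- character()
  if (length(object@Ne) != length(object@populations))
    msg <- c(msg, "one Ne per population required")
  if (any(object@Ne <= 0)) msg <- c(msg, "all Ne must be > 0")
  ev <- object@events
  if (nrow(ev)) {
    if (is.unsorted(ev$time_gen)) msg <- c(msg, "events must be time-ordered")
    if (any(ev$time_gen < 0)) msg <- c(msg, "event times must be >= 0")
    if (!all(ev$type %in% c("split", "size")))
      msg <- c(msg, "event type must be 'split' or 'size'")
    if (!all(ev$pop %in% object@populations) ||
        !all(is.na(ev$dest) | ev$dest %in% object@populations))
      msg <- c(msg, "event populations must be declared")
    # reachability: going back in time every split deactivates its pop;
    # exactly one deme must remain at the end
    active <- rep(TRUE, length(object@populations))
    names(active) <- object@populations
    for (k in seq_len(nrow(ev))) {
      if (ev$type[k] == "split") {
        if (!active[ev$pop[k]] || !active[ev$dest[k]]) {
          msg <- c(msg, sprintf("split at t=%g involves inactive deme",
                                ev$time_gen[k]))
          break
        }
        active[ev$pop[k]] <- FALSE
      } else if (!active[ev$pop[k]]) {
        msg <- c(msg, sprintf("size change at t=%g on inactive deme",
                              ev$time_gen[k]))
        break
      }
    }
    if (sum(active) != 1 && length(object@populations) > 1)
      msg <- c(msg, "populations do not merge to a single root")
  } else if (length(object@populations) > 1) {
    msg <- c(msg, "multiple populations require split events to a single root")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DemographicModel
#'
#' @param populations character labels
#' @param Ne present-day diploid effective sizes
#' @param events data.frame with columns \code{time_gen}, \code{type},
#'   \code{pop}, \code{dest}, \code{Ne} (use \code{NA} where not applicable)
#' @param mu mutation rate per site per generation
#' @param generationTime years per generation
#' @return a \linkS4class{DemographicModel}
#' @export
DemographicModel <- function(populations, Ne,
                             events = data.frame(time_gen = numeric(),
                                                 type = character(),
                                                 pop = character(),
                                                 dest = character(),
                                                 Ne = numeric()),
                             mu = 1.23e-8, generationTime = 2) {
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  if (nrow(events)) events <- events[order(events$time_gen), , drop = FALSE]
  new("DemographicModel", populations = as.character(populations),
      Ne = as.numeric(Ne), events = events, mu = mu,
      generationTime = generationTime, neUnits = "diploid")
}

setMethod("show", "DemographicModel", function(object) {
  cat("DemographicModel:", length(object@populations), "population(s)\n")
  cat("  Ne (diploid):",
      paste(sprintf("%s=%g", object@populations, object@Ne), collapse = ", "),
      "\n")
  cat("  events:", nrow(object@events),
      "| mu =", object@mu, "| generation =", object@generationTime, "yr\n")
})

#' FitResult: outcome of a composite-likelihood demographic fit
#'
#' @slot modelId model label
#' @slot par named parameter estimates
#' @slot logLik maximized composite log-likelihood
#' @slot aic 2k - 2 lnL
#' @slot nRuns number of independent optimizer runs
#' @slot runLogLik per-run best log-likelihoods
#' @slot ci matrix of bootstrap percentile CIs (rows = parameters) or NULL
#' @slot converged logical
#' @exportClass FitResult
setClass("FitResult",
  representation(modelId = "character", par = "numeric", logLik = "numeric",
                 aic = "numeric", nRuns = "integer", runLogLik = "numeric",
                 ci = "matrixOrNULL", converged = "logical"))

setValidity("FitResult", function(object) {
  k <- length(object@par)
  if (is.finite(object@logLik) &&
      abs(object@aic - (2 * k - 2 * object@logLik)) > 1e-6)
    "AIC must equal 2k - 2 lnL" else TRUE
})

setMethod("show", "FitResult", function(object) {
  cat("FitResult [", object@modelId, "] lnL =",
      sprintf("%.3f", object@logLik), " AIC =",
      sprintf("%.3f", object@aic), " (", object@nRuns, "runs )\n")
  print(round(object@par, 4))
  if (!is.null(object@ci)) { cat("95% bootstrap CI:\n"); print(round(object@ci, 4)) }
})

#' @describeIn FitResult parameter estimates
#' @param x a FitResult
#' @export
fittedPar <- function(x) x@par

#' @describeIn FitResult AIC accessor
#' @export
modelAIC <- function(x) x@aic

#' DFEResult: gamma distribution of fitness effects fit
#'
#' @slot shape gamma shape of the deleterious-effect distribution
#' @slot meanNes mean scaled selection coefficient E[Ne s]
#' @slot theta fitted mutation-rate scale of the selected class
#' @slot binMasses mass in Ne*s bins [0,1), [1,10), [10,100), [100,Inf)
#' @slot r per-frequency-class distortion factors from the neutral SFS
#' @slot logLik maximized Poisson log-likelihood
#' @slot ci bootstrap CI matrix over bins, or NULL
#' @exportClass DFEResult
setClass("DFEResult",
  representation(shape = "numeric", meanNes = "numeric", theta = "numeric",
                 binMasses = "numeric", r = "numeric", logLik = "numeric",
                 ci = "matrixOrNULL"))

setValidity("DFEResult", function(object) {
  msg <- character()
  if (length(object@binMasses) != 4 || any(object@binMasses < -1e-9))
    msg <- c(msg, "binMasses must be 4 non-negative masses")
  if (abs(sum(object@binMasses) - 1) > 1e-6)
    msg <- c(msg, "binMasses must sum to 1")
  if (object@shape <= 0) msg <- c(msg, "shape must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DFEResult", function(object) {
  cat("DFEResult: shape =", sprintf("%.3f", object@shape),
      " mean Ne*s =", sprintf("%.2f", object@meanNes), "\n")
  m <- object@binMasses
  cat(sprintf("  Ne*s bins  [0,1): %.3f  [1,10): %.3f  [10,100): %.3f  [100,Inf): %.3f\n",
              m[1], m[2], m[3], m[4]))
})

#' @describeIn DFEResult bin-mass accessor
#' @param x a DFEResult
#' @export
binMasses <- function(x) x@binMasses
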