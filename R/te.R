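# Transposable-element genomic content from sequencing depth: normalization,
# coverage filter, population means, Gaussian interaction model with intercept
# releveling, and rank tests against a reference population.

.TE_SUPERFAMILIES <- c("CACTA", "hAT", "Helitron", "Mutator", "PIF-Harbinger",
                       "Tc1-Mariner", "LTR/Copia", "LTR/Gypsy")

.check_te_table <- function(table) {
  need <- c("individual", "population", "superfamily", "te_depth",
            "genome_depth")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("TE table missing column(s): ", paste(miss, collapse = ", "))
  invisible(table)
}

#' Normalize TE sequencing depth by genome-wide depth
#'
#' Adds \code{norm_depth = te_depth / genome_depth} per individual and
#' superfamily, removing differences in sequencing effort between
#' individuals.
#'
#' @param table data.frame with columns \code{individual}, \code{population},
#'   \code{superfamily}, \code{te_depth}, \code{genome_depth} (and optionally
#'   \code{coverage})
#' @return the table with a \code{norm_depth} column
#' @export
normalizeDepth <- function(table) {
  .check_te_table(table)
  bad <- table$genome_depth <= 0
  if (any(bad))
    stop("zero genome-wide depth for individual(s): ",
         paste(unique(table$individual[bad]), collapse = ", "))
  table$norm_depth <- table$te_depth / table$genome_depth
  table
}

#' Drop TE superfamilies with insufficient consensus coverage
#'
#' A superfamily is retained when its mean consensus-coverage fraction across
#' individuals is at least \code{minCov} ("at least 80%" by default; the
#' per-superfamily mean is the adopted reading of the coverage denominator
#' and is configurable). Excluded superfamilies are listed in the
#' \code{"excluded"} attribute.
#'
#' @param table TE depth table with a \code{coverage} column in [0,1]
#' @param minCov minimum mean coverage fraction
#' @return the filtered table
#' @export
coverageFilter <- function(table, minCov = 0.80) {
  .check_te_table(table)
  if (is.null(table$coverage)) stop("coverage column required")
  cov <- tapply(table$coverage, table$superfamily, mean)
  dropped <- names(cov)[cov < minCov]
  out <- table[!table$superfamily %in% dropped, , drop = FALSE]
  attr(out, "excluded") <- dropped
  out
}

#' Per-population, per-superfamily mean normalized TE depth
#'
#' @param table normalized TE depth table (see \code{\link{normalizeDepth}})
#' @return data.frame: \code{population}, \code{superfamily},
#'   \code{mean_norm_depth}, \code{n}
#' @export
populationMeans <- function(table) {
  .check_te_table(table)
  if (is.null(table$norm_depth)) table <- normalizeDepth(table)
  agg <- stats::aggregate(norm_depth ~ population + superfamily, table, mean)
  names(agg)[3] <- "mean_norm_depth"
  cnt <- stats::aggregate(norm_depth ~ population + superfamily, table,
                          length)
  agg$n <- cnt$norm_depth
  agg
}

#' Gaussian interaction model: depth ~ population * superfamily
#'
#' Ordinary least squares (a Gaussian identity-link GLM) with treatment
#' coding, the reference level of \code{population} set by releveling so the
#' intercept is the chosen baseline (TR-D for the range-expansion contrasts,
#' EN1-D for the homostyly contrasts). Releveling changes the coefficients
#' but not the fitted values.
#'
#' @param table normalized TE depth table
#' @param interceptPopulation reference population level
#' @param interceptSuperfamily optional reference superfamily level
#' @return list: \code{fit} (the \code{lm} object), \code{coefficients}
#'   (data.frame with estimate, SE, t, p)
#' @export
interactionLM <- function(table, interceptPopulation,
                          interceptSuperfamily = NULL) {
  .check_te_table(table)
  if (is.null(table$norm_depth)) table <- normalizeDepth(table)
  if (length(unique(table$population)) < 2 ||
      length(unique(table$superfamily)) < 2)
    stop("need >= 2 populations and >= 2 superfamilies")
  table$population <- stats::relevel(factor(table$population),
                                     ref = interceptPopulation)
  sf <- factor(table$superfamily)
  if (!is.null(interceptSuperfamily))
    sf <- stats::relevel(sf, ref = interceptSuperfamily)
  table$superfamily <- sf
  fit <- stats::lm(norm_depth ~ population * superfamily, data = table)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design; aliased terms: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  cf <- summary(fit)$coefficients
  list(fit = fit,
       coefficients = data.frame(term = rownames(cf), estimate = cf[, 1],
                                 se = cf[, 2], t = cf[, 3], p = cf[, 4],
                                 row.names = NULL, stringsAsFactors = FALSE))
}

#' Pairwise Wilcoxon tests vs a reference population, Bonferroni-corrected
#'
#' Per superfamily, compares each population's normalized depths with the
#' reference population by Wilcoxon rank-sum; p-values are Bonferroni
#' corrected over the comparisons performed for that superfamily (populations
#' minus one) and flagged significant below \code{alpha}. Groups with fewer
#' than 2 individuals are skipped with a warning.
#'
#' @param table normalized TE depth table
#' @param referencePopulation baseline population
#' @param alpha significance threshold on the adjusted p-value
#' @return data.frame: superfamily, population, W, p, p_adj, significant,
#'   m (number of comparisons used for the correction)
#' @export
pairwiseWilcoxonBonferroni <- function(table, referencePopulation,
                                       alpha = 0.05) {
  .check_te_table(table)
  if (is.null(table$norm_depth)) table <- normalizeDepth(table)
  out <- list()
  for (sf in unique(table$superfamily)) {
    sub <- table[table$superfamily == sf, , drop = FALSE]
    ref <- sub$norm_depth[sub$population == referencePopulation]
    others <- setdiff(unique(sub$population), referencePopulation)
    rows <- list()
    for (pop in others) {
      grp <- sub$norm_depth[sub$population == pop]
      if (length(grp) < 2 || length(ref) < 2) {
        warning("group with < 2 individuals skipped: ", pop, " / ", sf)
        next
      }
      wt <- wilcoxonRankSum(grp, ref)
      rows[[length(rows) + 1]] <- data.frame(
        superfamily = sf, population = pop, W = wt$W, p = wt$p,
        stringsAsFactors = FALSE)
    }
    if (!length(rows)) next
    block <- do.call(rbind, rows)
    block$p_adj <- bonferroni(block$p)
    block$significant <- block$p_adj < alpha
    block$m <- nrow(block)
    out[[length(out) + 1]] <- block
  }
  if (!length(out))
    return(data.frame(superfamily = character(), population = character(),
                      W = numeric(), p = numeric(), p_adj = numeric(),
                      significant = logical(), m = integer()))
  do.call(rbind, out)
}
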