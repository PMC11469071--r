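# Windowed diversity statistics, LD, PCA and rank-based tests.

.harmonic <- function(k) if (k < 1) 0 else sum(1 / seq_len(k))

#' Watterson's theta per site
#'
#' theta_W = S / (a_(n-1) * L) with a_k the k-th harmonic number.
#'
#' @param S number of segregating sites
#' @param n haploid sample size (>= 2)
#' @param L number of accessible sites the S were ascertained over
#' @return theta_W per site
#' @export
wattersonTheta <- function(S, n, L) {
  stopifnot(n >= 2, S >= 0)
  if (L < 1) stop("accessible length must be >= 1")
  S / (.harmonic(n - 1) * L)
}

# per-site pairwise-difference terms 2 c (nc - c) / (nc (nc - 1))
.pi_site_terms <- function(cl) {
  nc <- 2 * colSums(!is.na(cl))
  c_alt <- colSums(cl, na.rm = TRUE)
  terms <- ifelse(nc >= 2, 2 * c_alt * (nc - c_alt) / (nc * (nc - 1)), 0)
  list(terms = terms, lowCalled = sum(nc < 2))
}

#' Nucleotide diversity per accessible site
#'
#' pi = sum over sites of 2 c (n_called - c) / (n_called (n_called - 1)),
#' divided by the number of accessible sites (not the window width), which is
#' the accessibility correction for missing data. Sites with fewer than two
#' called haplotypes contribute zero and are tallied in the
#' \code{"lowCalled"} attribute.
#'
#' @param gm a \linkS4class{GenotypeMatrix} restricted to the window
#' @param nAccessible number of accessible sites in the window
#' @return pi per site
#' @export
nucleotideDiversity <- function(gm, nAccessible) {
  if (nAccessible < 1) stop("window has no accessible sites")
  p <- .pi_site_terms(calls(gm))
  out <- sum(p$terms) / nAccessible
  attr(out, "lowCalled") <- p$lowCalled
  out
}

#' Total pairwise diversity implied by an unfolded SFS
#'
#' pi_total = sum_i i (n - i) xi_i * 2 / (n (n-1)); divide by accessible
#' length for a per-site value.
#'
#' @param sfs an unfolded \linkS4class{SFS1D}
#' @return total pairwise differences (not per site)
#' @export
piFromSFS <- function(sfs) {
  stopifnot(is(sfs, "SFS1D"), !sfs@folded)
  n <- sfs@n
  i <- seq_len(n - 1)
  sum(i * (n - i) * sfs@counts) * 2 / (n * (n - 1))
}

#' Tajima's D from an unfolded SFS
#'
#' Standard normalization: D = (pi_total - S/a1) / sqrt(e1 S + e2 S (S-1))
#' with the usual a1, a2, b1, b2, c1, c2, e1, e2 constants computed from the
#' haploid sample size.
#'
#' @param sfs an unfolded \linkS4class{SFS1D} with S > 0
#' @return Tajima's D
#' @export
tajimasD <- function(sfs) {
  stopifnot(is(sfs, "SFS1D"))
  n <- sfs@n
  S <- sum(sfs@counts)
  if (S <= 0) stop("Tajima's D undefined for S = 0")
  a1 <- .harmonic(n - 1)
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  if (v <= 0) stop("Tajima's D variance term non-positive")
  (piFromSFS(sfs) - S / a1) / sqrt(v)
}

#' Windowed diversity statistics with accessibility correction
#'
#' Tiles each chromosome into nonoverlapping windows of \code{windowSize}
#' accessible sites (the default; \code{mode = "bp"} tiles raw base pairs
#' instead, for sensitivity analysis) and reports Watterson's theta, pi and
#' Tajima's D per window. The accessible-site denominator makes the
#' missing-data correction exact and windows comparable. A site-class
#' restriction is expressed by AND-ing the class membership into \code{mask}
#' before calling (see \code{\link{classMask}}). Windows with zero accessible
#' sites are skipped.
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param mask named list of logical accessibility vectors per chromosome
#' @param windowSize window extent: accessible sites (default) or bp
#' @param mode \code{"sites"} or \code{"bp"}
#' @return data.frame with one row per window: \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive), \code{n_accessible}, \code{S},
#'   \code{theta_w}, \code{pi}, \code{tajima_d}
#' @export
windowedStats <- function(gm, mask, windowSize = 50000,
                          mode = c("sites", "bp")) {
  mode <- match.arg(mode)
  sites <- siteInfo(gm)
  cl <- calls(gm)
  nHap <- 2L * nrow(cl)
  out <- list()
  for (chrom in names(mask)) {
    acc <- mask[[chrom]]
    if (mode == "sites") {
      cum <- cumsum(acc)
      nWin <- ceiling(max(cum, 0) / windowSize)
      winOf <- function(pos) pmin(nWin, (cum[pos] - 1) %/% windowSize + 1)
    } else {
      nWin <- ceiling(length(acc) / windowSize)
      winOf <- function(pos) (pos - 1) %/% windowSize + 1
    }
    if (nWin == 0) next
    j <- which(sites$chrom == chrom)
    j <- j[acc[sites$pos[j]]]  # variants at accessible positions only
    vwin <- if (length(j)) winOf(sites$pos[j]) else integer()
    for (w in seq_len(nWin)) {
      if (mode == "sites") {
        posIn <- which(cum > (w - 1) * windowSize & cum <= w * windowSize &
                         acc)
      } else {
        posIn <- which(acc)
        posIn <- posIn[(posIn - 1) %/% windowSize + 1 == w]
      }
      nAcc <- length(posIn)
      if (nAcc == 0) next
      jw <- j[vwin == w]
      sub <- cl[, jw, drop = FALSE]
      p <- .pi_site_terms(sub)
      nc <- 2 * colSums(!is.na(sub))
      alt <- colSums(sub, na.rm = TRUE)
      S <- sum(alt > 0 & alt < nc)
      D <- NA_real_
      if (S > 0) {
        xi <- tabulate(pmin(alt[alt > 0 & alt < nc], nHap - 1), nHap - 1)
        D <- tryCatch(tajimasD(SFS1D(xi, nHap)), error = function(e) NA_real_)
      }
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = min(posIn), end = max(posIn),
        n_accessible = nAcc, S = S,
        theta_w = wattersonTheta(S, nHap, nAcc),
        pi = sum(p$terms) / nAcc, tajima_d = D,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      n_accessible = integer(), S = integer(),
                      theta_w = numeric(), pi = numeric(),
                      tajima_d = numeric()))
  do.call(rbind, out)
}

#' Accessibility mask restricted to a degeneracy class
#'
#' @param annotation data.frame from \code{\link{annotateDegeneracy}}
#' @param class one of \code{"zerofold"}, \code{"fourfold"},
#'   \code{"othercoding"}
#' @param chromLengths named integer vector
#' @return an \code{AccessibilityMask}-style list: TRUE only at positions of
#'   the requested class
#' @export
classMask <- function(annotation, class, chromLengths) {
  out <- lapply(names(chromLengths), function(chrom) {
    v <- rep(FALSE, chromLengths[[chrom]])
    rows <- annotation$chrom == chrom & annotation$class == class
    v[annotation$pos[rows]] <- TRUE
    v
  })
  names(out) <- names(chromLengths)
  class(out) <- "AccessibilityMask"
  out
}

#' Combine accessibility masks by AND
#' @param a,b masks as named lists of logicals over the same chromosomes
#' @export
intersectMasks <- function(a, b) {
  out <- lapply(names(a), function(chrom) a[[chrom]] & b[[chrom]])
  names(out) <- names(a)
  class(out) <- "AccessibilityMask"
  out
}

#' Ratio of nonsynonymous to synonymous diversity (pi_N / pi_S)
#'
#' @param stats0 windowed statistics at 0-fold sites (data.frame from
#'   \code{\link{windowedStats}}) or a numeric pi value
#' @param stats4 same at 4-fold sites
#' @return the ratio of mean pi at 0-fold sites to mean pi at 4-fold sites
#' @export
pinpsRatio <- function(stats0, stats4) {
  p0 <- if (is.data.frame(stats0)) mean(stats0$pi) else mean(stats0)
  p4 <- if (is.data.frame(stats4)) mean(stats4$pi) else mean(stats4)
  if (!is.finite(p4) || p4 <= 0) stop("pi_S is zero: ratio undefined")
  p0 / p4
}

#' Composite (genotype) r-squared between two sites
#'
#' Squared Pearson correlation of diploid dosage vectors over individuals
#' called at both sites; the unphased analogue of haplotype r2.
#'
#' @param a,b dosage vectors in \{0,1,2,NA\}
#' @return r2 in [0,1], or NA if either site has zero variance
#' @export
ldR2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' LD decay curve: mean r2 by physical distance
#'
#' Computes genotype r2 for all intra-chromosome pairs within \code{maxDist}
#' after excluding sites with minor-allele frequency below \code{mafMin}
#' (default excludes singletons: maf_min = 1.5 / (2 * n_individuals)), and
#' averages by distance bin.
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param maxDist maximum pair distance in bp
#' @param binWidth distance-bin width in bp
#' @param mafMin minimum minor-allele frequency; \code{NULL} uses the
#'   singleton-excluding default
#' @return data.frame: \code{dist} (bin midpoint), \code{mean_r2},
#'   \code{n_pairs}
#' @export
ldDecayCurve <- function(gm, maxDist = 50000, binWidth = 1000,
                         mafMin = NULL) {
  cl <- calls(gm)
  nInd <- nrow(cl)
  if (is.null(mafMin)) mafMin <- 1.5 / (2 * nInd)
  sites <- siteInfo(gm)
  f <- colMeans(cl, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  keep <- which(!is.na(maf) & maf >= mafMin)
  nb <- ceiling(maxDist / binWidth)
  sums <- numeric(nb); cnts <- integer(nb)
  for (chrom in unique(sites$chrom)) {
    j <- keep[sites$chrom[keep] == chrom]
    if (length(j) < 2) next
    pos <- sites$pos[j]
    for (x in seq_len(length(j) - 1)) {
      upper <- which(pos > pos[x] & pos - pos[x] <= maxDist)
      for (y in upper) {
        r2 <- ldR2(cl[, j[x]], cl[, j[y]])
        if (is.na(r2)) next
        b <- pmin(nb, (pos[y] - pos[x] - 1) %/% binWidth + 1)
        sums[b] <- sums[b] + r2
        cnts[b] <- cnts[b] + 1L
      }
    }
  }
  data.frame(dist = (seq_len(nb) - 0.5) * binWidth,
             mean_r2 = ifelse(cnts > 0, sums / cnts, NA_real_),
             n_pairs = cnts)
}

#' Greedy LD pruning within sliding windows
#'
#' Left-to-right pass: within each window (width \code{windowBp}, advancing
#' by \code{stepBp}), the later member of any retained pair with r2 >
#' \code{r2Max} is removed. Deterministic for sorted input.
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param windowBp window width in bp
#' @param stepBp step between window starts in bp
#' @param r2Max maximum tolerated genotype r2
#' @return integer vector of retained site indices (columns of \code{gm})
#' @export
ldPrune <- function(gm, windowBp = 50000, stepBp = 10000, r2Max = 0.1) {
  cl <- calls(gm)
  sites <- siteInfo(gm)
  keep <- rep(TRUE, ncol(cl))
  for (chrom in unique(sites$chrom)) {
    j <- which(sites$chrom == chrom)
    pos <- sites$pos[j]
    starts <- seq(min(pos), max(pos), by = stepBp)
    for (s in starts) {
      w <- j[pos >= s & pos < s + windowBp]
      w <- w[keep[w]]
      if (length(w) < 2) next
      for (x in seq_len(length(w) - 1)) {
        if (!keep[w[x]]) next
        for (y in (x + 1):length(w)) {
          if (!keep[w[y]]) next
          r2 <- ldR2(cl[, w[x]], cl[, w[y]])
          if (!is.na(r2) && r2 > r2Max) keep[w[y]] <- FALSE
        }
      }
    }
  }
  which(keep)
}

#' Genotype PCA
#'
#' Mean-imputes missing dosages per site, centers (and optionally scales)
#' and eigen-decomposes. Feed LD-pruned, singleton-free genotypes to match
#' the usual protocol for population structure.
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param nPC number of components to return (truncated to rank, warned)
#' @param scale divide by per-site standard deviation
#' @return list: \code{coords} (individuals x PCs),
#'   \code{varianceFraction}, \code{sdev}
#' @export
genotypePCA <- function(gm, nPC = 10, scale = TRUE) {
  cl <- calls(gm)
  mu <- colMeans(cl, na.rm = TRUE)
  for (k in which(colSums(is.na(cl)) > 0)) cl[is.na(cl[, k]), k] <- mu[k]
  sdv <- apply(cl, 2, stats::sd)
  use <- sdv > 0
  pr <- stats::prcomp(cl[, use, drop = FALSE], center = TRUE, scale. = scale)
  rank <- sum(pr$sdev > 1e-12)
  if (nPC > rank) {
    warning("requested ", nPC, " PCs but rank is ", rank, "; truncating")
    nPC <- rank
  }
  vf <- pr$sdev^2 / sum(pr$sdev^2)
  coords <- pr$x[, seq_len(nPC), drop = FALSE]
  rownames(coords) <- sampleInfo(gm)$id
  list(coords = coords, varianceFraction = vf[seq_len(nPC)], sdev = pr$sdev)
}

#' Rank-based tests used throughout the analyses
#'
#' Thin, uniformly-shaped wrappers over the standard tie-corrected tests:
#' Spearman rank correlation (t-approximation for the p-value),
#' Kruskal-Wallis, Wilcoxon rank-sum (normal approximation with continuity
#' correction) and Bonferroni adjustment capped at 1.
#'
#' @param x,y paired numeric vectors
#' @return \code{spearmanTest}: list with \code{rho}, \code{p};
#'   \code{kruskalTest}: list with \code{chisq}, \code{df}, \code{p};
#'   \code{wilcoxonRankSum}: list with \code{W}, \code{p};
#'   \code{bonferroni}: adjusted p-values
#' @export
spearmanTest <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 paired points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for a constant vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' @rdname spearmanTest
#' @param values numeric observations
#' @param groups grouping factor (>= 2 levels)
#' @export
kruskalTest <- function(values, groups) {
  kt <- stats::kruskal.test(values, as.factor(groups))
  list(chisq = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' @rdname spearmanTest
#' @param a,b the two samples to compare
#' @export
wilcoxonRankSum <- function(a, b) {
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = TRUE))
  list(W = unname(wt$statistic), p = wt$p.value)
}

#' @rdname spearmanTest
#' @param p vector of p-values
#' @export
bonferroni <- function(p) stats::p.adjust(p, method = "bonferroni")
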