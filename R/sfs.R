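# Building, folding, projecting and serializing site frequency spectra.

# per-site derived counts and called haplotype numbers, honouring the
# ancestral-allele assignment (reference-allele polarization by default)
.derived_counts <- function(gm, ancestral) {
  sites <- siteInfo(gm)
  if (is.null(ancestral)) ancestral <- sites$ref
  stopifnot(length(ancestral) == nrow(sites))
  cl <- calls(gm)
  nCalled <- 2L * colSums(!is.na(cl))
  altCount <- colSums(cl, na.rm = TRUE)
  derived <- ifelse(ancestral == sites$ref, altCount,
             ifelse(ancestral == sites$alt, nCalled - altCount, NA_real_))
  list(derived = derived, nCalled = nCalled,
       unpolarized = sum(is.na(derived)))
}

#' Build an unfolded site frequency spectrum from genotypes
#'
#' Counts sites by derived-allele count among called haplotypes. Sites where
#' the assigned ancestral allele matches neither allele are excluded (tallied
#' in the \code{"excluded"} attribute). Sites with missing genotypes are
#' incorporated by hypergeometric projection down to a common haploid size
#' \code{nProject}; sites called in fewer than \code{nProject} haplotypes are
#' dropped (tallied).
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param ancestral per-site ancestral alleles; default \code{NULL} uses the
#'   reference allele (reference-genome polarization)
#' @param nProject target haploid sample size; default is the smallest number
#'   of called haplotypes across sites, so every site contributes
#' @return an \linkS4class{SFS1D} (entries may be fractional after projection)
#' @export
unfoldedSFS <- function(gm, ancestral = NULL, nProject = NULL) {
  dc <- .derived_counts(gm, ancestral)
  ok <- !is.na(dc$derived) & dc$nCalled >= 2
  if (!any(ok)) stop("no polarizable sites: empty SFS")
  der <- dc$derived[ok]; nc <- dc$nCalled[ok]
  m <- if (is.null(nProject)) min(nc) else as.integer(nProject)
  if (m < 2) stop("projection size must be >= 2")
  dropped <- sum(nc < m)
  keep <- nc >= m
  der <- der[keep]; nc <- nc[keep]
  xi <- numeric(m - 1); mono <- c(0, 0)
  # exact sites at full size contribute unit mass; others hypergeometric
  for (grp in split(seq_along(der), nc)) {
    n_g <- nc[grp[1]]
    tab <- table(der[grp])
    for (s in seq_along(tab)) {
      c_g <- as.integer(names(tab)[s]); w <- as.numeric(tab[s])
      if (n_g == m) {
        if (c_g == 0) mono[1] <- mono[1] + w
        else if (c_g == m) mono[2] <- mono[2] + w
        else xi[c_g] <- xi[c_g] + w
      } else {
        pj <- stats::dhyper(0:m, c_g, n_g - c_g, m)
        mono <- mono + w * pj[c(1, m + 1)]
        xi <- xi + w * pj[2:m]
      }
    }
  }
  out <- SFS1D(xi, m, folded = FALSE, monomorphic = mono)
  attr(out, "excluded") <- dc$unpolarized
  attr(out, "dropped") <- dropped
  out
}

#' Fold a site frequency spectrum onto minor-allele counts
#'
#' eta_i = xi_i + xi_(n-i) for i < n/2 and eta_(n/2) = xi_(n/2).
#'
#' @param sfs an unfolded \linkS4class{SFS1D}
#' @return a folded \linkS4class{SFS1D}
#' @export
foldSFS <- function(sfs) {
  stopifnot(is(sfs, "SFS1D"), !sfs@folded)
  n <- sfs@n; xi <- sfs@counts
  h <- floor(n / 2)
  eta <- vapply(seq_len(h), function(i)
    if (i == n - i) xi[i] else xi[i] + xi[n - i], numeric(1))
  SFS1D(eta, n, folded = TRUE, monomorphic = sfs@monomorphic)
}

#' Project an SFS to a smaller sample size
#'
#' Expected spectrum under hypergeometric subsampling of \code{m} haplotypes
#' without replacement: xi'_j = sum_i xi_i P[Hypergeom = j]. Mass falling on
#' the monomorphic classes (j = 0 or m) is moved to the monomorphic tallies,
#' so total polymorphic mass never increases.
#'
#' @param sfs an unfolded \linkS4class{SFS1D}
#' @param m target haploid size, 2 <= m <= n
#' @return an \linkS4class{SFS1D} at size \code{m}
#' @export
projectSFS <- function(sfs, m) {
  stopifnot(is(sfs, "SFS1D"), !sfs@folded)
  n <- sfs@n; m <- as.integer(m)
  if (m > n) stop("cannot project to a larger sample size")
  if (m < 2) stop("m must be >= 2")
  if (m == n) return(sfs)
  xi <- numeric(m - 1)
  mono <- ifelse(is.na(sfs@monomorphic), 0, sfs@monomorphic)
  for (i in seq_len(n - 1)) {
    if (sfs@counts[i] == 0) next
    pj <- stats::dhyper(0:m, i, n - i, m)
    mono <- mono + sfs@counts[i] * pj[c(1, m + 1)]
    xi <- xi + sfs@counts[i] * pj[2:m]
  }
  SFS1D(xi, m, folded = FALSE, monomorphic = mono)
}

#' Build a multidimensional SFS across populations
#'
#' Strict mode: sites with any missing genotype are rejected (tallied in the
#' \code{"rejected"} attribute), so every retained site is scored in all
#' individuals. Monomorphic sites land in the corner cells.
#'
#' @param gm a \linkS4class{GenotypeMatrix} whose samples carry population
#'   labels
#' @param populations population order for the output dimensions; default is
#'   the order of first appearance in the sample table
#' @param ancestral per-site ancestral alleles (default: reference allele)
#' @return a \linkS4class{JointSFS} of site counts
#' @export
makeJointSFS <- function(gm, populations = NULL, ancestral = NULL) {
  smp <- sampleInfo(gm)
  if (is.null(populations)) populations <- unique(smp$population)
  cl <- calls(gm)
  sites <- siteInfo(gm)
  if (is.null(ancestral)) ancestral <- sites$ref
  complete <- colSums(is.na(cl)) == 0
  polarizable <- ancestral == sites$ref | ancestral == sites$alt
  use <- complete & polarizable
  nhap <- vapply(populations, function(p) 2L * sum(smp$population == p),
                 integer(1))
  dims <- unname(nhap) + 1L
  counts <- array(0, dim = dims)
  if (any(use)) {
    percell <- sapply(populations, function(p) {
      rows <- smp$population == p
      alt <- colSums(cl[rows, use, drop = FALSE])
      ifelse(ancestral[use] == sites$ref[use], alt, nhap[p] - alt)
    })
    percell <- matrix(percell, ncol = length(populations))
    idx <- as.vector(1 + percell %*% cumprod(c(1, dims[-length(dims)])))
    tab <- table(idx)
    counts[as.integer(names(tab))] <- as.numeric(tab)
  }
  out <- JointSFS(counts, populations)
  attr(out, "rejected") <- sum(!complete)
  out
}

#' Marginalize a JointSFS onto one population
#'
#' @param jsfs a \linkS4class{JointSFS}
#' @param population label of the population to keep
#' @return an \linkS4class{SFS1D} for that population
#' @export
marginalSFS <- function(jsfs, population) {
  k <- match(population, jsfs@populations)
  if (is.na(k)) stop("unknown population: ", population)
  m <- apply(jsfs@counts, k, sum)
  n <- dim(jsfs@counts)[k] - 1L
  SFS1D(m[2:n], n, folded = FALSE, monomorphic = m[c(1, n + 1)])
}

# row-major flattening: first-listed population varies slowest
.flatten_rowmajor <- function(a) as.vector(aperm(a, rev(seq_along(dim(a)))))
.unflatten_rowmajor <- function(v, dims) {
  aperm(array(v, dim = rev(dims)), rev(seq_along(dims)))
}

#' Write a site frequency spectrum to a text file
#'
#' Dialects: \code{"dadi"} (one header line \code{n1 n2 ... [un]folded}, then
#' the full spectrum including monomorphic corners, row-major with the
#' first-listed population varying slowest), \code{"multisfs"} (header
#' \code{npop n1 n2 ...}, then the flattened spectrum, same order) and
#' \code{"tsv"} (1D only: columns \code{i}, \code{count}).
#'
#' @param sfs an \linkS4class{SFS1D} or \linkS4class{JointSFS}
#' @param path output file
#' @param dialect one of \code{"dadi"}, \code{"multisfs"}, \code{"tsv"}
#' @export
writeSFS <- function(sfs, path, dialect = c("dadi", "multisfs", "tsv")) {
  dialect <- match.arg(dialect)
  if (is(sfs, "SFS1D")) {
    stopifnot(!sfs@folded || dialect == "tsv")
    mono <- ifelse(is.na(sfs@monomorphic), 0, sfs@monomorphic)
    full <- c(mono[1], sfs@counts, mono[2])
    dims <- sfs@n + 1L
  } else {
    full <- .flatten_rowmajor(sfs@counts)
    dims <- dim(sfs@counts)
  }
  if (dialect == "tsv") {
    stopifnot(is(sfs, "SFS1D"))
    utils::write.table(
      data.frame(i = seq_along(sfs@counts), count = sfs@counts),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (dialect == "dadi") {
    hdr <- paste(c(dims, if (is(sfs, "SFS1D") && sfs@folded) "folded"
                         else "unfolded"), collapse = " ")
    writeLines(c(hdr, paste(format(full, digits = 12, trim = TRUE),
                            collapse = " ")), path)
  } else {
    writeLines(c(paste(c(length(dims), dims - 1L), collapse = " "),
                 paste(format(full, digits = 12, trim = TRUE),
                       collapse = " ")), path)
  }
  invisible(path)
}

#' Read a site frequency spectrum written by \code{\link{writeSFS}}
#'
#' @param path input file
#' @param dialect one of \code{"dadi"}, \code{"multisfs"}, \code{"tsv"}
#' @return an \linkS4class{SFS1D} (one dimension) or \linkS4class{JointSFS}
#' @export
readSFS <- function(path, dialect = c("dadi", "multisfs", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    d <- utils::read.table(path, header = TRUE, sep = "\t")
    return(SFS1D(d$count, n = nrow(d) + 1L))
  }
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  vals <- as.numeric(strsplit(trimws(paste(lines[-1], collapse = " ")),
                              "\\s+")[[1]])
  if (dialect == "dadi") {
    folded <- identical(hdr[length(hdr)], "folded")
    dims <- as.integer(hdr[seq_len(length(hdr) - 1)])
  } else {
    npop <- as.integer(hdr[1])
    if (length(hdr) != npop + 1) stop("multisfs header/dimension mismatch")
    dims <- as.integer(hdr[-1]) + 1L
    folded <- FALSE
  }
  if (length(vals) != prod(dims))
    stop(sprintf("SFS body has %d entries, header implies %d",
                 length(vals), prod(dims)))
  if (length(dims) == 1) {
    n <- dims - 1L
    SFS1D(vals[2:n], n, folded = folded, monomorphic = vals[c(1, n + 1)])
  } else {
    JointSFS(.unflatten_rowmajor(vals, dims),
             paste0("pop", seq_along(dims)))
  }
}
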