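# VCF reading and the site/genotype filtering cascade.

.site_key <- function(x) {
  if (is(x, "GenotypeMatrix")) x <- siteInfo(x)
  paste(x$chrom, x$pos, sep = ":")
}

.info_num <- function(vcf, field) {
  v <- suppressWarnings(vcfR::extract.info(vcf, element = field,
                                           as.numeric = TRUE))
  if (is.null(v)) rep(NA_real_, nrow(vcf@fix)) else as.numeric(v)
}

#' Read a VCF into a GenotypeMatrix plus per-site variant records
#'
#' Parses diploid GT calls into dosages (0/1/2/NA) and collects the site-level
#' annotations used by the filter cascade (QD, MQ, FS, MQRankSum,
#' ReadPosRankSum, DP, InbreedingCoeff) together with per-genotype allele
#' depths. Annotations absent from a record are stored as \code{NA}, never as
#' zero. Multiallelic records are flagged \code{biallelic = FALSE}; their
#' genotypes carrying alleles beyond the first alternate are set missing.
#'
#' @param path VCF 4.x file (plain or bgzipped)
#' @param popmap optional data.frame with columns \code{id},
#'   \code{population} and optionally \code{morph} to label samples
#' @return list with \code{genotypes} (\linkS4class{GenotypeMatrix}),
#'   \code{records} (data.frame, one row per VCF data line) and \code{AD}
#'   (list of \code{ref}/\code{alt} depth matrices, individuals x sites)
#' @export
readVCFGenotypes <- function(path, popmap = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  # diploid check and dosage conversion
  alleles <- gsub("\\|", "/", gt)
  nall <- lengths(regmatches(alleles, gregexpr("/", alleles))) + 1L
  called <- !is.na(alleles) & alleles != "./." & alleles != "."
  if (any(nall[called] != 2))
    stop("unsupported ploidy: non-diploid GT encountered")
  a1 <- suppressWarnings(as.integer(sub("/.*", "", alleles)))
  a2 <- suppressWarnings(as.integer(sub(".*/", "", alleles)))
  dos <- a1 + a2
  dos[!as.vector(called)] <- NA_integer_
  dos[!is.na(a1) & (a1 > 1 | a2 > 1)] <- NA_integer_  # beyond first alt
  dim(dos) <- dim(gt)     # sub() drops dimensions
  dos <- t(dos)           # individuals x sites
  records <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    biallelic = !grepl(",", fix$ALT) & !is.na(fix$ALT) & fix$ALT != ".",
    QD = .info_num(vcf, "QD"), MQ = .info_num(vcf, "MQ"),
    FS = .info_num(vcf, "FS"), MQRankSum = .info_num(vcf, "MQRankSum"),
    ReadPosRankSum = .info_num(vcf, "ReadPosRankSum"),
    DP = .info_num(vcf, "DP"),
    InbreedingCoeff = .info_num(vcf, "InbreedingCoeff"),
    stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (!is.null(ad) && !all(is.na(ad))) {
    parts <- strsplit(as.vector(ad), ",")
    fld <- function(k) suppressWarnings(as.numeric(vapply(parts, function(p)
      if (length(p) >= k) p[k] else NA_character_, character(1))))
    adRef <- t(matrix(fld(1), nrow = nrow(ad)))
    adAlt <- t(matrix(fld(2), nrow = nrow(ad)))
  } else adRef <- adAlt <- NULL
  ids <- colnames(gt)
  samples <- data.frame(id = ids, population = NA_character_,
                        morph = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(popmap)) {
    m <- match(ids, popmap$id)
    samples$population <- popmap$population[m]
    if (!is.null(popmap$morph)) samples$morph <- popmap$morph[m]
  }
  gm <- GenotypeMatrix(dos, samples,
                       records[, c("chrom", "pos", "ref", "alt")])
  list(genotypes = gm, records = records,
       AD = list(ref = adRef, alt = adAlt))
}

#' Apply the site-level quality filter cascade
#'
#' Keeps records with QD > 2, MQ > 40, FS < 60, MQRankSum > -12.5,
#' ReadPosRankSum > -8, depth within [depthMean/2, 3*depthMean] and
#' InbreedingCoeff >= -0.99 (sites below that represent fixed heterozygosity,
#' typically collapsed paralogs). A record missing an annotation passes that
#' single criterion, mirroring common VCF practice for e.g. MQRankSum at
#' homozygous sites. The filters are set intersections, so their order is
#' immaterial.
#'
#' @param records data.frame from \code{\link{readVCFGenotypes}}
#' @param depthMean dataset mean site depth (the reference point for the
#'   depth bounds)
#' @param thresholds named list overriding any of \code{qdMin}, \code{mqMin},
#'   \code{fsMax}, \code{mqrsMin}, \code{rprsMin}, \code{inbMin},
#'   \code{dpLowFactor}, \code{dpHighFactor}
#' @return the surviving subset of \code{records}
#' @export
applySiteFilters <- function(records, depthMean, thresholds = list()) {
  stopifnot(depthMean > 0)
  th <- modifyList(list(qdMin = 2.0, mqMin = 40.0, fsMax = 60.0,
                        mqrsMin = -12.5, rprsMin = -8.0, inbMin = -0.99,
                        dpLowFactor = 0.5, dpHighFactor = 3.0), thresholds)
  pass <- function(x, f) is.na(x) | f(x)
  keep <- pass(records$QD, function(x) x > th$qdMin) &
    pass(records$MQ, function(x) x > th$mqMin) &
    pass(records$FS, function(x) x < th$fsMax) &
    pass(records$MQRankSum, function(x) x > th$mqrsMin) &
    pass(records$ReadPosRankSum, function(x) x > th$rprsMin) &
    pass(records$DP, function(x) !(x < th$dpLowFactor * depthMean |
                                     x > th$dpHighFactor * depthMean)) &
    pass(records$InbreedingCoeff, function(x) x >= th$inbMin)
  records[keep, , drop = FALSE]
}

#' Apply genotype-level depth and allelic-balance filters
#'
#' Genotypes whose total allele depth falls below \code{adMin} or above
#' \code{adMax} are set to missing. Any site that still contains a
#' heterozygous call whose allelic balance AB = AD_alt / (AD_ref + AD_alt)
#' lies outside \code{[abLow, abHigh]} is removed entirely (such sites tend to
#' carry erroneous heterozygous calls). Called genotypes without AD
#' information are retained with one warning.
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param AD list with \code{ref} and \code{alt} depth matrices aligned to
#'   \code{gm}
#' @param adMin,adMax total-depth bounds per genotype
#' @param abLow,abHigh allelic-balance window for heterozygous calls
#' @return a filtered \linkS4class{GenotypeMatrix}
#' @export
applyGenotypeFilters <- function(gm, AD, adMin = 6, adMax = 60,
                                 abLow = 0.30, abHigh = 0.70) {
  cl <- calls(gm)
  if (is.null(AD$ref) || is.null(AD$alt)) {
    warning("AD missing for called genotypes; genotypes retained")
    return(gm)
  }
  tot <- AD$ref + AD$alt
  called <- !is.na(cl)
  noAD <- called & is.na(tot)
  if (any(noAD))
    warning(sum(noAD), " called genotype(s) without AD retained")
  bad <- called & !is.na(tot) & (tot < adMin | tot > adMax)
  cl[bad] <- NA_integer_
  ab <- AD$alt / tot
  het <- !is.na(cl) & cl == 1L & !is.na(ab)
  offending <- het & (ab < abLow | ab > abHigh)
  dropSite <- colSums(offending) > 0
  GenotypeMatrix(cl[, !dropSite, drop = FALSE], sampleInfo(gm),
                 siteInfo(gm)[!dropSite, , drop = FALSE])
}

#' Finalize a callset: biallelic sites on whitelisted chromosomes
#'
#' Retains biallelic SNPs located on the supplied chromosome whitelist with
#' per-site missingness strictly below \code{maxMissing}.
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param chromosomes chromosome whitelist (e.g. the 11 assembled chromosomes)
#' @param records optional records data.frame carrying the
#'   \code{biallelic} flag; when absent, biallelic status is inferred from the
#'   site table (single-base REF/ALT)
#' @param maxMissing maximum tolerated fraction of missing calls per site
#' @return a filtered \linkS4class{GenotypeMatrix}
#' @export
finalizeCallset <- function(gm, chromosomes, records = NULL,
                            maxMissing = 0.20) {
  sites <- siteInfo(gm)
  if (!is.null(records)) {
    bi <- records$biallelic[match(.site_key(gm), .site_key(records))]
    bi[is.na(bi)] <- FALSE
  } else {
    bi <- !grepl(",", sites$alt) & nchar(sites$ref) == 1 &
      nchar(sites$alt) == 1
  }
  miss <- colMeans(is.na(calls(gm)))
  keep <- bi & sites$chrom %in% chromosomes & miss < maxMissing
  if (!any(keep)) warning("empty callset after finalization")
  subsetGenotypes(gm, j = keep)
}

#' Subsample polymorphic sites uniformly at random
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param n number of polymorphic sites to draw (without replacement); if
#'   fewer are available, all are returned with a warning
#' @param seed optional integer seed for reproducibility
#' @return a \linkS4class{GenotypeMatrix} of sampled sites, in genomic order
#' @export
samplePolymorphicSites <- function(gm, n, seed = NULL) {
  cl <- calls(gm)
  alt <- colSums(cl, na.rm = TRUE)
  ncalled <- 2L * colSums(!is.na(cl))
  poly <- which(alt > 0 & alt < ncalled)
  if (n > length(poly)) {
    warning("requested ", n, " sites but only ", length(poly),
            " polymorphic sites available; returning all")
    n <- length(poly)
  }
  pick <- .with_seed(seed, sort(sample(poly, n)))
  subsetGenotypes(gm, j = pick)
}
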