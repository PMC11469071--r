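# Synthetic-dataset generator: a serial-founder expansion with optional
# selfing demes, a toy genome annotation, and a TE depth table, emitting the
# standard file formats so every pipeline stage is testable without data
# downloads.

#' Study design for the synthetic serial-founder dataset
#'
#' Defaults mirror the sampled system: nine demes along an east-to-west
#' expansion axis (six dimorphic, two trimorphic, one monomorphic; 105
#' diploid individuals in total), eleven chromosomes, serial founder
#' bottlenecks at each colonization step, inbreeding in the homostyle-bearing
#' demes (F = 0.45 trimorphic, 0.9 monomorphic), a gamma DFE acting on 0-fold
#' sites and a population-by-superfamily TE effect matrix. Sizes and the
#' sequence scale are reduced (Ne in the thousands, ~1 Mb of genome) so a
#' full pipeline run stays desk-sized; the mutation rate is scaled up
#' correspondingly to preserve realistic per-site diversity.
#'
#' @param nInd per-deme diploid sample sizes
#' @param Ne per-deme present-day diploid effective sizes
#' @param splitGen backward-time colonization (split) times in generations
#'   for demes 2..k (deme i founded from deme i-1)
#' @param founderNe founder bottleneck size at each colonization
#' @param founderDur bottleneck duration in generations
#' @param F per-deme inbreeding coefficient
#' @param nChrom,chromLen genome layout
#' @param genesPerChrom,geneLen,cdsLen gene layout (single-CDS genes)
#' @param repeatFrac fraction of each chromosome masked as repeat
#' @param mu mutation rate per site per generation (scaled)
#' @param dfeShape,dfeMeanNes gamma DFE on 0-fold sites (Ne*s units)
#' @param teEffects population x superfamily matrix of normalized-depth
#'   shifts (NULL = modest expansion-like defaults)
#' @param teNoiseSd individual-level noise SD of normalized TE depth
#' @return a list of class \code{"studyDesign"}
#' @export
studyDesign <- function(
    nInd = c(`TR-D` = 10, `SK-D` = 10, `CH-D` = 10, `EN1-D` = 9,
             `EN2-D` = 9, `EN3-D` = 10, `EN4-T` = 17, `EN5-T` = 19,
             `EN6-M` = 11),
    Ne = c(10000, 7000, 6000, 4000, 3500, 3000, 2500, 2200, 800),
    splitGen = c(16000, 14000, 9000, 8000, 7000, 6000, 5500, 5000),
    founderNe = c(400, 400, 300, 300, 300, 250, 250, 120),
    founderDur = 200,
    F = c(0, 0, 0, 0, 0, 0, 0.45, 0.45, 0.9),
    nChrom = 11, chromLen = 100000,
    genesPerChrom = 4, geneLen = 3000, cdsLen = 900,
    repeatFrac = 0.05,
    mu = 1.23e-7,
    dfeShape = 0.3, dfeMeanNes = 100,
    teEffects = NULL, teNoiseSd = 0.05) {
  k <- length(nInd)
  stopifnot(length(Ne) == k, length(splitGen) == k - 1,
            length(founderNe) == k - 1, length(F) == k,
            !is.unsorted(rev(splitGen)))
  if (is.null(teEffects)) {
    teEffects <- matrix(0, k, length(.TE_SUPERFAMILIES),
                        dimnames = list(names(nInd), .TE_SUPERFAMILIES))
    teEffects[-1, "Mutator"] <- 0.3   # higher Mutator content west of TR
    teEffects[1, "hAT"] <- 0.3        # higher hAT content in the core deme
  }
  structure(list(nInd = nInd, Ne = Ne, splitGen = splitGen,
                 founderNe = founderNe, founderDur = founderDur, F = F,
                 nChrom = nChrom, chromLen = chromLen,
                 genesPerChrom = genesPerChrom, geneLen = geneLen,
                 cdsLen = cdsLen, repeatFrac = repeatFrac, mu = mu,
                 dfeShape = dfeShape, dfeMeanNes = dfeMeanNes,
                 teEffects = teEffects, teNoiseSd = teNoiseSd),
            class = "studyDesign")
}

#' Serial-founder demographic model implied by a study design
#'
#' Backward in time, deme i recovers to its founder size at
#' \code{splitGen[i-1] - founderDur} and merges into deme i-1 at
#' \code{splitGen[i-1]}.
#'
#' @param design a \code{\link{studyDesign}}
#' @return a \linkS4class{DemographicModel}
#' @export
designModel <- function(design) {
  pops <- names(design$nInd)
  k <- length(pops)
  ev <- list()
  for (i in 2:k) {
    Tsplit <- design$splitGen[i - 1]
    ev[[length(ev) + 1]] <- data.frame(
      time_gen = max(0, Tsplit - design$founderDur), type = "size",
      pop = pops[i], dest = NA_character_, Ne = design$founderNe[i - 1],
      stringsAsFactors = FALSE)
    ev[[length(ev) + 1]] <- data.frame(
      time_gen = Tsplit, type = "split", pop = pops[i], dest = pops[i - 1],
      Ne = NA_real_, stringsAsFactors = FALSE)
  }
  DemographicModel(pops, design$Ne, do.call(rbind, ev), mu = design$mu,
                   generationTime = 2)
}

# toy annotation: genes evenly spaced, each with one CDS of cdsLen at the
# gene start; repeats one interval per chromosome
.design_annotation <- function(design) {
  genes <- list(); repeats <- list()
  for (c in seq_len(design$nChrom)) {
    chrom <- paste0("chr", c)
    span <- design$chromLen %/% (design$genesPerChrom + 1)
    for (g in seq_len(design$genesPerChrom)) {
      start <- g * span
      genes[[length(genes) + 1]] <- data.frame(
        chrom = chrom, start = start, end = start + design$geneLen - 1,
        cds_start = start, cds_end = start + design$cdsLen - 1,
        strand = if (g %% 2 == 0) "-" else "+",
        id = sprintf("gene_%s_%d", chrom, g), stringsAsFactors = FALSE)
    }
    rlen <- round(design$chromLen * design$repeatFrac)
    repeats[[length(repeats) + 1]] <- data.frame(
      chrom = chrom, start = design$chromLen - rlen + 1,
      end = design$chromLen, stringsAsFactors = FALSE)
  }
  list(genes = do.call(rbind, genes), repeats = do.call(rbind, repeats))
}

.write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (r in seq_len(nrow(genes))) {
    g <- genes[r, ]
    lines <- c(lines,
      sprintf("%s\tsynth\tgene\t%d\t%d\t.\t%s\t.\tID=%s", g$chrom, g$start,
              g$end, g$strand, g$id),
      sprintf("%s\tsynth\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              g$chrom, g$start, g$end, g$strand, g$id, g$id),
      sprintf("%s\tsynth\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s.t1",
              g$chrom, g$cds_start, g$cds_end, g$strand, g$id, g$id))
  }
  writeLines(lines, path)
}

.write_vcf <- function(gm, records, AD, path) {
  smp <- sampleInfo(gm)
  sites <- siteInfo(gm)
  cl <- calls(gm)
  hdr <- c("##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Strand bias\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"MQ rank sum\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read pos rank sum\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Site depth\">",
    "##INFO=<ID=InbreedingCoeff,Number=1,Type=Float,Description=\"Inbreeding coefficient\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", smp$id), collapse = "\t"))
  gtStr <- matrix("./.", nrow(cl), ncol(cl))
  gtStr[!is.na(cl) & cl == 0] <- "0/0"
  gtStr[!is.na(cl) & cl == 1] <- "0/1"
  gtStr[!is.na(cl) & cl == 2] <- "1/1"
  adStr <- matrix(sprintf("%d,%d", ifelse(is.na(AD$ref), 0, AD$ref),
                          ifelse(is.na(AD$alt), 0, AD$alt)),
                  nrow(cl), ncol(cl))
  body <- vapply(seq_len(ncol(cl)), function(j) {
    info <- sprintf(
      "QD=%.2f;MQ=%.2f;FS=%.2f;MQRankSum=%.2f;ReadPosRankSum=%.2f;DP=%d;InbreedingCoeff=%.3f",
      records$QD[j], records$MQ[j], records$FS[j], records$MQRankSum[j],
      records$ReadPosRankSum[j], records$DP[j], records$InbreedingCoeff[j])
    paste(c(sites$chrom[j], sites$pos[j], ".", sites$ref[j], sites$alt[j],
            ".", "PASS", info, "GT:AD",
            paste(gtStr[, j], adStr[, j], sep = ":")), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
}

#' Generate a complete synthetic dataset
#'
#' Simulates genotypes under the design's serial-founder model (one
#' coalescent genealogy per chromosome), assigns morph labels, thins 0-fold
#' coding sites toward the selected-site spectrum implied by the design's
#' gamma DFE (acceptance-sampling on derived-allele counts), fabricates
#' site-level quality annotations and allele depths from simple calibrated
#' distributions (solely to exercise the filter cascade), and draws the TE
#' depth table around population-by-superfamily means. With \code{outDir}
#' set, writes \code{sim.vcf}, \code{genes.gff3}, \code{repeats.bed}
#' (0-based half-open), \code{ancestral.tsv}, \code{te_depth.tsv} and
#' \code{truth.json}.
#'
#' @param design a \code{\link{studyDesign}}
#' @param seed integer seed; identical seeds give identical datasets
#' @param outDir optional output directory
#' @return list: \code{genotypes} (\linkS4class{GenotypeMatrix}),
#'   \code{records}, \code{AD}, \code{annotation} (genes/repeats tables),
#'   \code{degeneracy} (site-class data.frame), \code{teTable}, \code{model}
#'   (the generating \linkS4class{DemographicModel}) and \code{truth}
#'   (every generating parameter)
#' @export
generateDataset <- function(design = studyDesign(), seed = 1, outDir = NULL) {
  model <- designModel(design)
  pops <- names(design$nInd)
  nh <- setNames(2L * as.integer(design$nInd), pops)
  config <- sampleConfig(nh, L = design$chromLen, F = design$F)
  .with_seed(seed, {
    gm <- simulateGenotypes(model, config, nLoci = design$nChrom,
                            seed = NULL)
    smp <- sampleInfo(gm)
    # morph labels: dimorphic S/L alternating; trimorphic S/L/H thirds;
    # monomorphic all H
    morph <- character(nrow(smp))
    for (p in pops) {
      rows <- which(smp$population == p)
      Fp <- design$F[match(p, pops)]
      if (Fp >= 0.9) {                      # monomorphic: all homostyles
        morph[rows] <- "H"
      } else if (Fp > 0) {                  # trimorphic: about half H
        nH <- floor(length(rows) / 2)
        morph[rows] <- c(rep(c("S", "L"), length.out = length(rows) - nH),
                         rep("H", nH))
      } else {                              # dimorphic
        morph[rows] <- rep(c("S", "L"), length.out = length(rows))
      }
    }
    smp$morph <- morph
    gm <- GenotypeMatrix(calls(gm), smp, siteInfo(gm))

    ann <- .design_annotation(design)
    deg <- .design_degeneracy(design, ann)

    # thin 0-fold sites toward the selected spectrum (acceptance sampling
    # on global derived counts)
    sites <- siteInfo(gm)
    key <- paste(sites$chrom, sites$pos)
    zkey <- paste(deg$chrom, deg$pos)[deg$class == "zerofold"]
    zf <- key %in% zkey
    if (any(zf)) {
      n <- 2L * nrow(calls(gm))
      eSel <- .dfe_expected(design$dfeShape, design$dfeMeanNes, n, K = 32)
      eNeu <- 1 / seq_len(n - 1)
      w <- eSel / eNeu
      w <- w / max(w)
      cnt <- colSums(calls(gm), na.rm = TRUE)
      acc <- rep(TRUE, ncol(calls(gm)))
      idx <- which(zf & cnt >= 1 & cnt <= n - 1)
      acc[idx] <- stats::runif(length(idx)) < w[cnt[idx]]
      gm <- subsetGenotypes(gm, j = acc)
      sites <- siteInfo(gm)
    }

    # fabricated quality annotations and allele depths
    nSite <- nSites(gm)
    nInd <- nrow(calls(gm))
    meanDepth <- 18.9
    records <- data.frame(
      chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
      alt = sites$alt, biallelic = TRUE,
      QD = pmax(0.1, stats::rnorm(nSite, 20, 6)),
      MQ = pmin(60, stats::rnorm(nSite, 58, 3)),
      FS = stats::rexp(nSite, rate = 1 / 4),
      MQRankSum = stats::rnorm(nSite, 0, 1.5),
      ReadPosRankSum = stats::rnorm(nSite, 0, 1.5),
      DP = stats::rpois(nSite, nInd * meanDepth),
      InbreedingCoeff = pmax(-1, stats::rnorm(nSite, 0.05, 0.15)),
      stringsAsFactors = FALSE)
    dp <- matrix(stats::rpois(nInd * nSite, meanDepth), nInd, nSite)
    dp[dp < 2] <- 2
    cl <- calls(gm)
    altFrac <- matrix(0, nInd, nSite)
    altFrac[!is.na(cl) & cl == 1] <- 0.5
    altFrac[!is.na(cl) & cl == 2] <- 1
    adAlt <- matrix(stats::rbinom(nInd * nSite, as.vector(dp),
                                  as.vector(altFrac)), nInd, nSite)
    AD <- list(ref = dp - adAlt, alt = adAlt)

    teTable <- .design_te_table(design, sampleInfo(gm))

    truth <- list(design = design[setdiff(names(design), "teEffects")],
                  teEffects = design$teEffects,
                  model = list(populations = model@populations,
                               Ne = model@Ne, events = model@events),
                  dfe = list(shape = design$dfeShape,
                             meanNes = design$dfeMeanNes,
                             binMasses = gammaBinMasses(design$dfeShape,
                                                        design$dfeMeanNes)),
                  seed = seed)

    out <- list(genotypes = gm, records = records, AD = AD,
                annotation = ann, degeneracy = deg, teTable = teTable,
                model = model, truth = truth)
    if (!is.null(outDir)) {
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      .write_vcf(gm, records, AD, file.path(outDir, "sim.vcf"))
      .write_gff3(ann$genes, file.path(outDir, "genes.gff3"))
      utils::write.table(
        data.frame(ann$repeats$chrom, ann$repeats$start - 1L,
                   ann$repeats$end),
        file.path(outDir, "repeats.bed"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
      utils::write.table(
        data.frame(chrom = sites$chrom, pos = sites$pos,
                   ancestral = sites$ref),
        file.path(outDir, "ancestral.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      utils::write.table(teTable, file.path(outDir, "te_depth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                                  force = TRUE),
                 file.path(outDir, "truth.json"))
    }
    out
  })
}

# degeneracy classes of the toy annotation without needing a reference
# sequence: CDS codons cycle through a fixed codon list so classes are known
# by construction (positions are classified with the same codon table used by
# annotateDegeneracy)
.design_degeneracy <- function(design, ann) {
  tab <- .degeneracy_table()
  codons <- c("GGG", "ATG", "CTT", "AAA")  # mix of 4-fold, 0-fold, other
  out <- list()
  for (r in seq_len(nrow(ann$genes))) {
    g <- ann$genes[r, ]
    len <- g$cds_end - g$cds_start + 1
    ncod <- len %/% 3
    cyc <- rep_len(codons, ncod)
    cls <- as.vector(t(tab[cyc, , drop = FALSE]))
    pos5 <- g$cds_start:(g$cds_start + 3 * ncod - 1)
    if (g$strand == "-") cls <- rev(cls)
    out[[r]] <- data.frame(chrom = g$chrom, pos = pos5, class = cls,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

.design_te_table <- function(design, samples) {
  pops <- names(design$nInd)
  sf <- colnames(design$teEffects)
  rows <- list()
  for (r in seq_len(nrow(samples))) {
    pop <- samples$population[r]
    gdepth <- max(5, stats::rnorm(1, 18.9, 3.08))
    for (s in sf) {
      mu <- 1 + design$teEffects[pop, s]
      nd <- max(0, stats::rnorm(1, mu, design$teNoiseSd))
      rows[[length(rows) + 1]] <- data.frame(
        individual = samples$id[r], population = pop, superfamily = s,
        te_depth = nd * gdepth, genome_depth = gdepth,
        coverage = stats::runif(1, 0.85, 1), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Inject distance-decaying correlation between sites (LD fixture)
#'
#' Copy-with-mutation chaining along each chromosome: walking left to right,
#' each site's dosage column keeps the previous site's value per individual
#' with probability rho^(distance / blockBp), otherwise retains its own.
#' Produces approximately geometrically decaying genotype correlation for
#' testing LD-decay estimation and pruning; used in lieu of recombination,
#' which the coalescent simulator does not model.
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param blockBp decay length scale in bp
#' @param rho per-block correlation in [0, 1)
#' @param seed optional integer seed
#' @return a \linkS4class{GenotypeMatrix} with correlated columns
#' @export
generateBlockLD <- function(gm, blockBp = 1000, rho = 0.9, seed = NULL) {
  stopifnot(rho >= 0, rho < 1)
  .with_seed(seed, {
    cl <- calls(gm)
    sites <- siteInfo(gm)
    for (chrom in unique(sites$chrom)) {
      j <- which(sites$chrom == chrom)
      if (length(j) < 2) next
      for (k in 2:length(j)) {
        d <- sites$pos[j[k]] - sites$pos[j[k - 1]]
        p <- rho^(d / blockBp)
        copy <- stats::runif(nrow(cl)) < p
        cl[copy, j[k]] <- cl[copy, j[k - 1]]
      }
    }
    GenotypeMatrix(cl, sampleInfo(gm), sites)
  })
}
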