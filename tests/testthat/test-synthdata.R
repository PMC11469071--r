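# Synthetic-data generator: reproducibility, round-tripping through the
# package's own readers, and the statistical structure it promises.

# a reduced design that keeps the full generator fast in routine testing
small_design <- function(...) {
  studyDesign(
    nInd = c(`TR-D` = 6, `SK-D` = 6, `CH-D` = 6, `EN1-D` = 6, `EN6-M` = 6),
    Ne = c(8000, 5000, 3500, 2500, 600),
    splitGen = c(12000, 9000, 6000, 4000),
    founderNe = c(400, 300, 250, 120),
    F = c(0, 0, 0, 0, 0.9),
    nChrom = 4, chromLen = 60000, genesPerChrom = 3,
    ...)
}

test_that("identical seeds give identical datasets, different seeds differ", {
  d <- small_design()
  a <- generateDataset(d, seed = 5)
  b <- generateDataset(d, seed = 5)
  expect_identical(calls(a$genotypes), calls(b$genotypes))
  expect_identical(a$records, b$records)
  expect_identical(a$teTable, b$teTable)
  c <- generateDataset(d, seed = 6)
  expect_false(identical(calls(a$genotypes), calls(c$genotypes)))
})

test_that("every emitted file parses with the package's own readers", {
  d <- small_design()
  out <- tempfile()
  gen <- generateDataset(d, seed = 7, outDir = out)
  expect_true(all(file.exists(file.path(out,
    c("sim.vcf", "genes.gff3", "repeats.bed", "ancestral.tsv",
      "te_depth.tsv", "truth.json")))))
  back <- readVCFGenotypes(file.path(out, "sim.vcf"))
  expect_equal(dim(calls(back$genotypes)), dim(calls(gen$genotypes)))
  expect_equal(calls(back$genotypes), calls(gen$genotypes),
               ignore_attr = TRUE)
  expect_equal(back$records$QD, gen$records$QD, tolerance = 0.01)
  # GFF + mask machinery accepts the annotation
  chromLens <- setNames(rep(d$chromLen, d$nChrom),
                        paste0("chr", seq_len(d$nChrom)))
  mask <- buildNeutralMask(file.path(out, "genes.gff3"),
                           file.path(out, "repeats.bed"), chromLens)
  expect_true(any(mask$chr1))
  expect_false(all(mask$chr1))
  # genes plus 2 kb flanks are masked
  g1 <- gen$annotation$genes[1, ]
  expect_false(any(mask[[g1$chrom]][pmax(1, g1$start - 2000):g1$end]))
  # the ancestral table covers every VCF site
  anc <- read.table(file.path(out, "ancestral.tsv"), header = TRUE)
  expect_equal(nrow(anc), nSites(gen$genotypes))
  te <- read.table(file.path(out, "te_depth.tsv"), header = TRUE, sep = "\t",
                   check.names = FALSE)
  expect_equal(sort(unique(te$superfamily)),
               sort(colnames(gen$truth$teEffects)))
  truth <- jsonlite::read_json(file.path(out, "truth.json"))
  expect_equal(truth$dfe$shape, d$dfeShape)
})

test_that("diversity declines along the founder series and the selfing deme is homozygous", {
  d <- small_design()
  gen <- generateDataset(d, seed = 8)
  gm <- gen$genotypes
  pops <- names(d$nInd)
  piPerPop <- vapply(pops, function(p) {
    sub <- subsetGenotypes(gm, i = sampleInfo(gm)$population == p)
    sum(.pi_terms_for_test(calls(sub)))
  }, numeric(1))
  st <- spearmanTest(seq_along(pops), piPerPop)
  expect_lt(st$rho, 0)
  expect_gt(piPerPop[1], piPerPop[5])
  # selfing deme: observed heterozygosity far below the outcrossing core
  hetRate <- function(p) {
    sub <- calls(subsetGenotypes(gm, i = sampleInfo(gm)$population == p))
    poly <- colSums(sub, na.rm = TRUE) > 0
    if (!any(poly)) return(0)
    mean(sub[, poly, drop = FALSE] == 1L, na.rm = TRUE)
  }
  expect_lt(hetRate("EN6-M"), 0.35 * hetRate("TR-D"))
  # morph labels: monomorphic deme all H, dimorphic demes S/L only
  smp <- sampleInfo(gm)
  expect_true(all(smp$morph[smp$population == "EN6-M"] == "H"))
  expect_setequal(unique(smp$morph[smp$population == "TR-D"]), c("S", "L"))
  # truth record carries the generating demography for recovery scoring
  expect_equal(gen$truth$model$Ne, d$Ne)
  expect_equal(gen$truth$dfe$binMasses,
               gammaBinMasses(d$dfeShape, d$dfeMeanNes))
})

test_that("0-fold thinning suppresses diversity at selected sites", {
  d <- small_design(dfeMeanNes = 400)
  gen <- generateDataset(d, seed = 9)
  gm <- gen$genotypes
  deg <- gen$degeneracy
  key <- paste(siteInfo(gm)$chrom, siteInfo(gm)$pos)
  zf <- key %in% paste(deg$chrom, deg$pos)[deg$class == "zerofold"]
  ff <- key %in% paste(deg$chrom, deg$pos)[deg$class == "fourfold"]
  # variants per annotated position: thinning depresses the 0-fold rate well
  # below the 4-fold rate (the raw position counts differ by design, so the
  # comparison must be per position)
  z <- sum(deg$class == "zerofold"); f <- sum(deg$class == "fourfold")
  n0 <- sum(zf); n4 <- sum(ff)
  expect_gt(n4, 0)
  expect_lt((n0 / z) / (n4 / f), 0.8)
})

test_that("block-LD injection decays at the designed length scale", {
  set.seed(10)
  dos <- vapply(runif(120, 0.3, 0.7), function(f) rbinom(40, 2, f),
                numeric(40))
  gm <- make_gm(dos, pos = sort(sample(1:24000, 120)))
  g0 <- generateBlockLD(gm, blockBp = 1000, rho = 0, seed = 11)
  expect_identical(calls(g0), calls(gm))  # rho = 0 leaves data untouched
  gl <- generateBlockLD(gm, blockBp = 1000, rho = 0.9, seed = 12)
  curve <- ldDecayCurve(gl, maxDist = 8000, binWidth = 1000)
  ok <- curve$n_pairs > 20
  # fitted exponential decay length within a factor 2 of the block scale:
  # regress log(mean r2 above baseline) on distance
  base <- 1 / 40
  y <- pmax(curve$mean_r2[ok] - base, 1e-3)
  fitlm <- stats::lm(log(y) ~ curve$dist[ok])
  decayLen <- -1 / stats::coef(fitlm)[2]
  # designed r2 decay length: block / (2 ln(1/rho)) ~ 4.76 kb at rho = 0.9
  designed <- 1000 / (2 * log(1 / 0.9))
  expect_gt(decayLen, designed / 4)
  expect_lt(decayLen, designed * 4)
  # pruning removes at least one site per saturated block
  pruned <- ldPrune(gl, windowBp = 4000, stepBp = 2000, r2Max = 0.1)
  expect_lt(length(pruned), nSites(gl))
})
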