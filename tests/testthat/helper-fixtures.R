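# Shared fixture builders and independent oracles, all generated in code.

# quick GenotypeMatrix from a dosage matrix
make_gm <- function(dos, pops = NULL, chrom = "chr1", pos = NULL) {
  dos <- as.matrix(dos)
  n <- nrow(dos)
  if (is.null(pops)) pops <- rep("pop1", n)
  if (is.null(pos)) pos <- seq_len(ncol(dos)) * 100L
  GenotypeMatrix(
    dos,
    data.frame(id = paste0("ind", seq_len(n)), population = pops,
               stringsAsFactors = FALSE),
    data.frame(chrom = rep(chrom, ncol(dos)), pos = pos,
               ref = rep("A", ncol(dos)), alt = rep("T", ncol(dos)),
               stringsAsFactors = FALSE))
}

# hand-written small VCF fixture
write_toy_vcf <- function(path, lines_body,
                          samples = c("s1", "s2")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"qd\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, lines_body), path)
  path
}

# exhaustive-pass LD pruning oracle: repeatedly scan all windows and remove
# the later site of the worst-offending pair until no pair violates r2max
brute_ld_prune <- function(gm, windowBp, stepBp, r2Max) {
  cl <- calls(gm)
  pos <- siteInfo(gm)$pos
  keep <- rep(TRUE, ncol(cl))
  repeat {
    removed <- FALSE
    starts <- seq(min(pos), max(pos), by = stepBp)
    for (s in starts) {
      w <- which(keep & pos >= s & pos < s + windowBp)
      if (length(w) < 2) next
      for (x in seq_len(length(w) - 1)) {
        if (!keep[w[x]]) next
        for (y in (x + 1):length(w)) {
          if (!keep[w[y]]) next
          r2 <- ldR2(cl[, w[x]], cl[, w[y]])
          if (!is.na(r2) && r2 > r2Max) {
            keep[w[y]] <- FALSE
            removed <- TRUE
          }
        }
      }
    }
    if (!removed) break
  }
  which(keep)
}

# synthetic TE depth table with optional population x superfamily shifts
make_te_table <- function(nPerPop = 8, pops = c("TR-D", "SK-D", "CH-D"),
                          superfamilies = c("Mutator", "hAT", "LTR/Copia"),
                          effects = NULL, noise = 0.05, seed = 1) {
  set.seed(seed)
  if (is.null(effects))
    effects <- matrix(0, length(pops), length(superfamilies),
                      dimnames = list(pops, superfamilies))
  rows <- list()
  for (p in pops) for (i in seq_len(nPerPop)) {
    gd <- rnorm(1, 19, 3)
    for (s in superfamilies) {
      nd <- 1 + effects[p, s] + rnorm(1, 0, noise)
      rows[[length(rows) + 1]] <- data.frame(
        individual = paste0(p, "_", i), population = p, superfamily = s,
        te_depth = nd * gd, genome_depth = gd,
        coverage = runif(1, 0.85, 1), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# independent per-site pairwise-difference terms (oracle for pi)
.pi_terms_for_test <- function(cl) {
  apply(cl, 2, function(col) {
    col <- col[!is.na(col)]
    n <- 2 * length(col); c_alt <- sum(col)
    if (n < 2) return(0)
    2 * c_alt * (n - c_alt) / (n * (n - 1))
  })
}

# Wright-Fisher transition-matrix oracle for the expected selected SFS:
# expected sojourn generations at each population derived count for a new
# mutation under genic selection s against the derived allele, binomially
# subsampled to n haplotypes. Returns the normalized expected spectrum.
wf_selected_sfs <- function(gamma, n, N = 200) {
  twoN <- 2 * N
  s <- gamma / (4 * N)
  j <- seq_len(twoN - 1)
  x <- j / twoN
  xsel <- x * (1 - s) / (1 - s * x)  # deterministic selection, then drift
  # transition matrix over transient states 1..2N-1
  Q <- t(vapply(seq_along(j), function(r)
    stats::dbinom(j, twoN, xsel[r]), numeric(twoN - 1)))
  # expected visits to state j starting from count 1: row 1 of (I - Q)^-1
  v <- solve(t(diag(twoN - 1) - Q), as.numeric(seq_len(twoN - 1) == 1))
  xi <- vapply(seq_len(n - 1), function(i)
    sum(v * stats::dbinom(i, n, x)), numeric(1))
  xi / sum(xi)
}
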