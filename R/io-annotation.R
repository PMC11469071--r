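# Site-class annotation: codon degeneracy from GFF3 + FASTA, and the
# intergenic accessibility mask used for neutral-site selection.

.BASES <- c("A", "C", "G", "T")

# degeneracy class of each position of one codon under the standard code:
# "fourfold" if no substitution changes the amino acid, "zerofold" if every
# substitution does, otherwise "othercoding". Stop codons and codons with
# ambiguity codes are "othercoding" throughout.
.codon_degeneracy <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  b <- strsplit(codon, "")[[1]]
  if (length(b) != 3 || !all(b %in% .BASES)) return(rep("othercoding", 3))
  aa <- gc[[codon]]
  if (aa == "*") return(rep("othercoding", 3))
  out <- character(3)
  for (p in 1:3) {
    alts <- .BASES[.BASES != b[p]]
    aas <- vapply(alts, function(x) {
      bb <- b; bb[p] <- x; gc[[paste(bb, collapse = "")]]
    }, character(1))
    nsyn <- sum(aas == aa)
    out[p] <- if (nsyn == 3) "fourfold" else if (nsyn == 0) "zerofold"
              else "othercoding"
  }
  out
}

# cached lookup over all 64 codons
.degeneracy_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      codons <- apply(expand.grid(.BASES, .BASES, .BASES,
                                  stringsAsFactors = FALSE)[, 3:1], 1,
                      paste, collapse = "")
      tab <<- do.call(rbind, lapply(codons, .codon_degeneracy))
      rownames(tab) <<- codons
    }
    tab
  }
})

#' Annotate 0-fold and 4-fold degenerate coding positions
#'
#' Walks every CDS (grouped by transcript, ordered and phase-adjusted,
#' strand-aware) and classifies each genomic position as \code{"zerofold"}
#' (every substitution changes the amino acid), \code{"fourfold"} (none does)
#' or \code{"othercoding"}. Positions with conflicting classes across
#' overlapping transcripts become \code{"othercoding"}. Codons containing
#' ambiguity codes, stop codons, and trailing bases of CDSs whose
#' phase-adjusted length is not a multiple of 3 (warned) are
#' \code{"othercoding"}.
#'
#' @param gff GFF3 file path or a \code{GRanges} of CDS features (needs
#'   \code{type}, \code{phase} and a transcript grouping column \code{Parent}
#'   or \code{ID})
#' @param fasta reference FASTA path or a named \code{DNAStringSet}
#' @return data.frame with \code{chrom}, \code{pos} (1-based) and
#'   \code{class}, one row per annotated CDS base
#' @export
annotateDegeneracy <- function(gff, fasta) {
  gr <- if (is.character(gff)) rtracklayer::import(gff) else gff
  gr <- gr[gr$type == "CDS"]
  if (!length(gr)) stop("no CDS features in annotation")
  seqs <- if (is.character(fasta)) Biostrings::readDNAStringSet(fasta)
          else fasta
  names(seqs) <- sub("\\s.*", "", names(seqs))
  grp <- if (!is.null(gr$Parent) && any(lengths(gr$Parent) > 0))
    vapply(as.list(gr$Parent), function(x)
      if (length(x)) x[[1]] else NA_character_, character(1))
  else as.character(gr$ID)
  grp[is.na(grp)] <- "orphan"
  tab <- .degeneracy_table()
  res <- new.env()
  assign_class <- function(chrom, pos, cls) {
    key <- paste0(chrom, ":", pos)
    for (k in seq_along(key)) {
      prev <- res[[key[k]]]
      res[[key[k]]] <- if (is.null(prev) || prev == cls[k]) cls[k]
                       else "othercoding"
    }
  }
  for (tx in unique(grp)) {
    parts <- gr[grp == tx]
    strand <- as.character(BiocGenerics::strand(parts))[1]
    ord <- order(BiocGenerics::start(parts),
                 decreasing = (strand == "-"))
    parts <- parts[ord]
    chrom <- as.character(GenomicRanges::seqnames(parts))[1]
    if (!chrom %in% names(seqs)) next
    # genomic positions in translation order
    posList <- lapply(seq_along(parts), function(i) {
      p <- BiocGenerics::start(parts)[i]:BiocGenerics::end(parts)[i]
      if (strand == "-") rev(p) else p
    })
    pos <- unlist(posList)
    phase <- suppressWarnings(as.integer(as.character(parts$phase[1])))
    if (is.na(phase)) phase <- 0L
    if (phase > 0) pos <- pos[-seq_len(phase)]
    chromSeq <- strsplit(as.character(seqs[[chrom]]), "")[[1]]
    bases <- chromSeq[pos]
    if (strand == "-")
      bases <- c(A = "T", C = "G", G = "C", T = "A", N = "N")[bases]
    ncodon <- length(pos) %/% 3
    trailing <- length(pos) - 3 * ncodon
    if (trailing > 0) {
      warning(sprintf("CDS %s length not divisible by 3; %d trailing base(s) set other-coding",
                      tx, trailing))
      assign_class(chrom, pos[(3 * ncodon + 1):length(pos)],
                   rep("othercoding", trailing))
    }
    if (ncodon > 0) {
      idx <- seq_len(3 * ncodon)
      codons <- paste0(bases[idx][c(TRUE, FALSE, FALSE)],
                       bases[idx][c(FALSE, TRUE, FALSE)],
                       bases[idx][c(FALSE, FALSE, TRUE)])
      known <- codons %in% rownames(tab)
      cls <- matrix("othercoding", nrow = ncodon, ncol = 3)
      cls[known, ] <- tab[codons[known], , drop = FALSE]
      assign_class(chrom, pos[idx], as.vector(t(cls)))
    }
  }
  keys <- ls(res)
  if (!length(keys))
    return(data.frame(chrom = character(), pos = integer(),
                      class = character(), stringsAsFactors = FALSE))
  sp <- strsplit(keys, ":")
  out <- data.frame(
    chrom = vapply(sp, `[`, character(1), 1),
    pos = as.integer(vapply(sp, `[`, character(1), 2)),
    class = vapply(keys, function(k) res[[k]], character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Build the neutral-site accessibility mask
#'
#' Marks as inaccessible every position inside a gene (introns and exons),
#' within \code{flank} bp up- or downstream of a gene, or inside a
#' repeat/centromere interval; everything else is accessible. Intervals
#' extending past a chromosome end are clipped with a warning.
#'
#' @param genes GFF3 path or \code{GRanges}; features of type \code{"gene"}
#'   are used (all features if no type column). \code{NULL} for none.
#' @param repeats BED path (0-based half-open) or \code{GRanges} of repeat and
#'   centromeric intervals. \code{NULL} for none.
#' @param chromLengths named integer vector of chromosome lengths
#' @param flank flank width in bp masked around each gene
#' @return named list of logical vectors (TRUE = accessible), one per
#'   chromosome, of class \code{"AccessibilityMask"}
#' @export
buildNeutralMask <- function(genes, repeats, chromLengths, flank = 2000) {
  asGR <- function(x) {
    if (is.null(x)) return(GenomicRanges::GRanges())
    if (is.character(x)) x <- rtracklayer::import(x)
    x
  }
  g <- asGR(genes)
  if (length(g) && !is.null(g$type) && any(g$type == "gene"))
    g <- g[g$type == "gene"]
  if (length(g))
    g <- GenomicRanges::resize(g, BiocGenerics::width(g) + 2 * flank,
                               fix = "center")
  r <- asGR(repeats)
  masked <- suppressWarnings(GenomicRanges::reduce(c(
    GenomicRanges::granges(g), GenomicRanges::granges(r))))
  out <- lapply(names(chromLengths), function(chrom) {
    len <- chromLengths[[chrom]]
    acc <- rep(TRUE, len)
    mi <- masked[as.character(GenomicRanges::seqnames(masked)) == chrom]
    if (length(mi)) {
      s <- pmax(1L, BiocGenerics::start(mi))  # flanks may extend past the
      e <- BiocGenerics::end(mi)              # left edge; clip silently
      if (any(e > len)) {
        warning("interval beyond chromosome length clipped on ", chrom)
        e <- pmin(e, len)
      }
      for (k in seq_along(s)) if (s[k] <= e[k]) acc[s[k]:e[k]] <- FALSE
    }
    acc
  })
  names(out) <- names(chromLengths)
  class(out) <- "AccessibilityMask"
  out
}
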