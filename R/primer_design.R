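# Degenerate primer design: conserved-motif discovery in a protein alignment
# and back-translation into minimal-cover IUPAC oligos.

# codon lists per amino acid, from the standard genetic code
.CODONS_OF <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

.alnCharMatrix <- function(aln) {
  s <- .asCharSeqs(aln)
  if (length(s) < 2L) stop("alignment must have at least 2 rows")
  w <- nchar(s)
  if (length(unique(w)) != 1L) stop("alignment rows must have equal length")
  do.call(rbind, strsplit(s, ""))
}

#' Find conserved amino-acid motifs in a protein alignment
#'
#' Scans every window of \code{windowLen} alignment columns and keeps those
#' in which each column is gap-free and shows at most \code{maxVariants}
#' distinct residues. These are the candidate primer-design motifs.
#'
#' @param aln Protein alignment: equal-length \code{AAStringSet} or named
#'   character vector (gaps as \code{-}).
#' @param windowLen Motif length in amino acids (>= 5).
#' @param maxVariants Maximum distinct residues tolerated per column.
#' @return A list of motifs; each has \code{startCol} (0-based alignment
#'   column) and \code{residues} (a list of per-column residue sets), sorted
#'   by start column.
#' @export
findConservedMotifs <- function(aln, windowLen = 7L, maxVariants = 1L) {
  if (windowLen < 5L) stop("'windowLen' must be >= 5")
  if (maxVariants < 1L) stop("'maxVariants' must be >= 1")
  m <- .alnCharMatrix(aln)
  ncols <- ncol(m)
  if (windowLen > ncols) stop("'windowLen' exceeds the number of alignment columns")
  colSets <- lapply(seq_len(ncols), function(j) unique(m[, j]))
  ok <- vapply(colSets, function(s) !("-" %in% s) && length(s) <= maxVariants,
               logical(1))
  out <- list()
  for (s in 0:(ncols - windowLen)) {
    if (all(ok[(s + 1):(s + windowLen)])) {
      out[[length(out) + 1L]] <- list(
        startCol = s,
        residues = colSets[(s + 1):(s + windowLen)])
    }
  }
  out
}

#' Back-translate a conserved motif into a degenerate nucleotide sequence
#'
#' For each amino-acid column the codons of every residue present are pooled
#' and each codon position is encoded as the minimal IUPAC code covering the
#' pooled bases. The result covers all codings of the motif (possibly more:
#' IUPAC over-coverage is one-sided, e.g. L gives \code{YTN} which expands to
#' 8 codons of which 6 encode leucine).
#'
#' @param motif A motif from \code{\link{findConservedMotifs}}, a plain
#'   amino-acid string, or a list of per-column residue sets.
#' @return IUPAC nucleotide string of length 3 x motif length.
#' @examples
#' backTranslate("MK")  # "ATGAAR"
#' backTranslate("L")   # "YTN"
#' @export
backTranslate <- function(motif) {
  cols <- if (is.list(motif) && !is.null(motif$residues)) motif$residues
          else if (is.character(motif) && length(motif) == 1L)
            as.list(strsplit(motif, "")[[1]])
          else if (is.list(motif)) motif
          else stop("unrecognized motif representation")
  out <- vapply(cols, function(res) {
    res <- unique(toupper(res))
    if (any(res == "-")) stop("motif columns must be gap-free")
    bad <- setdiff(res, .AA_LETTERS)
    if (length(bad))
      stop("residue with no codon in back-translation: ",
           paste(bad, collapse = ", "))
    codons <- unlist(.CODONS_OF[res], use.names = FALSE)
    cm <- do.call(rbind, strsplit(codons, ""))
    paste(vapply(1:3, function(p) iupacCode(cm[, p]), character(1)),
          collapse = "")
  }, character(1))
  paste(out, collapse = "")
}

#' Degeneracy of an IUPAC sequence
#'
#' The number of distinct unambiguous expansions: the product over positions
#' of the base-set sizes.
#'
#' @param iupacSeq IUPAC nucleotide string.
#' @return Numeric degeneracy (>= 1).
#' @examples
#' degeneracyOf("ATGAAR")  # 2
#' degeneracyOf("YTN")     # 8
#' @export
degeneracyOf <- function(iupacSeq) {
  if (length(iupacSeq) != 1L || !nzchar(iupacSeq))
    stop("'iupacSeq' must be a single nonempty string")
  ch <- strsplit(toupper(iupacSeq), "")[[1]]
  .checkNt(paste(ch, collapse = ""), what = "primer")
  prod(nchar(.IUPAC[ch]))
}

# mean Wallace-rule melting temperature over the expansions of an IUPAC primer:
# 2(A+T) + 4(G+C), averaged by expected base composition per position
.wallaceTm <- function(iupacSeq) {
  ch <- strsplit(toupper(iupacSeq), "")[[1]]
  sum(vapply(ch, function(c) {
    b <- expandIupac(c)
    mean(ifelse(b %in% c("G", "C"), 4, 2))
  }, numeric(1)))
}

#' Design degenerate primer pairs flanking a hypervariable region
#'
#' Enumerates all conserved motifs ending before / starting after the
#' designated hypervariable column interval, back-translates them, and keeps
#' pairs whose degeneracies and expected insert length satisfy the
#' constraints. Pairs are ranked by the product of the two degeneracies
#' (ascending), then by smaller expected insert, then by leftmost forward
#' motif. Reverse primers are reverse-complemented, ready to synthesize.
#'
#' @param aln Protein alignment of the design references.
#' @param hypervariable 0-based half-open alignment-column interval of the
#'   hypervariable region the insert must span.
#' @param windowLen Motif length in amino acids (default 7, i.e. 21-nt primers).
#' @param maxVariants Maximum residues per motif column (default 1).
#' @param maxDegeneracy Maximum degeneracy per primer (default 512).
#' @param insertLenRange Allowed expected trimmed-insert length in nt.
#' @return List of \linkS4class{PrimerPair}; if empty, the
#'   \code{"diagnostics"} attribute tabulates which constraint failed most.
#' @export
designPrimerPairs <- function(aln, hypervariable, windowLen = 7L,
                              maxVariants = 1L, maxDegeneracy = 512,
                              insertLenRange = c(60L, 600L)) {
  m <- .alnCharMatrix(aln)
  ncols <- ncol(m)
  hv <- as.integer(hypervariable)
  if (length(hv) != 2L || hv[1] < 0L || hv[2] > ncols || hv[1] >= hv[2])
    stop("'hypervariable' must be a 0-based half-open interval within the alignment")
  motifs <- findConservedMotifs(aln, windowLen, maxVariants)
  starts <- vapply(motifs, `[[`, numeric(1), "startCol")
  fwdIdx <- which(starts + windowLen <= hv[1])
  revIdx <- which(starts >= hv[2])
  gapFree <- vapply(seq_len(ncols), function(j) all(m[, j] != "-"), logical(1))

  fails <- c(no_forward_motif = 0, no_reverse_motif = 0,
             degeneracy = 0, insert_length = 0)
  if (!length(fwdIdx)) fails["no_forward_motif"] <- 1
  if (!length(revIdx)) fails["no_reverse_motif"] <- 1

  pairs <- list()
  key <- NULL
  for (fi in fwdIdx) {
    fm <- motifs[[fi]]
    fSeq <- backTranslate(fm)
    fDeg <- degeneracyOf(fSeq)
    if (fDeg > maxDegeneracy) { fails["degeneracy"] <- fails["degeneracy"] + length(revIdx); next }
    for (ri in revIdx) {
      rm_ <- motifs[[ri]]
      rSeqPlus <- backTranslate(rm_)
      rDeg <- degeneracyOf(rSeqPlus)
      if (rDeg > maxDegeneracy) { fails["degeneracy"] <- fails["degeneracy"] + 1; next }
      insCols <- c(fm$startCol + windowLen, rm_$startCol)
      span <- if (insCols[2] > insCols[1])
        sum(gapFree[(insCols[1] + 1):insCols[2]]) else 0L
      insLen <- 3L * span
      if (insLen < insertLenRange[1] || insLen > insertLenRange[2]) {
        fails["insert_length"] <- fails["insert_length"] + 1; next
      }
      fwd <- new("DegeneratePrimer", iupacSeq = fSeq, degeneracy = fDeg,
                 orientation = "forward",
                 motifStartCol = as.integer(fm$startCol),
                 motifLength = as.integer(windowLen))
      rev <- new("DegeneratePrimer", iupacSeq = revComp(rSeqPlus),
                 degeneracy = rDeg, orientation = "reverse",
                 motifStartCol = as.integer(rm_$startCol),
                 motifLength = as.integer(windowLen))
      pairs[[length(pairs) + 1L]] <- new("PrimerPair", forward = fwd,
                                         reverse = rev,
                                         insertCols = as.integer(insCols),
                                         expectedInsertLenNt = insLen)
      key <- rbind(key, c(fDeg * rDeg, insLen, fm$startCol))
    }
  }
  if (!length(pairs)) {
    warning("no primer pair satisfied the constraints; see attr(,'diagnostics')")
    return(structure(list(), diagnostics = fails))
  }
  ord <- order(key[, 1], key[, 2], key[, 3])
  pairs[ord]
}

#' Export designed primers as a TSV-ready data.frame
#'
#' @param pairs List of \linkS4class{PrimerPair}.
#' @return data.frame with one row per primer (id, orientation, IUPAC
#'   sequence, degeneracy, motif columns, mean Wallace-rule Tm).
#' @export
primerTable <- function(pairs) {
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    do.call(rbind, lapply(list(p@forward, p@reverse), function(pr) {
      data.frame(pair = i,
                 id = sprintf("pair%02d_%s", i, substr(pr@orientation, 1, 3)),
                 orientation = pr@orientation, iupac_seq = pr@iupacSeq,
                 degeneracy = pr@degeneracy,
                 motif_start_col = pr@motifStartCol,
                 motif_end_col = pr@motifStartCol + pr@motifLength,
                 mean_tm = .wallaceTm(pr@iupacSeq),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
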