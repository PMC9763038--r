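# Independent brute-force oracles and small generators used across the
# suite. These deliberately re-derive results by exhaustive enumeration,
# never by calling the implementation under test.

NT <- c("A", "C", "G", "T")

randNt <- function(n) paste(sample(NT, n, replace = TRUE), collapse = "")

randAa <- function(n) paste(sample(c("A","R","N","D","C","Q","E","G","H","I",
                                     "L","K","M","F","P","S","T","W","Y","V"),
                                   n, replace = TRUE), collapse = "")

IUPAC_MAP <- Biostrings::IUPAC_CODE_MAP

# expand an IUPAC string to all unambiguous strings (small degeneracy only)
expandAll <- function(s) {
  sets <- strsplit(IUPAC_MAP[strsplit(s, "")[[1]]], "")
  out <- ""
  for (st in sets) out <- as.vector(outer(out, st, paste0))
  out
}

# positionwise IUPAC membership mismatch count
oracleMismatches <- function(primer, window) {
  pc <- strsplit(primer, "")[[1]]
  wc <- strsplit(window, "")[[1]]
  sum(vapply(seq_along(pc),
             function(i) !wc[i] %in% strsplit(IUPAC_MAP[[pc[i]]], "")[[1]],
             logical(1)))
}

# O(nm) all-window, both-strand scan
oracleBindingSites <- function(template, primer, maxMismatch) {
  L <- nchar(template); m <- nchar(primer)
  rcP <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(primer)))
  rows <- list()
  if (m <= L) for (s in 0:(L - m)) {
    w <- substr(template, s + 1, s + m)
    mmP <- oracleMismatches(primer, w)
    if (mmP <= maxMismatch)
      rows[[length(rows) + 1]] <- data.frame(start = s, strand = "+",
                                             mismatches = mmP)
    mmM <- oracleMismatches(rcP, w)
    if (mmM <= maxMismatch)
      rows[[length(rows) + 1]] <- data.frame(start = s, strand = "-",
                                             mismatches = mmM)
  }
  if (!length(rows))
    return(data.frame(start = integer(0), strand = character(0),
                      mismatches = integer(0)))
  d <- do.call(rbind, rows)
  d <- d[order(d$start, d$strand), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# vectorized variant of the same all-window scan (one strand), for the
# large randomized comparisons: mismatches per window from direct IUPAC
# set membership
oracleScanStrand <- function(template, primer) {
  tch <- strsplit(template, "")[[1]]
  pch <- strsplit(primer, "")[[1]]
  L <- length(tch); m <- length(pch)
  if (m > L) return(integer(0))
  nw <- L - m + 1
  mm <- integer(nw)
  for (i in seq_len(m)) {
    set_i <- strsplit(IUPAC_MAP[[pch[i]]], "")[[1]]
    mm <- mm + !(tch[i:(i + nw - 1)] %in% set_i)
  }
  mm
}

oracleBindingSitesFast <- function(template, primer, maxMismatch) {
  rcP <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(primer)))
  mmP <- oracleScanStrand(template, primer)
  mmM <- oracleScanStrand(template, rcP)
  sP <- which(mmP <= maxMismatch); sM <- which(mmM <= maxMismatch)
  d <- rbind(
    data.frame(start = sP - 1L, strand = rep("+", length(sP)),
               mismatches = mmP[sP]),
    data.frame(start = sM - 1L, strand = rep("-", length(sM)),
               mismatches = mmM[sM]))
  d <- d[order(d$start, d$strand), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# site-pair enumeration oracle for amplify(): inserts only, both senses
oracleAmplify <- function(template, fwdSeq, revSeq, maxMismatch, lenRange) {
  fS <- oracleBindingSites(template, fwdSeq, maxMismatch)
  rS <- oracleBindingSites(template, revSeq, maxMismatch)
  lf <- nchar(fwdSeq); lr <- nchar(revSeq)
  ins <- character(0)
  fP <- fS[fS$strand == "+", , drop = FALSE]
  rM <- rS[rS$strand == "-", , drop = FALSE]
  for (a in fP$start) for (b in rM$start) {
    if (b >= a + lf) {
      x <- substr(template, a + lf + 1, b)
      if (nchar(x) >= lenRange[1] && nchar(x) <= lenRange[2]) ins <- c(ins, x)
    }
  }
  fM <- fS[fS$strand == "-", , drop = FALSE]
  rP <- rS[rS$strand == "+", , drop = FALSE]
  for (a in fM$start) for (b in rP$start) {
    if (b + lr <= a) {
      x <- substr(template, b + lr + 1, a)
      if (nchar(x) >= lenRange[1] && nchar(x) <= lenRange[2])
        ins <- c(ins, as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(x))))
    }
  }
  sort(ins)
}

# minimal IUPAC cover of a motif's codon union, by direct enumeration
IUPAC_BY_BASESET <- local({
  key <- vapply(strsplit(IUPAC_MAP, ""),
                function(b) paste(sort(b), collapse = ""), character(1))
  stats::setNames(names(IUPAC_MAP), key)
})

oracleBackTranslate <- function(motifAa) {
  gc <- Biostrings::GENETIC_CODE
  cols <- strsplit(motifAa, "")[[1]]
  paste(vapply(cols, function(res) {
    codons <- names(gc)[gc == res]
    cm <- do.call(rbind, strsplit(codons, ""))
    paste(vapply(1:3, function(p) {
      IUPAC_BY_BASESET[[paste(sort(unique(cm[, p])), collapse = "")]]
    }, character(1)), collapse = "")
  }, character(1)), collapse = "")
}

# exhaustive global-alignment oracle: returns the optimal score and the set
# of (matches, columns) pairs achieved by optimal alignments (match +1,
# mismatch 0, gap -1)
oracleGlobalAlign <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  res <- new.env()
  res$best <- -Inf; res$stats <- list()
  recur <- function(i, j, score, matches, cols) {
    if (i > length(x) && j > length(y)) {
      if (score > res$best) { res$best <- score; res$stats <- list() }
      if (score == res$best)
        res$stats[[length(res$stats) + 1]] <- c(matches, cols)
      return(invisible())
    }
    if (i <= length(x) && j <= length(y))
      recur(i + 1, j + 1, score + (x[i] == y[j]), matches + (x[i] == y[j]),
            cols + 1)
    if (i <= length(x)) recur(i + 1, j, score - 1, matches, cols + 1)
    if (j <= length(y)) recur(i, j + 1, score - 1, matches, cols + 1)
  }
  recur(1, 1, 0, 0, 0)
  list(score = res$best,
       identities = unique(vapply(res$stats,
                                  function(s) 100 * s[1] / s[2], numeric(1))))
}

# random tree with strictly positive branch lengths and its additive
# distance matrix
randAdditive <- function(nLeaves) {
  tr <- ape::rtree(nLeaves, br = function(n) runif(n, 0.1, 1))
  D <- ape::cophenetic.phylo(tr)
  labs <- sort(rownames(D))
  list(tree = tr, D = D[labs, labs])
}

# tiny deterministic community for pipeline smoke tests
smallSim <- function(seed = 7, readsPerLayer = 1500L, errorRate = 1e-3,
                     ...) {
  cfg <- simulationConfig(seed = seed, readsPerLayer = readsPerLayer,
                          errorRate = errorRate,
                          nStrains = c(hcrnav = 6L, related = 6L,
                                       background = 3L),
                          hcUaStrains = 4L, ...)
  sim <- generateReferencePanel(cfg)
  pair <- plantedPrimerPair(sim)
  list(cfg = cfg, sim = sim, pair = pair,
       cp = classificationPanel(sim, pair))
}
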