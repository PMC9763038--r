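# Conserved-motif discovery, back-translation and primer-pair design.

test_that("fully conserved alignments yield every window", {
  aln <- setNames(rep("MKLFWHDENR", 3), paste0("s", 1:3))
  m <- findConservedMotifs(aln, windowLen = 6, maxVariants = 1)
  expect_length(m, 10 - 6 + 1)
  expect_equal(vapply(m, `[[`, numeric(1), "startCol"), 0:4)
})

test_that("a 2-residue column excludes covering windows at maxVariants = 1", {
  aln <- c(a = "MKLFWHDENR", b = "MKLFWHDENR", c = "MKLSWHDENR")  # col 3 varies
  m1 <- findConservedMotifs(aln, windowLen = 5, maxVariants = 1)
  expect_equal(vapply(m1, `[[`, numeric(1), "startCol"), c(4, 5))
  m2 <- findConservedMotifs(aln, windowLen = 5, maxVariants = 2)
  expect_length(m2, 6)
})

test_that("motif discovery equals a brute-force window scan", {
  set.seed(11)
  for (rep_ in 1:10) {
    rows <- vapply(1:4, function(i) randAa(25), character(1))
    # inject shared conserved stretch and some gaps
    for (i in 2:4) substr(rows[i], 8, 15) <- substr(rows[1], 8, 15)
    substr(rows[2], 3, 3) <- "-"
    names(rows) <- paste0("r", 1:4)
    w <- 6; mv <- 2
    got <- vapply(findConservedMotifs(rows, w, mv), `[[`, numeric(1),
                  "startCol")
    m <- do.call(rbind, strsplit(rows, ""))
    okCol <- vapply(1:25, function(j) {
      u <- unique(m[, j]); !("-" %in% u) && length(u) <= mv
    }, logical(1))
    want <- (0:(25 - w))[vapply(0:(25 - w), function(s)
      all(okCol[(s + 1):(s + w)]), logical(1))]
    expect_equal(got, want)
  }
})

test_that("back-translation produces the minimal IUPAC cover", {
  expect_equal(backTranslate("MK"), "ATGAAR")
  expect_equal(backTranslate("FW"), "TTYTGG")
  expect_equal(backTranslate("L"), "YTN")
  expect_error(backTranslate("M*"), "no codon")
  # all 20 amino acids against the enumeration oracle
  for (aa in c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
               "S","T","W","Y","V"))
    expect_equal(backTranslate(aa), oracleBackTranslate(aa))
  set.seed(3)
  for (i in 1:40) {
    motif <- randAa(sample(2:8, 1))
    expect_equal(backTranslate(motif), oracleBackTranslate(motif))
  }
})

test_that("back-translation over-coverage is one-sided", {
  set.seed(5)
  gc <- Biostrings::GENETIC_CODE
  for (i in 1:15) {
    motif <- randAa(3)
    bt <- backTranslate(motif)
    exps <- expandAll(bt)
    # every true coding of the motif is covered
    cod <- lapply(strsplit(motif, "")[[1]], function(r) names(gc)[gc == r])
    truths <- apply(expand.grid(cod, stringsAsFactors = FALSE), 1, paste,
                    collapse = "")
    expect_true(all(truths %in% exps))
    expect_gte(degeneracyOf(bt), length(truths))
  }
})

test_that("degeneracy is the per-position product", {
  expect_equal(degeneracyOf("ATG"), 1)
  expect_equal(degeneracyOf("ATGAAR"), 2)
  expect_equal(degeneracyOf("YTN"), 8)
  expect_error(degeneracyOf("AXT"))
  set.seed(8)
  for (i in 1:20) {
    s <- paste(sample(names(IUPAC_MAP), 8, replace = TRUE), collapse = "")
    expect_equal(degeneracyOf(s), length(expandAll(s)))
  }
})

test_that("pair design flanks the hypervariable block and honors constraints", {
  flank1 <- "MKHWDEF"; flank2 <- "NQCWHKY"
  rows <- setNames(c(paste0(flank1, "AAAAA", flank2),
                     paste0(flank1, "RRRRR", flank2),
                     paste0(flank1, "DDDDD", flank2)), paste0("s", 1:3))
  pairs <- designPrimerPairs(rows, hypervariable = c(7, 12), windowLen = 7,
                             insertLenRange = c(1, 100))
  expect_length(pairs, 1)
  p <- pairs[[1]]
  expect_equal(p@forward@iupacSeq, backTranslate(flank1))
  expect_equal(p@reverse@iupacSeq, revComp(backTranslate(flank2)))
  expect_equal(p@expectedInsertLenNt, 15L)
  # leucine-bearing flank excluded at maxDegeneracy 1
  rowsL <- setNames(c(paste0("MWMWMWM", "AAAAA", "LMWMWMW")), "s1")
  rowsL <- c(rowsL, s2 = rowsL[[1]], s3 = rowsL[[1]])
  suppressWarnings({
    none <- designPrimerPairs(rowsL, hypervariable = c(7, 12), windowLen = 7,
                              maxDegeneracy = 1, insertLenRange = c(1, 100))
  })
  expect_length(none, 0)
  expect_true(!is.null(attr(none, "diagnostics")))
})

test_that("designed primers cover their own panel and ignore row order", {
  s <- smallSim()
  pairs <- designPrimerPairs(s$sim$designAlignment,
                             hypervariable = s$sim$geometry$window)
  expect_gt(length(pairs), 0)
  aln <- as.character(s$sim$designAlignment)
  genes <- s$sim$refGenes
  pad <- s$cfg$padNt
  for (p in pairs[seq_len(min(3, length(pairs)))]) {
    for (g in genes) {
      fs <- p@forward@motifStartCol
      win <- substr(g, pad + 3 * fs + 1, pad + 3 * (fs + p@forward@motifLength))
      expect_equal(iupacMismatches(p@forward@iupacSeq, win), 0)
      rs <- p@reverse@motifStartCol
      winR <- substr(g, pad + 3 * rs + 1, pad + 3 * (rs + p@reverse@motifLength))
      expect_equal(iupacMismatches(revComp(p@reverse@iupacSeq), winR), 0)
    }
  }
  perm <- sample(length(aln))
  pairsPerm <- designPrimerPairs(aln[perm],
                                 hypervariable = s$sim$geometry$window)
  expect_equal(lapply(pairsPerm, function(p) p@forward@iupacSeq),
               lapply(pairs, function(p) p@forward@iupacSeq))
  expect_equal(lapply(pairsPerm, function(p) p@reverse@iupacSeq),
               lapply(pairs, function(p) p@reverse@iupacSeq))
})
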