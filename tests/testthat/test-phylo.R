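# p-distances, neighbor joining (checked against closed forms, additivity
# and ape's independent implementation), bootstrap supports and host-range
# typing.

test_that("p-distances count mismatches over comparable columns", {
  aln <- c(a = "AAAA", b = "AAAT", c = "TTTT")
  D <- pDistanceMatrix(aln)
  expect_equal(D["a", "b"], 0.25)
  expect_equal(D["a", "c"], 1)
  expect_equal(diag(D), c(a = 0, b = 0, c = 0))
  # gapped pair: only gap-free columns compared
  g <- c(a = "A-CD", b = "AAC-", c = "AACD")
  Dg <- pDistanceMatrix(g)
  expect_equal(Dg["a", "b"], 0)      # columns 1 and 3 compared
  expect_error(pDistanceMatrix(c(a = "A--A", b = "-AA-", c = "AAAA")),
               "comparable")
  expect_error(pDistanceMatrix(c(a = "AA", b = "AAA", c = "AAAA")))
})

test_that("three-taxon closed form is exact", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighborJoining(D)
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(el[["A"]], 0.5)
  expect_equal(el[["B"]], 1.5)
  expect_equal(el[["C"]], 2.5)
})

test_that("NJ recovers random additive trees exactly (topology and lengths)", {
  skip_if_not_installed("phangorn")
  set.seed(101)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    ra <- randAdditive(n)
    tr <- neighborJoining(ra$D)
    expect_equal(phangorn::RF.dist(ape::unroot(ra$tree), tr), 0)
    co <- ape::cophenetic.phylo(tr)[rownames(ra$D), rownames(ra$D)]
    expect_lt(max(abs(co - ra$D)), 1e-9)
  }
})

test_that("NJ agrees with ape's independent implementation on additive input", {
  skip_if_not_installed("phangorn")
  set.seed(202)
  for (i in 1:10) {
    ra <- randAdditive(7)
    expect_equal(phangorn::RF.dist(neighborJoining(ra$D), ape::nj(ra$D)), 0)
  }
})

test_that("tie-breaking is deterministic on an equidistant matrix", {
  L <- c("a", "b", "c", "d")
  D <- matrix(1, 4, 4, dimnames = list(L, L)); diag(D) <- 0
  t1 <- neighborJoining(D)
  t2 <- neighborJoining(D)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  # the lexicographically smallest pair (a, b) is joined first
  expect_true(ape::is.monophyletic(ape::root(t1, "d"), c("a", "b")))
})

test_that("total tree length is invariant to label permutation", {
  set.seed(303)
  ra <- randAdditive(6)
  perm <- sample(6)
  Dp <- ra$D[perm, perm]
  expect_equal(sum(neighborJoining(Dp)$edge.length),
               sum(neighborJoining(ra$D)$edge.length))
})

test_that("negative branch estimates are clamped and logged", {
  # a non-additive matrix known to produce a negative NJ estimate
  L <- c("a", "b", "c", "d")
  D <- matrix(c(0, 1, 6, 6,
                1, 0, 6, 6,
                6, 6, 0, 1,
                6, 6, 1, 0), 4, dimnames = list(L, L))
  D["a", "c"] <- D["c", "a"] <- 2   # break additivity hard
  tr <- neighborJoining(D)
  expect_true(all(tr$edge.length >= 0))
})

.splitLeaves <- function(tree) {
  pp <- ape::prop.part(tree)
  lapply(pp, function(cl) sort(attr(pp, "labels")[cl]))
}

test_that("bootstrap supports are deterministic and saturate on a clean split", {
  set.seed(17)
  # two 4-leaf clades separated by 30 diagnostic columns
  blockA <- paste(rep("A", 30), collapse = "")
  blockB <- paste(rep("S", 30), collapse = "")
  noise <- function() randAa(10)
  aln <- c(
    setNames(vapply(1:4, function(i) paste0(blockA, noise()), character(1)),
             paste0("x", 1:4)),
    setNames(vapply(1:4, function(i) paste0(blockB, noise()), character(1)),
             paste0("y", 1:4)))
  tr1 <- bootstrapSupport(aln, nReplicates = 200, seed = 99)
  tr2 <- bootstrapSupport(aln, nReplicates = 200, seed = 99)
  expect_identical(attr(tr1, "supports"), attr(tr2, "supports"))
  expect_identical(ape::write.tree(tr1), ape::write.tree(tr2))
  # the x/y split must have support 100
  sup <- attr(tr1, "supports")
  splitKey <- paste(sort(paste0("y", 1:4)), collapse = "\r")
  expect_true(splitKey %in% names(sup))
  expect_equal(unname(sup[splitKey]), 100)
})

test_that("single-replicate supports are 0 or 100", {
  set.seed(23)
  aln <- setNames(vapply(1:5, function(i) randAa(40), character(1)),
                  paste0("t", 1:5))
  tr <- bootstrapSupport(aln, nReplicates = 1, seed = 5)
  expect_true(all(attr(tr, "supports") %in% c(0, 100)))
})

test_that("support masking blanks values at or below the cutoff", {
  set.seed(29)
  aln <- setNames(vapply(1:6, function(i) randAa(30), character(1)),
                  paste0("t", 1:6))
  tr <- bootstrapSupport(aln, nReplicates = 50, seed = 3)
  masked <- maskSupports(tr, 50)
  num <- suppressWarnings(as.numeric(masked$node.label))
  expect_true(all(is.na(num) | num > 50))
})

test_that("host-range typing follows identity, threshold and clade membership", {
  s <- smallSim()
  panel <- s$cp$panel
  refs <- panelSequences(panel)
  # a variant identical to the CY reference types CY
  cyRef <- refs[[which(panelTypes(panel) == "CY")[1]]]
  cyAcc <- names(refs)[which(panelTypes(panel) == "CY")[1]]
  uaAcc <- names(which(panelTypes(panel) == "UA"))
  q <- setNames(c(cyRef), "qvar")
  aln <- c(q, refs[panelGroups(panel) == "HcRNAV"])
  # perturb one residue so the distance matrix has no duplicate rows
  substr(aln[["qvar"]], 1, 1) <- "W"
  tree <- neighborJoining(pDistanceMatrix(aln))
  expect_equal(assignHostRangeType("qvar", aln[["qvar"]], panel, tree), "CY")
  # below the identity threshold the type is unknown
  expect_equal(assignHostRangeType("qvar", aln[["qvar"]], panel, tree,
                                   minIdentity = 99.9), "unknown")
  expect_error(assignHostRangeType("missing", cyRef, panel, tree), "lacks")
})

test_that("variants evolved from a UA reference at 5% divergence type UA", {
  s <- smallSim()
  sr <- simulateReads(s$sim, s$cfg, pair = s$pair)
  res <- runPipeline(sr$reads, sr$layers, s$cp$panel,
                     layerLevels = s$cfg$layerNames)
  ev <- evaluateRecovery(res, sr)
  expect_equal(ev$typeAccuracy, 100)
})
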