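# Percent identity, the threshold classification rule and per-layer
# composition.

test_that("equal-length identity is positionwise", {
  a <- randAa(20)
  expect_equal(percentIdentity(a, a), 100)
  b <- "AAAAAAAAAA"; c_ <- "AAAAAAAAAC"
  expect_equal(percentIdentity(b, c_), 90)
  expect_error(percentIdentity("", "A"), "nonempty")
})

test_that("gapped identity matches the exhaustive alignment oracle", {
  set.seed(19)
  for (i in 1:20) {
    a <- randAa(sample(4:8, 1))
    b <- randAa(sample(4:8, 1))
    if (nchar(a) == nchar(b)) b <- paste0(b, "A")
    got <- percentIdentity(a, b)
    oracle <- oracleGlobalAlign(a, b)
    expect_true(got %in% oracle$identities,
                info = sprintf("a=%s b=%s got=%g allowed=%s", a, b, got,
                               paste(round(oracle$identities, 3),
                                     collapse = ",")))
  }
})

.toyPanel <- function() {
  hc1 <- paste(rep("ACDEFGHIKL", 2), collapse = "")  # 20 aa
  hc2 <- paste0(substr(hc1, 1, 18), "MW")
  rel <- paste(rep("MNPQRSTVWY", 2), collapse = "")
  referencePanel(c(HC_A = hc1, HC_B = hc2, REL_A = rel),
                 group = c("HcRNAV", "HcRNAV", "Alvernaviridae_like"),
                 hostType = c("UA", "CY", "unknown"))
}

test_that("the HcRNAV threshold is strict and the related floor inclusive", {
  panel <- .toyPanel()
  hc1 <- panelSequences(panel)[["HC_A"]]
  # 86% identity (17.2/20 -> use 18/20 = 90 and 17/20 = 85)
  q90 <- paste0(substr(hc1, 1, 18), "YY")        # 18/20 = 90%
  expect_equal(classifyAsv(q90, panel)$group, "HcRNAV_derived")
  q85 <- paste0(substr(hc1, 1, 17), "YYY")       # 17/20 = exactly 85%
  r85 <- classifyAsv(q85, panel)
  expect_equal(r85$percentIdentity, 85)
  expect_equal(r85$group, "Alvernaviridae_like")  # strict >85 fails, floor met
  # just above the boundary
  expect_equal(classifyAsv(q85, panel, hcThreshold = 84.999)$group,
               "HcRNAV_derived")
})

test_that("best related hit beats a weak HcRNAV hit; noise is unassigned", {
  panel <- .toyPanel()
  rel <- panelSequences(panel)[["REL_A"]]
  q <- paste0(substr(rel, 1, 18), "AA")  # 90% to REL_A, low to HcRNAV
  r <- classifyAsv(q, panel)
  expect_equal(r$group, "Alvernaviridae_like")
  expect_equal(r$bestRef, "REL_A")
  noise <- paste(rep("G", 20), collapse = "")
  expect_equal(classifyAsv(noise, panel)$group, "unassigned")
})

test_that("raising the threshold never increases HcRNAV-derived calls", {
  set.seed(55)
  panel <- .toyPanel()
  hc1 <- panelSequences(panel)[["HC_A"]]
  queries <- vapply(1:30, function(i) {
    s <- hc1
    k <- sample(0:10, 1)
    if (k > 0) {
      pos <- sample(20, k)
      for (p_ in pos) substr(s, p_, p_) <- "W"
    }
    s
  }, character(1))
  nHc <- vapply(c(50, 70, 85, 90, 95), function(th)
    sum(vapply(queries, function(q)
      classifyAsv(q, panel, hcThreshold = th)$group == "HcRNAV_derived",
      logical(1))), numeric(1))
  expect_true(all(diff(nHc) <= 0))
})

test_that("composition normalizes per layer and pools Others", {
  panel <- .toyPanel()
  hc <- panelSequences(panel)[["HC_A"]]
  rel <- panelSequences(panel)[["REL_A"]]
  hcnt <- "GCTTGTGATGAATTTGGTCATATTAAATTGGCTTGTGATGAATTTGGTCATATTAAATTG"
  relnt <- "ATGAATCCTCAAAGATCTACTGTTTGGTATATGAATCCTCAAAGATCTACTGTTTGGTAT"
  reads <- c(rep(hcnt, 60), rep(relnt, 40))
  layers <- rep("L1", 100)
  x <- dereplicateReads(reads, layers)
  res <- collapseByTranslation(x)
  cls <- classifyTable(res$table, panel)
  comp <- composeLayers(res$table, cls, othersMinFraction = 0)
  expect_equal(sum(comp["L1", ]), 1)
  expect_equal(unname(comp["L1", "HcRNAV_derived"]), 0.6)
  expect_equal(unname(comp["L1", "Alvernaviridae_like"]), 0.4)
})

test_that("composition is invariant to splitting a group's reads across variants", {
  panel <- .toyPanel()
  # two distinct nt codings of the same protein vs one: same composition
  a1 <- "GCTTGTGATGAATTTGGTCATATTAAATTGGCTTGTGATGAATTTGGTCATATTAAATTG"
  a2 <- sub("GCT", "GCA", a1)  # synonymous first codon
  relnt <- "ATGAATCCTCAAAGATCTACTGTTTGGTATATGAATCCTCAAAGATCTACTGTTTGGTAT"
  mk <- function(reads) {
    x <- dereplicateReads(reads, rep("L1", length(reads)))
    res <- collapseByTranslation(x)
    cls <- classifyTable(res$table, panel)
    composeLayers(res$table, cls, othersMinFraction = 0)
  }
  c1 <- mk(c(rep(a1, 60), rep(relnt, 40)))
  c2 <- mk(c(rep(a1, 30), rep(a2, 30), rep(relnt, 40)))
  expect_equal(c1, c2)
})

test_that("zero-read layers warn and give zero rows", {
  panel <- .toyPanel()
  a1 <- "GCTTGTGATGAATTTGGTCATATTAAATTGGCTTGTGATGAATTTGGTCATATTAAATTG"
  x <- dereplicateReads(rep(a1, 10), rep("L1", 10), layerLevels = c("L1", "L2"))
  res <- collapseByTranslation(x)
  cls <- classifyTable(res$table, panel)
  expect_warning(comp <- composeLayers(res$table, cls), "zero reads")
  expect_equal(unname(comp["L2", ]), c(0, 0, 0))
})

test_that("the nucleotide-level 92% rule is strict", {
  ref <- randNt(50)
  x <- dereplicateReads(rep(ref, 3), rep("L1", 3))
  out <- classifyNucleotide(x, c(R1 = ref), threshold = 92)
  expect_true(out$hcrnav_nt)
  # 46/50 = 92% exactly: strict rule excludes
  q <- ref
  for (p in c(2, 13, 27, 41)) substr(q, p, p) <- setdiff(NT, substr(q, p, p))[1]
  x2 <- dereplicateReads(rep(q, 3), rep("L1", 3))
  out2 <- classifyNucleotide(x2, c(R1 = ref), threshold = 92)
  expect_equal(out2$percent_identity, 92)
  expect_false(out2$hcrnav_nt)
})
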