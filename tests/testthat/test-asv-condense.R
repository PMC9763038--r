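# Dereplication, singleton removal, synonymous collapse and the abundance
# floor, with count-conservation properties.

test_that("dereplication tallies per-layer counts like a hash oracle", {
  t1 <- dereplicateReads(c("AAA", "AAA", "AAA", "AAT"), rep("L1", 4))
  expect_equal(unname(asvTotals(t1)), c(3, 1))
  expect_equal(SummarizedExperiment::rowData(t1)$sequence, c("AAA", "AAT"))

  t2 <- dereplicateReads(c("AAA", "AAA"), c("L1", "L2"))
  expect_equal(nrow(t2), 1)
  expect_equal(unname(asvCounts(t2)[1, ]), c(1, 1))

  set.seed(14)
  reads <- sample(vapply(1:12, function(i) randNt(9), character(1)), 400,
                  replace = TRUE)
  layers <- sample(c("A", "B", "C"), 400, replace = TRUE)
  t3 <- dereplicateReads(reads, layers, layerLevels = c("A", "B", "C"))
  for (k in sample(nrow(t3), 5)) {
    s <- SummarizedExperiment::rowData(t3)$sequence[k]
    for (l in c("A", "B", "C"))
      expect_equal(asvCounts(t3)[k, l], sum(reads == s & layers == l))
  }
  expect_equal(sum(asvCounts(t3)), 400)
  # rows sorted by decreasing total, ties by sequence
  tot <- asvTotals(t3)
  expect_true(all(diff(tot) <= 0))
  expect_error(dereplicateReads(character(0), character(0)))
  expect_error(dereplicateReads("AANA", "L1"), "unambiguous")
})

test_that("singleton removal uses total count across layers", {
  x <- dereplicateReads(c(rep("AAA", 3), "AAT"), rep("L1", 4))
  y <- suppressMessages(removeSingletons(x))
  expect_equal(nrow(y), 1)
  expect_equal(SummarizedExperiment::rowData(y)$sequence, "AAA")

  allS <- dereplicateReads(c("AAA", "AAT"), c("L1", "L1"))
  expect_warning(suppressMessages(removeSingletons(allS)), "empty")

  # one read in each of two layers: total 2, retained
  x2 <- dereplicateReads(c("AAA", "AAA", "CCC", "CCC", "GGG"),
                         c("L1", "L2", "L1", "L1", "L1"))
  y2 <- suppressMessages(removeSingletons(x2))
  expect_true("AAA" %in% SummarizedExperiment::rowData(y2)$sequence)
  # ... but removed under the per-layer option
  y3 <- suppressMessages(removeSingletons(x2, perLayer = TRUE))
  expect_false("AAA" %in% SummarizedExperiment::rowData(y3)$sequence)
})

test_that("synonymous variants collapse; nonsynonymous stay apart", {
  x <- dereplicateReads(c(rep("ATGAAA", 2), rep("ATGAAG", 3)), rep("L1", 5))
  res <- collapseByTranslation(x)
  expect_equal(nrow(res$table), 1)
  expect_equal(SummarizedExperiment::rowData(res$table)$sequence, "MK")
  expect_equal(unname(asvTotals(res$table)), 5)
  expect_equal(rownames(res$table), "ASV_001s")   # 2 members -> 's' suffix
  expect_setequal(res$map$ASV_001s, rownames(x))

  x2 <- dereplicateReads(c(rep("ATGAAA", 2), rep("ATGGAA", 3)), rep("L1", 5))
  res2 <- collapseByTranslation(x2)
  expect_equal(sort(SummarizedExperiment::rowData(res2$table)$sequence),
               c("ME", "MK"))
  expect_equal(rownames(res2$table), c("ASV_001", "ASV_002"))  # no suffix
})

test_that("internal stops are dropped with a warning, counts conserved otherwise", {
  x <- dereplicateReads(c(rep("ATGTAAAAA", 2), rep("ATGAAATAA", 3)),
                        rep("L1", 5))
  expect_warning(res <- collapseByTranslation(x), "internal stop")
  # trailing stop is tolerated, internal stop is not
  expect_equal(SummarizedExperiment::rowData(res$table)$sequence, "MK*")
  expect_equal(sum(asvTotals(res$table)), 3)
})

test_that("counts are conserved through dereplicate -> collapse; collapse is idempotent", {
  set.seed(31)
  for (rep_ in 1:5) {
    pool <- vapply(1:15, function(i) randNt(18), character(1))
    reads <- sample(pool, 600, replace = TRUE)
    layers <- sample(paste0("L", 1:4), 600, replace = TRUE)
    nt <- dereplicateReads(reads, layers)
    expect_equal(sum(asvCounts(nt)), 600)
    res <- suppressWarnings(collapseByTranslation(nt))
    keptReads <- sum(asvCounts(nt)) -
      sum(asvCounts(nt)[grepl("\\*.", translateSeq(
        SummarizedExperiment::rowData(nt)$sequence)), , drop = FALSE])
    expect_equal(sum(asvCounts(res$table)), keptReads)
    expect_lte(nrow(res$table), nrow(nt))
    # idempotence at the amino-acid level
    res2 <- collapseByTranslation(res$table)
    expect_equal(SummarizedExperiment::rowData(res2$table)$sequence,
                 SummarizedExperiment::rowData(res$table)$sequence)
    expect_equal(asvCounts(res2$table), asvCounts(res$table),
                 ignore_attr = TRUE)
    # collapse map partitions the retained nucleotide ids
    expect_setequal(unlist(res$map),
                    rownames(nt)[!grepl("\\*.", translateSeq(
                      SummarizedExperiment::rowData(nt)$sequence))])
  }
})

test_that("equality of nt and aa counts holds exactly when no synonyms exist", {
  x <- dereplicateReads(c(rep("ATGGAA", 3), rep("ATGAAA", 2)), rep("L1", 5))
  res <- collapseByTranslation(x)
  expect_equal(nrow(res$table), nrow(x))
})

test_that("abundance floor is inclusive at the boundary", {
  # grand total 10000; 2 reads = 0.02% retained, 1 read = 0.01% removed
  reads <- c(rep("AAAAAA", 9997), rep("CCCCCC", 2), "GGGGGG")
  x <- dereplicateReads(reads, rep("L1", length(reads)))
  res <- collapseByTranslation(x)
  y <- suppressMessages(abundanceFilter(res$table, 2e-4))
  seqs <- SummarizedExperiment::rowData(y)$sequence
  expect_true("PP" %in% seqs)    # CCCCCC -> PP at exactly 0.02%
  expect_false("GG" %in% seqs)   # 0.01%
  expect_error(abundanceFilter(res$table, 1.5), "0, 1")

  # random tables match the arithmetic oracle
  set.seed(77)
  pool <- vapply(1:30, function(i) randNt(12), character(1))
  reads <- sample(pool, 5000, replace = TRUE,
                  prob = stats::rlnorm(30, sdlog = 2))
  x2 <- dereplicateReads(reads, rep("L1", 5000))
  for (f in c(1e-4, 1e-3, 5e-3)) {
    kept <- suppressMessages(abundanceFilter(x2, f))
    want <- rownames(x2)[asvTotals(x2) / sum(asvCounts(x2)) >= f]
    expect_setequal(rownames(kept), want)
  }
})
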