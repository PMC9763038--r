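# Dereplication of amplicon reads into nucleotide ASVs, singleton removal,
# synonymous collapse to amino-acid ASVs, and the relative-abundance floor.
#
# Exact dereplication stands in for error-model denoising: on simulated
# low-error reads every distinct sequence is its own variant, and the
# singleton filter removes the bulk of one-off sequencing errors.

#' Dereplicate reads into a nucleotide ASV table
#'
#' Counts every distinct read sequence per layer. Nucleotide variants are
#' named \code{NT_001, NT_002, ...} in order of decreasing total abundance
#' (ties broken by sequence).
#'
#' @param reads Character vector (or \code{DNAStringSet}) of unambiguous
#'   read sequences.
#' @param layers Character vector of layer labels, one per read.
#' @param layerLevels Optional ordering of layers (default: order of first
#'   appearance).
#' @return An \linkS4class{AsvTable} at nucleotide level.
#' @export
dereplicateReads <- function(reads, layers, layerLevels = NULL) {
  reads <- .asCharSeqs(reads)
  if (length(reads) == 0L) stop("no reads to dereplicate")
  if (length(layers) != length(reads))
    stop("'layers' must have one label per read")
  bad <- setdiff(unique(unlist(strsplit(unique(reads), ""))),
                 c("A", "C", "G", "T"))
  if (length(bad))
    stop("reads must be unambiguous A/C/G/T; found: ", paste(bad, collapse = ", "))
  if (is.null(layerLevels)) layerLevels <- unique(layers)
  fSeq <- factor(reads)
  fLay <- factor(layers, levels = layerLevels)
  counts <- table(fSeq, fLay)
  counts <- matrix(as.integer(counts), nrow = nlevels(fSeq),
                   dimnames = list(NULL, layerLevels))
  .newAsvTable(levels(fSeq), counts, level = "nt")
}

#' Remove singleton ASVs
#'
#' Drops variants whose total count, summed across layers, is exactly 1.
#' (The survey pools layers into one amplicon analysis, so a variant seen
#' once in each of two layers is retained; use \code{perLayer = TRUE} to
#' remove per-layer singletons instead.)
#'
#' @param x An \linkS4class{AsvTable}.
#' @param perLayer Remove variants that are singletons in every layer they
#'   occur in, rather than by total count.
#' @return Filtered \code{AsvTable}; the number of removed variants/reads is
#'   reported via \code{message}.
#' @export
removeSingletons <- function(x, perLayer = FALSE) {
  stopifnot(is(x, "AsvTable"))
  if (nrow(x) == 0L) stop("table is empty")
  cnt <- asvCounts(x)
  keep <- if (perLayer) apply(cnt, 1L, max) > 1L else rowSums(cnt) > 1L
  nDrop <- sum(!keep)
  message(sprintf("removeSingletons: removed %d variant(s), %d read(s)",
                  nDrop, sum(cnt[!keep, , drop = FALSE])))
  if (!any(keep)) warning("all variants were singletons; table is empty")
  x[keep, ]
}

#' Collapse nucleotide ASVs into amino-acid ASVs by translation
#'
#' Translates every nucleotide variant in the given frame and merges
#' variants with identical translations (synonymous variants), summing their
#' per-layer counts. Amino-acid variants are named \code{ASV_001, ASV_002,
#' ...} by decreasing abundance, with an \code{s} suffix when the variant
#' condenses more than one nucleotide variant (synonymous group). Variants
#' whose translation contains an internal stop are dropped with a warning.
#' Applied to an amino-acid table the operation groups identical sequences,
#' which makes it idempotent.
#'
#' @param x An \linkS4class{AsvTable}.
#' @param frame Reading frame of the insert (default 0: the forward primer
#'   is designed in codon phase, so the trimmed insert starts on a codon).
#' @return A list with \code{table} (amino-acid \code{AsvTable}) and
#'   \code{map} (named list: aa ASV id -> member nt ASV ids).
#' @export
collapseByTranslation <- function(x, frame = 0L) {
  stopifnot(is(x, "AsvTable"))
  if (nrow(x) == 0L) stop("cannot collapse an empty table")
  seqs <- SummarizedExperiment::rowData(x)$sequence
  if (asvLevel(x) == "aa") {
    aa <- seqs  # already amino acids: grouping identical sequences is a no-op
    keep <- rep(TRUE, length(aa))
  } else {
    aa <- translateSeq(seqs, frame = frame)
    keep <- !grepl("\\*.", aa)  # internal stop: '*' before the last residue
    if (!any(keep)) stop("every variant has an internal stop in frame ", frame)
    if (any(!keep))
      warning(sprintf("dropped %d variant(s) with internal stop codons (%d reads)",
                      sum(!keep), sum(asvCounts(x)[!keep, , drop = FALSE])))
  }
  cnt <- asvCounts(x)[keep, , drop = FALSE]
  ids <- rownames(x)[keep]
  aa <- aa[keep]
  grp <- factor(aa, levels = unique(aa))
  agg <- rowsum(cnt, grp, reorder = FALSE)
  members <- split(ids, grp)
  tab <- .newAsvTable(levels(grp), agg, level = "aa", members = members)
  # recover member lists in the table's final (abundance-sorted) order
  map <- members[SummarizedExperiment::rowData(tab)$sequence]
  names(map) <- rownames(tab)
  list(table = tab, map = map)
}

#' Filter ASVs by relative read abundance
#'
#' Keeps variants whose total count is at least \code{minFraction} of the
#' grand total (inclusive boundary: a variant at exactly the floor is
#' retained, matching the >= 0.02\% rule).
#'
#' @param x An \linkS4class{AsvTable}.
#' @param minFraction Abundance floor as a fraction (default 2e-4 = 0.02\%).
#' @return Filtered \code{AsvTable}.
#' @export
abundanceFilter <- function(x, minFraction = 2e-4) {
  stopifnot(is(x, "AsvTable"))
  if (minFraction < 0 || minFraction > 1)
    stop("'minFraction' must be in [0, 1]")
  grand <- sum(asvCounts(x))
  if (grand <= 0L) stop("table has no reads")
  keep <- asvTotals(x) / grand >= minFraction
  message(sprintf("abundanceFilter: removed %d variant(s) below %.4g%%",
                  sum(!keep), 100 * minFraction))
  x[keep, ]
}

#' Write an ASV table to TSV
#'
#' @param x An \linkS4class{AsvTable}.
#' @param path Output TSV path.
#' @export
writeAsvTable <- function(x, path) {
  d <- data.frame(asv_id = rownames(x),
                  as.data.frame(SummarizedExperiment::rowData(x)),
                  asvCounts(x), total = asvTotals(x),
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
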