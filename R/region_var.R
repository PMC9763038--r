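# Per-column polymorphism profiling of aligned amplicon translations and
# segmentation into conserved (<=1 residue) / variable (>=2 residues)
# regions. All intervals are 0-based, half-open.

#' Per-column polymorphism profile of a protein alignment
#'
#' Counts distinct residues per alignment column. Gaps are excluded by
#' default (a deletion is not a residue polymorphism); set
#' \code{countGaps = TRUE} to count \code{-} as a residue state.
#'
#' @param aln Equal-length amino-acid sequences (>= 2 rows).
#' @param countGaps Count gaps as a residue state (default \code{FALSE}).
#' @return Integer vector of per-column distinct-residue counts.
#' @export
columnPolymorphism <- function(aln, countGaps = FALSE) {
  m <- .alnCharMatrix(aln)
  vapply(seq_len(ncol(m)), function(j) {
    res <- unique(m[, j])
    if (!countGaps) res <- setdiff(res, "-")
    max(length(res), 1L)
  }, integer(1))
}

#' Segment a polymorphism profile into conserved and variable regions
#'
#' Columns with >= 2 distinct residues are polymorphic. Maximal runs of
#' polymorphic columns become variable regions; runs separated by at most
#' \code{mergeGap} monomorphic columns are merged. Everything else is
#' conserved. The returned intervals tile the profile without overlap and
#' adjacent intervals always carry different labels.
#'
#' @param profile Integer vector from \code{\link{columnPolymorphism}}.
#' @param mergeGap Merge variable runs separated by at most this many
#'   monomorphic columns (default 2).
#' @return data.frame with 0-based half-open \code{start}, \code{end} and
#'   \code{label} (\code{"conserved"}/\code{"variable"}).
#' @export
segmentRegions <- function(profile, mergeGap = 2L) {
  n <- length(profile)
  if (n == 0L) stop("profile is empty")
  poly <- profile >= 2L
  if (any(poly)) {
    # merge polymorphic runs across small monomorphic gaps
    r <- rle(poly)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    inner <- which(!r$values & r$lengths <= mergeGap)
    inner <- inner[inner > 1L & inner < length(r$values)]
    poly[unlist(mapply(seq, starts[inner], ends[inner], SIMPLIFY = FALSE))] <- TRUE
  }
  r <- rle(poly)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts, end = ends,
             label = ifelse(r$values, "variable", "conserved"),
             stringsAsFactors = FALSE)
}

#' Map alignment-column intervals to ungapped reference coordinates
#'
#' Converts each region interval from alignment columns to 0-based,
#' half-open coordinates on a chosen (possibly gapped) reference row.
#'
#' @param regions data.frame from \code{\link{segmentRegions}}.
#' @param refId Name of the reference row.
#' @param aln The alignment the regions were computed on (must contain
#'   \code{refId}).
#' @return \code{regions} with \code{ref_start} and \code{ref_end} columns
#'   added.
#' @export
mapRegionsToReference <- function(regions, refId, aln) {
  s <- .asCharSeqs(aln)
  if (!refId %in% names(s)) stop("reference '", refId, "' is not in the alignment")
  ref <- strsplit(s[[refId]], "")[[1]]
  nonGap <- as.integer(ref != "-")
  before <- c(0L, cumsum(nonGap))   # before[k+1] = non-gap chars in cols [0, k)
  if (any(regions$end > length(ref)))
    stop("region interval exceeds the alignment width")
  regions$ref_start <- before[regions$start + 1L]
  regions$ref_end <- before[regions$end + 1L]
  regions
}

#' Write region annotations as a BED-like TSV
#'
#' Emits 0-based half-open intervals suitable for external structure
#' annotation overlays.
#'
#' @param regions data.frame from \code{\link{segmentRegions}} (optionally
#'   with reference coordinates).
#' @param path Output TSV path.
#' @param name Feature name prefix.
#' @export
writeRegionsTsv <- function(regions, path, name = "amplicon") {
  d <- cbind(name = name, regions)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
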