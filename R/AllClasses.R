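#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

# AsvTable --------------------------------------------------------------------

#' Amplicon sequence variant table
#'
#' An \code{AsvTable} is a \linkS4class{SummarizedExperiment} whose rows are
#' amplicon sequence variants (ASVs) and whose columns are sediment layers
#' (or any sample grouping). The single \code{"counts"} assay holds read
#' counts; \code{rowData} carries the variant sequence and, for amino-acid
#' tables, the nucleotide member ASVs collapsed into each row. Rows are kept
#' sorted by decreasing total count (ties broken by sequence) and sequences
#' are unique within a table.
#'
#' @slot level \code{"nt"} or \code{"aa"}: the alphabet of the variants.
#' @export
setClass("AsvTable", contains = "SummarizedExperiment",
         representation(level = "character"))

setValidity("AsvTable", function(object) {
  msg <- NULL
  if (length(object@level) != 1L || !object@level %in% c("nt", "aa"))
    msg <- c(msg, "level must be 'nt' or 'aa'")
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "an assay named 'counts' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!"sequence" %in% names(rd))
    msg <- c(msg, "rowData must contain a 'sequence' column")
  else {
    if (anyDuplicated(rd$sequence))
      msg <- c(msg, "sequences must be unique within a table")
    tot <- rowSums(SummarizedExperiment::assay(object, "counts"))
    ord <- order(-tot, rd$sequence)
    if (!identical(ord, seq_along(tot)))
      msg <- c(msg, "rows must be sorted by decreasing total count, ties by sequence")
  }
  if (is.null(msg)) TRUE else msg
})

# internal constructor: sequences/counts already aggregated, not yet ordered
.newAsvTable <- function(sequences, counts, level, members = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  tot <- rowSums(counts)
  ord <- order(-tot, sequences)
  sequences <- sequences[ord]
  counts <- counts[ord, , drop = FALSE]
  n <- length(sequences)
  if (level == "nt") {
    ids <- sprintf("NT_%03d", seq_len(n))
    rd <- S4Vectors::DataFrame(sequence = sequences)
  } else {
    members <- members[ord]
    nm <- lengths(members)
    ids <- sprintf("ASV_%03d%s", seq_len(n), ifelse(nm > 1L, "s", ""))
    rd <- S4Vectors::DataFrame(sequence = sequences,
                               nMembers = nm,
                               members = vapply(members, paste, character(1),
                                                collapse = ","))
  }
  rownames(counts) <- ids
  rownames(rd) <- ids
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd)
  new("AsvTable", se, level = level)
}

#' @describeIn AsvTable-accessors Alphabet level, \code{"nt"} or \code{"aa"}.
#' @export
asvLevel <- function(x) x@level

#' Accessors for AsvTable objects
#'
#' @param x An \code{AsvTable}.
#' @name AsvTable-accessors
NULL

#' @describeIn AsvTable-accessors Variant sequences as a named
#'   \code{DNAStringSet}/\code{AAStringSet}.
#' @export
asvSequences <- function(x) {
  s <- SummarizedExperiment::rowData(x)$sequence
  names(s) <- rownames(x)
  if (x@level == "nt") Biostrings::DNAStringSet(s) else Biostrings::AAStringSet(s)
}

#' @describeIn AsvTable-accessors Integer count matrix (ASVs x layers).
#' @export
asvCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @describeIn AsvTable-accessors Total read count per ASV.
#' @export
asvTotals <- function(x) rowSums(SummarizedExperiment::assay(x, "counts"))

#' @describeIn AsvTable-accessors Member nucleotide-ASV ids per amino-acid ASV.
#' @export
asvMembers <- function(x) {
  if (x@level != "aa") stop("members are defined for amino-acid tables only")
  m <- strsplit(SummarizedExperiment::rowData(x)$members, ",", fixed = TRUE)
  names(m) <- rownames(x)
  m
}

setMethod("show", "AsvTable", function(object) {
  cat(sprintf("AsvTable (%s) with %d variants over %d layers, %d reads\n",
              object@level, nrow(object), ncol(object),
              sum(SummarizedExperiment::assay(object, "counts"))))
  if (nrow(object)) {
    tot <- rowSums(SummarizedExperiment::assay(object, "counts"))
    k <- min(5L, nrow(object))
    for (i in seq_len(k))
      cat(sprintf("  %s  %6d reads  %s...\n", rownames(object)[i], tot[i],
                  substr(SummarizedExperiment::rowData(object)$sequence[i], 1, 24)))
    if (nrow(object) > k) cat("  ...\n")
  }
})

# ReferencePanel ---------------------------------------------------------------

#' Reference panel of major capsid protein sequences
#'
#' Holds the amino-acid reference sequences used for classification and
#' host-range typing. Each entry has a group label (\code{HcRNAV},
#' \code{Alvernaviridae_like} or \code{other}) and, for HcRNAV strains, a
#' host-range type (\code{UA}, \code{CY} or \code{unknown}).
#'
#' @slot sequences \code{AAStringSet} named by accession.
#' @slot group Character vector of group labels, one per entry.
#' @slot hostType Character vector of host-range types, one per entry.
#' @export
setClass("ReferencePanel",
         representation(sequences = "AAStringSet", group = "character",
                        hostType = "character"))

setValidity("ReferencePanel", function(object) {
  msg <- NULL
  n <- length(object@sequences)
  if (n == 0L) msg <- c(msg, "panel must be nonempty")
  if (is.null(names(object@sequences)) || anyDuplicated(names(object@sequences)))
    msg <- c(msg, "accessions (sequence names) must be present and unique")
  if (length(object@group) != n || length(object@hostType) != n)
    msg <- c(msg, "group and hostType must have one entry per sequence")
  if (!all(object@group %in% c("HcRNAV", "Alvernaviridae_like", "other")))
    msg <- c(msg, "groups must be HcRNAV, Alvernaviridae_like or other")
  if (!all(object@hostType %in% c("UA", "CY", "unknown")))
    msg <- c(msg, "host types must be UA, CY or unknown")
  if (!any(object@group == "HcRNAV"))
    msg <- c(msg, "panel must contain at least one HcRNAV entry")
  if (is.null(msg)) TRUE else msg
})

#' Construct a ReferencePanel
#'
#' @param sequences Named \code{AAStringSet} or named character vector of
#'   amino-acid sequences; names are accessions.
#' @param group Group label per entry: \code{"HcRNAV"},
#'   \code{"Alvernaviridae_like"} or \code{"other"}.
#' @param hostType Host-range type per entry: \code{"UA"}, \code{"CY"} or
#'   \code{"unknown"} (default).
#' @return A \code{ReferencePanel}.
#' @export
referencePanel <- function(sequences, group,
                           hostType = rep("unknown", length(sequences))) {
  if (is.character(sequences)) sequences <- Biostrings::AAStringSet(sequences)
  new("ReferencePanel", sequences = sequences, group = group,
      hostType = hostType)
}

#' @describeIn ReferencePanel Accessions of the panel entries.
#' @param x,object A \code{ReferencePanel}.
#' @export
panelAccessions <- function(x) names(x@sequences)

#' @describeIn ReferencePanel Panel sequences as a named character vector.
#' @export
panelSequences <- function(x) setNames(as.character(x@sequences),
                                       names(x@sequences))

#' @describeIn ReferencePanel Group label per entry.
#' @export
panelGroups <- function(x) setNames(x@group, names(x@sequences))

#' @describeIn ReferencePanel Host-range type per entry.
#' @export
panelTypes <- function(x) setNames(x@hostType, names(x@sequences))

setMethod("show", "ReferencePanel", function(object) {
  cat(sprintf("ReferencePanel with %d entries (%d HcRNAV, %d related, %d other)\n",
              length(object@sequences), sum(object@group == "HcRNAV"),
              sum(object@group == "Alvernaviridae_like"),
              sum(object@group == "other")))
  for (i in seq_along(object@sequences))
    cat(sprintf("  %-22s %-18s %-7s %d aa\n", names(object@sequences)[i],
                object@group[i], object@hostType[i],
                Biostrings::width(object@sequences)[i]))
})

#' Read a reference panel from FASTA plus sidecar metadata TSV
#'
#' The metadata TSV must have columns \code{accession}, \code{group} and
#' \code{type}, matching the FASTA ids.
#'
#' @param fastaPath Amino-acid FASTA of reference sequences.
#' @param metaPath Sidecar TSV.
#' @return A \code{ReferencePanel}.
#' @export
readReferencePanel <- function(fastaPath, metaPath) {
  seqs <- readSeqFasta(fastaPath, "aa")
  meta <- utils::read.delim(metaPath, stringsAsFactors = FALSE)
  need <- c("accession", "group", "type")
  if (!all(need %in% names(meta)))
    stop("panel metadata must have columns: ", paste(need, collapse = ", "))
  i <- match(names(seqs), meta$accession)
  if (anyNA(i)) stop("panel metadata missing accession(s): ",
                     paste(names(seqs)[is.na(i)], collapse = ", "))
  referencePanel(seqs, group = meta$group[i], hostType = meta$type[i])
}

# Primers ----------------------------------------------------------------------

#' Degenerate primer
#'
#' An IUPAC-coded oligonucleotide back-translated from a conserved
#' amino-acid motif of a protein alignment. Coordinates are 0-based
#' alignment columns.
#'
#' @slot iupacSeq IUPAC nucleotide string as synthesized (reverse primers are
#'   already reverse-complemented).
#' @slot degeneracy Number of distinct unambiguous expansions.
#' @slot orientation \code{"forward"} or \code{"reverse"}.
#' @slot motifStartCol 0-based alignment column where the source motif starts.
#' @slot motifLength Motif length in amino acids.
#' @export
setClass("DegeneratePrimer",
         representation(iupacSeq = "character", degeneracy = "numeric",
                        orientation = "character", motifStartCol = "integer",
                        motifLength = "integer"))

setValidity("DegeneratePrimer", function(object) {
  msg <- NULL
  if (!object@orientation %in% c("forward", "reverse"))
    msg <- c(msg, "orientation must be 'forward' or 'reverse'")
  deg <- prod(nchar(.IUPAC[strsplit(object@iupacSeq, "")[[1]]]))
  if (!isTRUE(all.equal(deg, object@degeneracy)))
    msg <- c(msg, "degeneracy must equal the product of per-position base-set sizes")
  if (object@degeneracy < 1) msg <- c(msg, "degeneracy must be >= 1")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "DegeneratePrimer", function(object) {
  cat(sprintf("DegeneratePrimer [%s] %s (degeneracy %d, motif cols %d-%d)\n",
              object@orientation, object@iupacSeq, object@degeneracy,
              object@motifStartCol, object@motifStartCol + object@motifLength))
})

#' @describeIn DegeneratePrimer IUPAC sequence of a primer.
#' @param x,object A \code{DegeneratePrimer}.
#' @export
primerSeq <- function(x) x@iupacSeq

#' Primer pair flanking a hypervariable region
#'
#' @slot forward,reverse \code{DegeneratePrimer} objects.
#' @slot insertCols 0-based half-open interval of alignment columns between
#'   the two motifs (the amplified, primer-trimmed insert).
#' @slot expectedInsertLenNt Expected trimmed insert length in nucleotides
#'   (3 x gap-free column span).
#' @export
setClass("PrimerPair",
         representation(forward = "DegeneratePrimer",
                        reverse = "DegeneratePrimer",
                        insertCols = "integer",
                        expectedInsertLenNt = "integer"))

setValidity("PrimerPair", function(object) {
  msg <- NULL
  fEnd <- object@forward@motifStartCol + object@forward@motifLength
  if (fEnd > object@reverse@motifStartCol)
    msg <- c(msg, "forward motif must lie strictly upstream of the reverse motif")
  if (length(object@insertCols) != 2L)
    msg <- c(msg, "insertCols must be a length-2 interval")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "PrimerPair", function(object) {
  cat(sprintf(
    "PrimerPair: fwd %s (deg %d) / rev %s (deg %d); insert cols [%d,%d), ~%d nt\n",
    object@forward@iupacSeq, object@forward@degeneracy,
    object@reverse@iupacSeq, object@reverse@degeneracy,
    object@insertCols[1], object@insertCols[2], object@expectedInsertLenNt))
})
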