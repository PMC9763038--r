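# Percent-identity classification of amino-acid ASVs against a packaged
# reference panel, and per-layer community composition. Exhaustive pairwise
# identity against the panel replaces a database BLAST search; the >85%
# HcRNAV rule is strict, per the labeling rule it implements.

#' Percent identity between two sequences
#'
#' Equal-length sequences are compared position by position
#' (matches / length x 100). Unequal lengths are globally aligned by
#' Needleman-Wunsch with match +1, mismatch 0 and linear gap -1 -- the gap
#' penalty steers the path only -- and identity is matches divided by
#' alignment columns. Traceback prefers diagonal, then a gap in \code{b},
#' then a gap in \code{a}, so results are deterministic.
#'
#' @param a,b Nonempty sequences (single strings).
#' @return Percent identity in [0, 100].
#' @export
percentIdentity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be nonempty")
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) == nchar(b)) {
    x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
    return(100 * sum(x == y) / length(x))
  }
  .nwIdentity(a, b)
}

# Needleman-Wunsch with the bespoke scoring above; returns identity over
# alignment columns.
.nwIdentity <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  H <- matrix(0, n + 1L, m + 1L)
  H[, 1L] <- -(0:n); H[1L, ] <- -(0:m)
  for (i in seq_len(n)) {
    match_ <- as.numeric(x[i] == y)
    for (j in seq_len(m)) {
      H[i + 1L, j + 1L] <- max(H[i, j] + match_[j],      # diagonal
                               H[i, j + 1L] - 1,         # gap in b
                               H[i + 1L, j] - 1)         # gap in a
    }
  }
  # deterministic traceback: diagonal > gap in b > gap in a
  i <- n; j <- m; matches <- 0L; cols <- 0L
  while (i > 0L || j > 0L) {
    cols <- cols + 1L
    if (i > 0L && j > 0L &&
        H[i + 1L, j + 1L] == H[i, j] + (x[i] == y[j])) {
      matches <- matches + (x[i] == y[j])
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && H[i + 1L, j + 1L] == H[i, j + 1L] - 1) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  100 * matches / cols
}

#' Classify one amino-acid ASV against the reference panel
#'
#' The variant is labeled \code{HcRNAV_derived} when its best identity to
#' any HcRNAV panel entry strictly exceeds \code{hcThreshold} (85\%: a hit at
#' exactly 85.0 is \emph{not} HcRNAV-derived); otherwise
#' \code{Alvernaviridae_like} when its best identity to any panel entry is at
#' least \code{relatedFloor}; otherwise \code{unassigned}. The reported best
#' reference is the panel-wide identity maximum, ties broken by accession.
#'
#' @param seq Amino-acid sequence (single string).
#' @param panel A \linkS4class{ReferencePanel}.
#' @param hcThreshold Strict HcRNAV identity threshold (default 85).
#' @param relatedFloor Minimum identity to call a panel relative (default 40).
#' @return List with \code{bestRef}, \code{percentIdentity}, \code{group}.
#' @export
classifyAsv <- function(seq, panel, hcThreshold = 85, relatedFloor = 40) {
  stopifnot(is(panel, "ReferencePanel"))
  refs <- panelSequences(panel)
  pid <- vapply(refs, function(r) percentIdentity(seq, r), numeric(1))
  ord <- order(-pid, names(refs))
  best <- ord[1L]
  hcMax <- suppressWarnings(max(pid[panelGroups(panel) == "HcRNAV"]))
  group <- if (hcMax > hcThreshold) "HcRNAV_derived"
           else if (max(pid) >= relatedFloor) "Alvernaviridae_like"
           else "unassigned"
  list(bestRef = names(refs)[best], percentIdentity = unname(pid[best]),
       group = group)
}

#' Classify every ASV in an amino-acid table
#'
#' @param x Amino-acid \linkS4class{AsvTable}.
#' @param panel A \linkS4class{ReferencePanel}.
#' @param hcThreshold,relatedFloor See \code{\link{classifyAsv}}.
#' @return \code{DataFrame} with one row per ASV: \code{best_ref},
#'   \code{percent_identity}, \code{group}.
#' @export
classifyTable <- function(x, panel, hcThreshold = 85, relatedFloor = 40) {
  stopifnot(is(x, "AsvTable"), asvLevel(x) == "aa")
  seqs <- SummarizedExperiment::rowData(x)$sequence
  res <- lapply(seqs, classifyAsv, panel = panel, hcThreshold = hcThreshold,
                relatedFloor = relatedFloor)
  S4Vectors::DataFrame(
    best_ref = vapply(res, `[[`, character(1), "bestRef"),
    percent_identity = vapply(res, `[[`, numeric(1), "percentIdentity"),
    group = vapply(res, `[[`, character(1), "group"),
    row.names = rownames(x))
}

#' Optional nucleotide-level HcRNAV call
#'
#' Flags nucleotide ASVs whose best identity to any HcRNAV nucleotide
#' reference strictly exceeds \code{threshold} (default 92\%), reported
#' alongside the protein-level classification.
#'
#' @param x Nucleotide \linkS4class{AsvTable}.
#' @param hcNtRefs Named character vector (or \code{DNAStringSet}) of HcRNAV
#'   nucleotide reference sequences (e.g. reference amplicon inserts).
#' @param threshold Strict identity threshold (default 92).
#' @return \code{DataFrame} with \code{best_ref}, \code{percent_identity}
#'   and logical \code{hcrnav_nt}.
#' @export
classifyNucleotide <- function(x, hcNtRefs, threshold = 92) {
  stopifnot(is(x, "AsvTable"), asvLevel(x) == "nt")
  refs <- .asCharSeqs(hcNtRefs)
  seqs <- SummarizedExperiment::rowData(x)$sequence
  res <- t(vapply(seqs, function(s) {
    pid <- vapply(refs, function(r) percentIdentity(s, r), numeric(1))
    i <- order(-pid, names(refs))[1L]
    c(best = i, pid = unname(pid[i]))
  }, numeric(2)))
  S4Vectors::DataFrame(best_ref = names(refs)[res[, 1L]],
                       percent_identity = res[, 2L],
                       hcrnav_nt = res[, 2L] > threshold,
                       row.names = rownames(x))
}

#' Per-layer community composition by group
#'
#' Sums reads per layer by classification group. Unassigned variants and
#' variants below the abundance floor are pooled into \code{"Others"}
#' (mirroring a composition figure's "Others" bucket of unattributable and
#' <0.02\% variants). Fractions are reads of the group divided by the
#' layer's total reads.
#'
#' @param x Amino-acid \linkS4class{AsvTable}.
#' @param classification Result of \code{\link{classifyTable}} for \code{x}.
#' @param othersMinFraction Variants below this fraction of the grand total
#'   are pooled into Others (default 2e-4).
#' @return Matrix (layers x groups) of fractions; each row sums to 1.
#'   Layers with zero reads give a zero row with a warning.
#' @export
composeLayers <- function(x, classification, othersMinFraction = 2e-4) {
  stopifnot(is(x, "AsvTable"))
  if (!identical(rownames(classification), rownames(x)))
    stop("classification rows must match the ASV table")
  cnt <- asvCounts(x)
  grand <- sum(cnt)
  lab <- classification$group
  lab[lab == "unassigned" | asvTotals(x) / grand < othersMinFraction] <- "Others"
  groups <- c("HcRNAV_derived", "Alvernaviridae_like", "Others")
  out <- matrix(0, nrow = ncol(cnt), ncol = length(groups),
                dimnames = list(colnames(cnt), groups))
  agg <- rowsum(cnt, factor(lab, levels = groups))
  out[, rownames(agg)] <- t(agg)
  layerTot <- rowSums(out)
  zero <- layerTot == 0
  if (any(zero)) {
    warning("layer(s) with zero reads: ",
            paste(rownames(out)[zero], collapse = ", "))
    layerTot[zero] <- 1
  }
  sweep(out, 1L, layerTot, "/")
}
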