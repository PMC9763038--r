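# Distance-based phylogenetics: uncorrected p-distances, a deterministic
# Saitou-Nei neighbor-joining implementation (lexicographic tie-break so
# trees are reproducible), column-resampling bootstrap supports, and
# host-range (UA/CY) typing of HcRNAV-derived variants. Trees are ape
# "phylo" objects; Newick is the serialization.

#' Pairwise p-distance matrix of an amino-acid alignment
#'
#' d(i, j) is the proportion of differing sites among columns where neither
#' row has a gap. A Poisson correction (-log(1 - p)) is available for deeper
#' divergences.
#'
#' @param aln Equal-length named sequences (character vector or
#'   \code{AAStringSet}); gaps as \code{-}.
#' @param correction \code{"none"} (default) or \code{"poisson"}.
#' @return Symmetric numeric matrix with zero diagonal, labeled by sequence
#'   names.
#' @export
pDistanceMatrix <- function(aln, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  s <- .asCharSeqs(aln)
  if (length(s) < 3L) stop("need at least 3 sequences")
  if (is.null(names(s)) || anyDuplicated(names(s)))
    stop("sequences must have unique names")
  m <- .alnCharMatrix(s)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(s), names(s)))
  gap <- m == "-"
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    use <- !gap[i, ] & !gap[j, ]
    if (!any(use))
      stop("no comparable columns between ", names(s)[i], " and ", names(s)[j])
    p <- mean(m[i, use] != m[j, use])
    if (correction == "poisson") {
      if (p >= 1) stop("Poisson correction undefined at p = 1")
      p <- -log(1 - p)
    }
    d[i, j] <- d[j, i] <- p
  }
  d
}

.checkDistanceMatrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D) || nrow(D) < 3L)
    stop("'D' must be a square matrix over at least 3 labels")
  if (is.null(rownames(D)) || !identical(rownames(D), colnames(D)))
    stop("'D' must have matching row and column labels")
  if (any(D < 0)) stop("distances must be non-negative")
  if (any(abs(D - t(D)) > 1e-12)) stop("'D' must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("'D' must have a zero diagonal")
  invisible(TRUE)
}

.fmtLen <- function(x) sprintf("%.15g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: at each step the pair minimizing
#' Q(i, j) = (n - 2) d(i, j) - sum_k d(i, k) - sum_k d(j, k) is joined, with
#' ties broken deterministically by the lexicographically smallest pair of
#' cluster labels (a cluster is labeled by its smallest leaf). Negative
#' branch-length estimates are clamped to zero and the clamped deficit is
#' recorded in the \code{"clampedDeficit"} attribute. Consistent on additive
#' matrices: the generating topology and branch lengths are recovered
#' exactly.
#'
#' @param D Symmetric labeled distance matrix (>= 3 taxa).
#' @return Unrooted \code{phylo} tree.
#' @export
neighborJoining <- function(D) {
  .checkDistanceMatrix(D)
  labs <- rownames(D)
  frag <- labs                      # growing newick fragment per cluster
  key <- labs                       # smallest leaf label per cluster
  deficit <- 0
  while (length(key) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    k1 <- pmin(key[cand[, 1]], key[cand[, 2]])
    k2 <- pmax(key[cand[, 1]], key[cand[, 2]])
    pick <- order(k1, k2)[1L]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    li <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0) { deficit <- deficit - li; li <- 0 }
    if (lj < 0) { deficit <- deficit - lj; lj <- 0 }
    newFrag <- sprintf("(%s:%s,%s:%s)", frag[i], .fmtLen(li),
                       frag[j], .fmtLen(lj))
    newKey <- min(key[i], key[j])
    dNew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dNew[keep]),
                c(dNew[keep], 0))
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], newKey)
    D <- D2
    frag <- c(frag[keep], newFrag)
    key <- c(key[keep], newKey)
  }
  # final star: three-point closed form
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  ls <- c(l1, l2, l3)
  deficit <- deficit - sum(ls[ls < 0])
  ls[ls < 0] <- 0
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], .fmtLen(ls[1]),
                 frag[2], .fmtLen(ls[2]), frag[3], .fmtLen(ls[3]))
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clampedDeficit") <- deficit
  tree
}

# canonical bipartition strings of a phylo tree's internal edges; each split
# is represented by the side NOT containing the alphabetically first tip
.treeSplits <- function(tree) {
  tips <- sort(tree$tip.label)
  pp <- ape::prop.part(tree)
  out <- character(0)
  for (cl in pp) {
    side <- sort(attr(pp, "labels")[cl])
    if (tips[1] %in% side) side <- setdiff(tips, side)
    if (length(side) >= 2L && length(side) <= length(tips) - 2L)
      out <- c(out, paste(side, collapse = "\r"))
  }
  unique(out)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement \code{nReplicates} times,
#' rebuilds the NJ tree per replicate, and scores each internal bipartition
#' of the full-data tree by the percentage of replicate trees containing it.
#' All supports are stored in \code{tree$node.label} (empty for the root of
#' the unrooted representation); the conventional display rule of masking
#' supports <= 50\% is applied by \code{\link{maskSupports}}, not here.
#' Fully reproducible for a given alignment, replicate count and seed.
#'
#' @param aln Equal-length named amino-acid sequences.
#' @param nReplicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param correction Distance correction, as in \code{\link{pDistanceMatrix}}.
#' @return The full-data \code{phylo} tree with a numeric \code{supports}
#'   attribute and per-node labels holding supports (0-100).
#' @export
bootstrapSupport <- function(aln, nReplicates = 1000L, seed = 1L,
                             correction = "none") {
  if (nReplicates < 1L) stop("'nReplicates' must be >= 1")
  s <- .asCharSeqs(aln)
  m <- .alnCharMatrix(s)
  if (ncol(m) < 2L) stop("alignment must have at least 2 columns")
  full <- neighborJoining(pDistanceMatrix(s, correction))
  set.seed(as.integer(seed))
  nc <- ncol(m)
  counts <- integer(0)
  splitCount <- new.env(parent = emptyenv())
  for (rep_ in seq_len(nReplicates)) {
    cols <- sample.int(nc, nc, replace = TRUE)
    rs <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
    names(rs) <- names(s)
    bt <- neighborJoining(pDistanceMatrix(rs, correction))
    for (sp in .treeSplits(bt)) {
      prev <- if (is.null(splitCount[[sp]])) 0L else splitCount[[sp]]
      assign(sp, prev + 1L, envir = splitCount)
    }
  }
  fullSplits <- .treeSplits(full)
  support <- vapply(fullSplits, function(sp) {
    cnt <- if (is.null(splitCount[[sp]])) 0L else splitCount[[sp]]
    100 * cnt / nReplicates
  }, numeric(1))
  # attach supports to internal nodes: node label of the node whose clade
  # defines each split
  ntip <- length(full$tip.label)
  nodeLab <- rep("", full$Nnode)
  pp <- ape::prop.part(full)
  tips <- sort(full$tip.label)
  for (k in seq_along(pp)) {
    side <- sort(attr(pp, "labels")[pp[[k]]])
    if (tips[1] %in% side) side <- setdiff(tips, side)
    spKey <- paste(side, collapse = "\r")
    if (spKey %in% names(support))
      nodeLab[k] <- .fmtLen(support[[spKey]])
  }
  full$node.label <- nodeLab
  attr(full, "supports") <- support
  full
}

#' Mask low bootstrap supports for display
#'
#' Blanks node labels whose support is at or below the cutoff (the usual
#' ">50\%" display convention); the full supports remain available in the
#' \code{supports} attribute.
#'
#' @param tree Tree from \code{\link{bootstrapSupport}}.
#' @param cutoff Mask supports <= this value (default 50).
#' @return The tree with masked node labels.
#' @export
maskSupports <- function(tree, cutoff = 50) {
  lab <- tree$node.label
  num <- suppressWarnings(as.numeric(lab))
  lab[!is.na(num) & num <= cutoff] <- ""
  tree$node.label <- lab
  tree
}

#' Assign a host-range type (UA/CY) to an HcRNAV-derived variant
#'
#' The variant is typed UA (resp. CY) when its nearest panel neighbor by
#' percent identity is a UA-typed (resp. CY-typed) HcRNAV reference, that
#' identity strictly exceeds \code{minIdentity}, and the variant's leaf
#' falls inside a clade of the tree containing references of only that type
#' (operationally: some bipartition of the tree groups the variant with at
#' least one reference of the type and none of any other type). Otherwise
#' \code{unknown} -- variants falling outside known strain clades stay
#' unassigned.
#'
#' @param asvId Leaf label of the variant in \code{tree}.
#' @param seq The variant's amino-acid sequence.
#' @param panel A \linkS4class{ReferencePanel}; its typed HcRNAV accessions
#'   must appear as leaves of \code{tree}.
#' @param tree \code{phylo} tree containing the variant and the references.
#' @param minIdentity Identity the nearest reference must exceed (default 85).
#' @return \code{"UA"}, \code{"CY"} or \code{"unknown"}.
#' @export
assignHostRangeType <- function(asvId, seq, panel, tree, minIdentity = 85) {
  stopifnot(is(panel, "ReferencePanel"))
  if (!asvId %in% tree$tip.label) stop("tree lacks leaf: ", asvId)
  refs <- panelSequences(panel)
  pid <- vapply(refs, function(r) percentIdentity(seq, r), numeric(1))
  nearest <- names(refs)[order(-pid, names(refs))[1L]]
  type <- panelTypes(panel)[[nearest]]
  if (!type %in% c("UA", "CY") || pid[[nearest]] <= minIdentity)
    return("unknown")
  typed <- panelTypes(panel)[panelTypes(panel) %in% c("UA", "CY")]
  typeRefs <- names(typed)[typed == type]
  otherRefs <- names(typed)[typed != type]
  pp <- ape::prop.part(tree)
  labels <- attr(pp, "labels")
  allTips <- tree$tip.label
  for (cl in pp) {
    for (side in list(labels[cl], setdiff(allTips, labels[cl]))) {
      if (!asvId %in% side) next
      if (any(typeRefs %in% side) && !any(otherRefs %in% side) &&
          length(side) < length(allTips))
        return(type)
    }
  }
  "unknown"
}

#' Type every HcRNAV-derived ASV in a table
#'
#' Builds (or reuses) the NJ tree over the HcRNAV-derived variants plus the
#' typed panel references, and applies \code{\link{assignHostRangeType}} to
#' each variant.
#'
#' @param x Amino-acid \linkS4class{AsvTable} (HcRNAV-derived subset).
#' @param panel A \linkS4class{ReferencePanel}.
#' @param tree Optional prebuilt tree; built from the variants plus HcRNAV
#'   references when \code{NULL}.
#' @param minIdentity See \code{\link{assignHostRangeType}}.
#' @return Named character vector of types, one per ASV.
#' @export
assignHostRangeTypes <- function(x, panel, tree = NULL, minIdentity = 85) {
  seqs <- SummarizedExperiment::rowData(x)$sequence
  names(seqs) <- rownames(x)
  if (is.null(tree)) {
    hc <- panelGroups(panel) == "HcRNAV"
    refSeqs <- panelSequences(panel)[hc]
    aln <- c(seqs, refSeqs)
    if (length(aln) < 3L)
      stop("need at least 3 sequences (variants + references) to build a tree")
    tree <- neighborJoining(pDistanceMatrix(aln))
  }
  vapply(names(seqs), function(id)
    assignHostRangeType(id, seqs[[id]], panel, tree, minIdentity),
    character(1))
}
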