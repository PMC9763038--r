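# Seeded simulator of a layered sediment viral community: a clonally
# related reference panel with a planted hypervariable window, codon-aware
# strain evolution (synonymous changes accepted everywhere, nonsynonymous
# changes concentrated in the window), per-layer strain sampling, and
# error-bearing amplicon reads -- with full ground truth for every stage.

# amino acids whose codon sets back-translate to degeneracy <= 3, used for
# primer motifs so the planted primers stay within practical degeneracy
.LOW_DEG_AA <- c("M", "W", "F", "Y", "H", "K", "N", "D", "E", "C", "Q", "I")

#' Simulation configuration
#'
#' Defines the study conditions the simulator emulates: five sediment
#' layers, HcRNAV-dominant deep layers vs related-virus-dominant shallow
#' layers, a hypervariable window with an elevated nonsynonymous acceptance
#' rate flanked by frozen primer motifs, lognormal strain abundances,
#' 300-nt single-end reads covering the whole insert, and a per-base
#' substitution error rate. Everything is deterministic given \code{seed}.
#'
#' @param seed Integer master seed; every downstream random draw derives
#'   from it.
#' @param nLayers Number of sediment layers (default 5, i.e. five 3-cm
#'   slices of a 15-cm core).
#' @param layerNames Layer labels.
#' @param proportions \code{nLayers x 3} matrix of per-layer group
#'   proportions (columns \code{hcrnav}, \code{related},
#'   \code{background}), each row summing to 1. The default mimics the
#'   survey's qualitative profile: related viruses dominate the shallow
#'   layers, HcRNAV reaches 0.60 in the deep layers.
#' @param nStrains Community strains per group
#'   (\code{hcrnav}/\code{related}/\code{background}).
#' @param hcUaStrains How many of the HcRNAV community strains descend from
#'   UA-type references (the rest are CY-derived).
#' @param withinDivergence Per-site nucleotide proposal rate on the branch
#'   from a reference to a community strain (default 0.05).
#' @param typeDivergence Total proposal divergence separating the UA and CY
#'   sub-ancestors (default 0.10, split over the two branches).
#' @param groupDivergence Proposal rate on the branch from the shared
#'   ancestor to the related-virus ancestor (default 0.25).
#' @param nonsynAccept Acceptance probability of a nonsynonymous proposal
#'   outside the hypervariable window (default 0.02: strong purifying
#'   selection on the structural scaffold).
#' @param nonsynMultiplier Fold increase of nonsynonymous acceptance inside
#'   the window (default 50, capped at probability 1), emulating the
#'   host-range loop under diversifying pressure.
#' @param groupNonsynAccept Nonsynonymous acceptance outside the window on
#'   the deep between-group branch (default 0.5), so groups separate at the
#'   protein level.
#' @param insertAa Amino-acid lengths of the insert parts:
#'   \code{c(left, window, right)} between the two 7-aa primer motifs.
#' @param motifLen Primer motif length in amino acids.
#' @param padNt Untranslated padding on each side of the ORF.
#' @param readsPerLayer Reads sequenced per layer (default 1e5).
#' @param errorRate Per-base substitution error rate (default 1e-3).
#' @param readLength Nominal read length (default 300 nt; inserts are
#'   designed shorter, so single-end reads cover them fully).
#' @return A validated configuration list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(seed = 1L,
                             nLayers = 5L,
                             layerNames = c("0-3cm", "3-6cm", "6-9cm",
                                            "9-12cm", "12-15cm"),
                             proportions = NULL,
                             nStrains = c(hcrnav = 24L, related = 12L,
                                          background = 4L),
                             hcUaStrains = 16L,
                             withinDivergence = 0.05,
                             typeDivergence = 0.10,
                             groupDivergence = 0.25,
                             nonsynAccept = 0.02,
                             nonsynMultiplier = 50,
                             groupNonsynAccept = 0.5,
                             insertAa = c(left = 23L, window = 20L,
                                          right = 23L),
                             motifLen = 7L,
                             padNt = 30L,
                             readsPerLayer = 1e5L,
                             errorRate = 1e-3,
                             readLength = 300L) {
  if (is.null(proportions)) {
    shallow <- c(hcrnav = 0.05, related = 0.90, background = 0.05)
    deep <- c(hcrnav = 0.60, related = 0.35, background = 0.05)
    nDeep <- max(1L, floor(nLayers * 2 / 5))
    proportions <- rbind(
      matrix(shallow, nLayers - nDeep, 3, byrow = TRUE),
      matrix(deep, nDeep, 3, byrow = TRUE))
    colnames(proportions) <- names(shallow)
  }
  rownames(proportions) <- layerNames
  cfg <- list(seed = as.integer(seed), nLayers = as.integer(nLayers),
              layerNames = layerNames, proportions = proportions,
              nStrains = nStrains, hcUaStrains = as.integer(hcUaStrains),
              withinDivergence = withinDivergence,
              typeDivergence = typeDivergence,
              groupDivergence = groupDivergence,
              nonsynAccept = nonsynAccept,
              nonsynMultiplier = nonsynMultiplier,
              groupNonsynAccept = groupNonsynAccept,
              insertAa = insertAa, motifLen = as.integer(motifLen),
              padNt = as.integer(padNt),
              readsPerLayer = as.integer(readsPerLayer),
              errorRate = errorRate, readLength = as.integer(readLength))
  class(cfg) <- "SimulationConfig"
  stopifnot(length(layerNames) == nLayers,
            nrow(cfg$proportions) == nLayers,
            all(abs(rowSums(cfg$proportions) - 1) < 1e-9),
            all(unlist(cfg[c("withinDivergence", "typeDivergence",
                             "groupDivergence", "nonsynAccept",
                             "errorRate")]) >= 0),
            cfg$errorRate <= 1, cfg$hcUaStrains <= nStrains[["hcrnav"]])
  cfg
}

# ORF geometry helpers (0-based aa coordinates within the ORF)
.geometry <- function(cfg) {
  ml <- cfg$motifLen
  ins <- cfg$insertAa
  fwd <- c(0L, ml)
  left <- c(ml, ml + ins[["left"]])
  window <- c(left[2], left[2] + ins[["window"]])
  right <- c(window[2], window[2] + ins[["right"]])
  rev <- c(right[2], right[2] + ml)
  list(fwd = fwd, left = left, window = window, right = right, rev = rev,
       orfAa = rev[2], insert = c(fwd[2], rev[1]))
}

# codon-aware evolution along one branch; motif codons and stops are never
# touched. Returns the gene with realized substitution counts as attributes.
.evolveGene <- function(gene, geo, padNt, proposalRate, nonsynAcceptOut,
                        nonsynAcceptIn) {
  ch <- strsplit(gene, "")[[1]]
  bases <- c("A", "C", "G", "T")
  orfStart <- padNt                      # 0-based nt offset of the ORF
  orfLen <- geo$orfAa * 3L
  aaPos <- function(p) (p - orfStart) %/% 3L   # 0-based aa index of nt pos p
  inMotif <- function(a) (a >= geo$fwd[1] && a < geo$fwd[2]) ||
                         (a >= geo$rev[1] && a < geo$rev[2])
  inWindow <- function(a) a >= geo$window[1] && a < geo$window[2]
  nSyn <- 0L; nNonsynIn <- 0L; nNonsynOut <- 0L
  # pads mutate freely (untranslated)
  padIdx <- c(seq_len(padNt), padNt + orfLen + seq_len(length(ch) - padNt - orfLen))
  hit <- padIdx[runif(length(padIdx)) < proposalRate]
  for (p in hit) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
  # ORF: propose, classify, accept per class
  orfIdx <- padNt + seq_len(orfLen)
  hit <- orfIdx[runif(orfLen) < proposalRate]
  for (p in hit) {
    a <- aaPos(p - 1L)
    if (inMotif(a)) next
    cod0 <- padNt + 3L * a
    codon <- paste(ch[(cod0 + 1L):(cod0 + 3L)], collapse = "")
    newBase <- sample(setdiff(bases, ch[p]), 1L)
    newCodon <- codon
    substr(newCodon, p - cod0, p - cod0) <- newBase
    aaOld <- Biostrings::GENETIC_CODE[[codon]]
    aaNew <- Biostrings::GENETIC_CODE[[newCodon]]
    if (aaNew == "*") next
    if (aaNew == aaOld) {
      ch[p] <- newBase; nSyn <- nSyn + 1L
    } else {
      acc <- if (inWindow(a)) nonsynAcceptIn else nonsynAcceptOut
      if (runif(1) < acc) {
        ch[p] <- newBase
        if (inWindow(a)) nNonsynIn <- nNonsynIn + 1L
        else nNonsynOut <- nNonsynOut + 1L
      }
    }
  }
  structure(paste(ch, collapse = ""), nSyn = nSyn, nNonsynIn = nNonsynIn,
            nNonsynOut = nNonsynOut)
}

.randomOrfGene <- function(cfg, geo) {
  repeat {
    aa <- character(geo$orfAa)
    motifCols <- c(seq(geo$fwd[1], geo$fwd[2] - 1L),
                   seq(geo$rev[1], geo$rev[2] - 1L))
    aa[motifCols + 1L] <- sample(.LOW_DEG_AA, length(motifCols), replace = TRUE)
    others <- setdiff(seq_len(geo$orfAa), motifCols + 1L)
    aa[others] <- sample(.AA_LETTERS, length(others), replace = TRUE)
    fwdDeg <- degeneracyOf(backTranslate(paste(aa[geo$fwd[1]:geo$fwd[2]],
                                               collapse = "")))
    revDeg <- degeneracyOf(backTranslate(paste(aa[(geo$rev[1] + 1L):geo$rev[2]],
                                               collapse = "")))
    if (fwdDeg > 512 || revDeg > 512) next
    codons <- vapply(aa, function(r) sample(.CODONS_OF[[r]], 1L), character(1))
    pad1 <- paste(sample(c("A", "C", "G", "T"), cfg$padNt, replace = TRUE),
                  collapse = "")
    pad2 <- paste(sample(c("A", "C", "G", "T"), cfg$padNt, replace = TRUE),
                  collapse = "")
    return(paste0(pad1, paste(codons, collapse = ""), pad2))
  }
}

#' Generate a reference panel and community strains with known ground truth
#'
#' Builds a random ancestral MCP-like ORF whose two primer motifs flank a
#' planted hypervariable window, evolves a panel of eight references from it
#' (three HcRNAV strains -- UA- and CY-typed -- and five related viruses),
#' and evolves the community strains the reads will be sampled from. The
#' mutation model proposes nucleotide changes, classifies them as
#' synonymous or nonsynonymous, and accepts them per class: synonymous
#' changes everywhere, nonsynonymous changes rarely outside the window and
#' at \code{nonsynMultiplier}-fold higher acceptance inside it. Primer
#' motifs never mutate. Deterministic under \code{cfg$seed}.
#'
#' @param cfg A \code{\link{simulationConfig}}.
#' @return A list of class \code{"SimulatedPanel"}: \code{designAlignment}
#'   (full-ORF translations of the eight references), \code{refGenes} and
#'   \code{strainGenes} (nucleotide genes), \code{truth} (strain table,
#'   window and motif coordinates, ancestral gene), \code{cfg} and
#'   \code{geometry}.
#' @export
generateReferencePanel <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  geo <- .geometry(cfg)
  set.seed(cfg$seed)
  anc <- .randomOrfGene(cfg, geo)
  ev <- function(g, rate, accOut, accIn) .evolveGene(g, geo, cfg$padNt, rate,
                                                     accOut, accIn)
  accIn <- min(1, cfg$nonsynAccept * cfg$nonsynMultiplier)
  # HcRNAV side: UA and CY sub-ancestors, then three references (2 UA, 1 CY)
  uaAnc <- ev(anc, cfg$typeDivergence / 2, cfg$nonsynAccept, accIn)
  cyAnc <- ev(anc, cfg$typeDivergence / 2, cfg$nonsynAccept, accIn)
  refGenes <- c(
    HCRNAV_UA1 = ev(uaAnc, cfg$withinDivergence / 2, cfg$nonsynAccept, accIn),
    HCRNAV_UA2 = ev(uaAnc, cfg$withinDivergence / 2, cfg$nonsynAccept, accIn),
    HCRNAV_CY1 = ev(cyAnc, cfg$withinDivergence / 2, cfg$nonsynAccept, accIn))
  # related viruses: one deep branch, then five references
  relAnc <- ev(anc, cfg$groupDivergence, cfg$groupNonsynAccept, 1)
  rel <- vapply(1:5, function(i) ev(relAnc, cfg$withinDivergence,
                                    cfg$groupNonsynAccept, 1), character(1))
  names(rel) <- sprintf("RELATED_%02d", 1:5)
  refGenes <- c(refGenes, rel)
  refGroups <- c(rep("HcRNAV", 3), rep("Alvernaviridae_like", 5))
  refTypes <- c("UA", "UA", "CY", rep("unknown", 5))
  # community strains
  ns <- cfg$nStrains
  hcSources <- c(sample(c("HCRNAV_UA1", "HCRNAV_UA2"), cfg$hcUaStrains,
                        replace = TRUE),
                 rep("HCRNAV_CY1", ns[["hcrnav"]] - cfg$hcUaStrains))
  relSources <- sample(names(rel), ns[["related"]], replace = TRUE)
  strains <- list(); src <- character(0); grp <- character(0); typ <- character(0)
  for (i in seq_along(hcSources)) {
    strains[[sprintf("STRAIN_HC_%02d", i)]] <-
      ev(refGenes[[hcSources[i]]], cfg$withinDivergence, cfg$nonsynAccept, accIn)
    src <- c(src, hcSources[i]); grp <- c(grp, "hcrnav")
    typ <- c(typ, refTypes[match(hcSources[i], names(refGenes))])
  }
  for (i in seq_along(relSources)) {
    strains[[sprintf("STRAIN_REL_%02d", i)]] <-
      ev(refGenes[[relSources[i]]], cfg$withinDivergence,
         cfg$groupNonsynAccept, 1)
    src <- c(src, relSources[i]); grp <- c(grp, "related")
    typ <- c(typ, "unknown")
  }
  # background: unrelated sequences that still carry the primer motifs
  ancMotifs <- strsplit(anc, "")[[1]]
  for (i in seq_len(ns[["background"]])) {
    g <- .randomOrfGene(cfg, geo)
    gch <- strsplit(g, "")[[1]]
    for (iv in list(geo$fwd, geo$rev)) {
      nt <- cfg$padNt + (3L * iv[1] + 1L):(3L * iv[2])
      gch[nt] <- ancMotifs[nt]
    }
    strains[[sprintf("STRAIN_BG_%02d", i)]] <- paste(gch, collapse = "")
    src <- c(src, NA_character_); grp <- c(grp, "background")
    typ <- c(typ, "unknown")
  }
  strainGenes <- vapply(strains, as.character, character(1))
  orfNt <- function(g) substr(g, cfg$padNt + 1L, cfg$padNt + 3L * geo$orfAa)
  designAlignment <- Biostrings::AAStringSet(
    translateSeq(vapply(refGenes, orfNt, character(1))))
  names(designAlignment) <- names(refGenes)
  truth <- list(
    strains = data.frame(strain = names(strainGenes), group = grp,
                         type = typ, sourceRef = src,
                         stringsAsFactors = FALSE),
    refGroups = setNames(refGroups, names(refGenes)),
    refTypes = setNames(refTypes, names(refGenes)),
    windowAa = geo$window, motifs = list(fwd = geo$fwd, rev = geo$rev),
    ancestralGene = anc)
  structure(list(designAlignment = designAlignment, refGenes = refGenes,
                 strainGenes = strainGenes, truth = truth, cfg = cfg,
                 geometry = geo),
            class = "SimulatedPanel")
}

#' Primer pair at the planted motif positions
#'
#' Back-translates the frozen motif columns of the design alignment into
#' the degenerate pair the simulator plants; useful as a known-good pair
#' and as the reference point for \code{\link{designPrimerPairs}}.
#'
#' @param sim A \code{"SimulatedPanel"} from
#'   \code{\link{generateReferencePanel}}.
#' @return A \linkS4class{PrimerPair}.
#' @export
plantedPrimerPair <- function(sim) {
  geo <- sim$geometry
  aln <- as.character(sim$designAlignment)
  fwdMotif <- substr(aln[[1]], geo$fwd[1] + 1L, geo$fwd[2])
  revMotif <- substr(aln[[1]], geo$rev[1] + 1L, geo$rev[2])
  fSeq <- backTranslate(fwdMotif)
  rPlus <- backTranslate(revMotif)
  fwd <- new("DegeneratePrimer", iupacSeq = fSeq,
             degeneracy = degeneracyOf(fSeq), orientation = "forward",
             motifStartCol = as.integer(geo$fwd[1]),
             motifLength = as.integer(sim$cfg$motifLen))
  rev <- new("DegeneratePrimer", iupacSeq = revComp(rPlus),
             degeneracy = degeneracyOf(rPlus), orientation = "reverse",
             motifStartCol = as.integer(geo$rev[1]),
             motifLength = as.integer(sim$cfg$motifLen))
  new("PrimerPair", forward = fwd, reverse = rev,
      insertCols = as.integer(geo$insert),
      expectedInsertLenNt = 3L * (geo$insert[2] - geo$insert[1]))
}

# amplicon insert of one template under a pair; errors if none
.strainInsert <- function(gene, id, pair, maxMismatch) {
  amp <- amplify(setNames(gene, id), pair, maxMismatch = maxMismatch,
                 insertLenRange = c(30L, 10000L))
  if (nrow(amp) == 0L)
    stop("template ", id, " yields no amplicon under the supplied pair")
  amp[1L, , drop = FALSE]
}

#' Classification panel matching a primer pair
#'
#' Trims every reference gene to the insert amplified by \code{pair} and
#' returns the translated inserts as a \linkS4class{ReferencePanel}, so
#' classification operates on the same region as the reads.
#'
#' @param sim A \code{"SimulatedPanel"}.
#' @param pair The \linkS4class{PrimerPair} used for amplification.
#' @return A list with \code{panel} (the \code{ReferencePanel}) and
#'   \code{ntInserts} (nucleotide inserts, for the optional
#'   nucleotide-level call).
#' @export
classificationPanel <- function(sim, pair = plantedPrimerPair(sim)) {
  ins <- vapply(names(sim$refGenes), function(id)
    .strainInsert(sim$refGenes[[id]], id, pair, 0L)$insert, character(1))
  aa <- setNames(translateSeq(ins), names(sim$refGenes))
  panel <- referencePanel(aa, group = unname(sim$truth$refGroups),
                          hostType = unname(sim$truth$refTypes))
  list(panel = panel, ntInserts = ins)
}

#' Simulate layered amplicon reads from the community
#'
#' Samples strains per layer from the planted group proportions (strain
#' weights lognormal within each group), amplifies each strain with the
#' primer pair, and emits single-end reads covering the whole insert with
#' independent per-base substitution errors. Deterministic given the
#' configuration seed.
#'
#' @param sim A \code{"SimulatedPanel"}.
#' @param cfg Its \code{\link{simulationConfig}} (defaults to
#'   \code{sim$cfg}).
#' @param pair Primer pair to amplify with (default: the planted pair).
#' @param maxMismatch Primer mismatch tolerance during amplification
#'   (default 1: environmental templates diverge from the design panel).
#' @return A list of class \code{"SimulatedReads"}: \code{reads} (named
#'   character), \code{layers}, \code{truth} (per-read source strain,
#'   strain insert translations, window coordinates within the insert,
#'   realized per-layer group fractions, strain weights), and \code{pair}.
#' @export
simulateReads <- function(sim, cfg = sim$cfg, pair = plantedPrimerPair(sim),
                          maxMismatch = 1L) {
  stopifnot(inherits(sim, "SimulatedPanel"))
  if (cfg$readsPerLayer < 1L) stop("readsPerLayer must be positive")
  amps <- lapply(names(sim$strainGenes), function(id)
    .strainInsert(sim$strainGenes[[id]], id, pair, maxMismatch))
  names(amps) <- names(sim$strainGenes)
  inserts <- vapply(amps, function(a) a$insert, character(1))
  insStartNt <- amps[[1L]]$insert_start
  insAaStart <- (insStartNt - cfg$padNt) %/% 3L
  windowInsertAa <- sim$geometry$window - insAaStart
  st <- sim$truth$strains
  set.seed(cfg$seed + 1L)
  weights <- stats::rlnorm(nrow(st))
  names(weights) <- st$strain
  groups <- colnames(cfg$proportions)
  readsL <- list(); layersL <- list(); strainL <- list()
  realized <- matrix(0, cfg$nLayers, length(groups),
                     dimnames = list(cfg$layerNames, groups))
  for (l in seq_len(cfg$nLayers)) {
    nG <- as.integer(stats::rmultinom(1L, cfg$readsPerLayer,
                                      cfg$proportions[l, ]))
    perStrain <- integer(nrow(st)); names(perStrain) <- st$strain
    for (g in seq_along(groups)) {
      idx <- which(st$group == groups[g])
      if (nG[g] == 0L || !length(idx)) next
      perStrain[idx] <- as.integer(stats::rmultinom(1L, nG[g], weights[idx]))
    }
    realized[l, ] <- nG / cfg$readsPerLayer
    sel <- rep(st$strain, perStrain)
    readsL[[l]] <- unname(inserts[sel])
    strainL[[l]] <- sel
    layersL[[l]] <- rep(cfg$layerNames[l], length(sel))
  }
  reads <- unlist(readsL); layers <- unlist(layersL)
  srcStrain <- unlist(strainL)
  # per-base substitution errors
  if (cfg$errorRate > 0) {
    len <- nchar(reads)
    nErr <- stats::rbinom(length(reads), len, cfg$errorRate)
    bases <- c("A", "C", "G", "T")
    for (r in which(nErr > 0L)) {
      pos <- sample.int(len[r], nErr[r])
      for (p in pos)
        substr(reads[r], p, p) <- sample(setdiff(bases,
                                                 substr(reads[r], p, p)), 1L)
    }
  }
  names(reads) <- sprintf("read%07d", seq_along(reads))
  truth <- list(readStrain = setNames(srcStrain, names(reads)),
                strainInsertAa = setNames(translateSeq(inserts), names(inserts)),
                strainInsertNt = inserts,
                windowInsertAa = windowInsertAa,
                insertStartNt = insStartNt,
                realizedFractions = realized,
                plannedFractions = cfg$proportions,
                strainWeights = weights,
                strains = st)
  structure(list(reads = reads, layers = layers, truth = truth, pair = pair),
            class = "SimulatedReads")
}

#' Write simulated reads as FASTQ plus a layer table
#'
#' @param simReads A \code{"SimulatedReads"} object.
#' @param fastqPath Output FASTQ (all qualities \code{I}, Phred 40).
#' @param layerPath Output TSV with \code{read_id} and \code{layer}.
#' @export
writeSimulatedReads <- function(simReads, fastqPath, layerPath) {
  con <- file(fastqPath, "w")
  on.exit(close(con))
  q <- vapply(nchar(simReads$reads),
              function(n) paste(rep("I", n), collapse = ""), character(1))
  writeLines(paste0("@", names(simReads$reads), "\n", simReads$reads,
                    "\n+\n", q), con, sep = "\n")
  utils::write.table(
    data.frame(read_id = names(simReads$reads), layer = simReads$layers),
    layerPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fastqPath)
}

#' Score pipeline outputs against the planted ground truth
#'
#' Computes, per layer, the L1 distance between the recovered group
#' composition and the planted proportions; the Jaccard overlap between the
#' detected variable columns and the planted hypervariable window; the
#' UA/CY confusion matrix of host-range typing against each variant's
#' source-strain type; and the symmetric difference between the recovered
#' amino-acid variant set and the planted protein haplotypes (exact
#' equality is expected at error rate 0 when every haplotype is sampled at
#' least twice).
#'
#' @param result Output of \code{\link{runPipeline}} on the simulated reads.
#' @param simReads The \code{"SimulatedReads"} object the pipeline consumed.
#' @return A list: \code{compositionL1} (per layer), \code{maxCompositionL1},
#'   \code{regionJaccard}, \code{typeConfusion}, \code{typeAccuracy},
#'   \code{aaSetEqual}, \code{nMissingAa}, \code{nExtraAa}.
#' @export
evaluateRecovery <- function(result, simReads) {
  truth <- simReads$truth
  planted <- truth$plannedFractions
  # score recovery on the fully classified table: the <0.02% "Others"
  # pooling of the composition figure is a display convention, not a
  # classification outcome
  comp <- composeLayers(result$aaTable, result$classification,
                        othersMinFraction = 0)
  map <- c(hcrnav = "HcRNAV_derived", related = "Alvernaviridae_like",
           background = "Others")
  l1 <- vapply(rownames(planted), function(l)
    sum(abs(comp[l, map] - planted[l, ])), numeric(1))
  # variable-region recovery (insert aa coordinates)
  jac <- NA_real_
  if (!is.null(result$regions) && nrow(result$regions)) {
    varCols <- unlist(lapply(which(result$regions$label == "variable"),
                             function(i) seq(result$regions$start[i],
                                             result$regions$end[i] - 1L)))
    w <- truth$windowInsertAa
    winCols <- seq(w[1], w[2] - 1L)
    jac <- length(intersect(varCols, winCols)) /
      length(union(varCols, winCols))
  }
  # typing confusion against source-strain types
  confusion <- matrix(0L, 2, 3, dimnames = list(truth = c("UA", "CY"),
                                                assigned = c("UA", "CY",
                                                             "unknown")))
  if (!is.null(result$types) && length(result$types)) {
    aaSeqs <- SummarizedExperiment::rowData(result$hcTable)$sequence
    names(aaSeqs) <- rownames(result$hcTable)
    for (id in names(result$types)) {
      hits <- truth$strains$type[truth$strainInsertAa == aaSeqs[[id]]]
      hits <- unique(hits[hits %in% c("UA", "CY")])
      if (length(hits) == 1L)
        confusion[hits, result$types[[id]]] <-
          confusion[hits, result$types[[id]]] + 1L
    }
  }
  typed <- sum(confusion)
  typeAccuracy <- if (typed > 0) 100 * sum(diag(confusion[, 1:2])) / typed
                  else NA_real_
  # collapse correctness: planted haplotypes sampled >= 2 reads
  readCounts <- table(truth$readStrain)
  sampled <- names(readCounts)[readCounts >= 2L]
  plantedHap <- unique(unname(truth$strainInsertAa[sampled]))
  gotHap <- SummarizedExperiment::rowData(result$aaTable)$sequence
  list(compositionL1 = l1, maxCompositionL1 = max(l1), regionJaccard = jac,
       typeConfusion = confusion, typeAccuracy = typeAccuracy,
       aaSetEqual = setequal(plantedHap, gotHap),
       nMissingAa = length(setdiff(plantedHap, gotHap)),
       nExtraAa = length(setdiff(gotHap, plantedHap)))
}
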