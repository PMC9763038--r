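# End-to-end orchestration: reads -> nt ASVs -> singleton removal ->
# synonymous collapse -> abundance floor -> classification -> per-layer
# composition -> NJ tree, host-range typing and region segmentation of the
# HcRNAV-derived variants. The manifest reconciles record counts across
# stages.

#' Run the full amplicon survey pipeline
#'
#' Executes dereplication, singleton removal, synonymous collapse, the
#' relative-abundance floor, panel classification, per-layer composition,
#' and -- for the HcRNAV-derived variants -- neighbor-joining phylogeny
#' (optionally bootstrapped), UA/CY host-range typing and conserved/variable
#' region segmentation. Classification and composition operate on the full
#' collapsed table; the floor is applied before the phylogenetic stages,
#' matching an analysis that draws its tree from variants at or above
#' 0.02\% abundance.
#'
#' @param reads Character vector (or \code{DNAStringSet}) of amplicon reads.
#' @param layers Layer label per read.
#' @param panel \linkS4class{ReferencePanel} for classification and typing.
#' @param ntRefs Optional named nucleotide reference inserts for the
#'   supplementary nucleotide-level HcRNAV call.
#' @param hcThreshold Strict protein identity threshold for the
#'   HcRNAV-derived label (default 85).
#' @param relatedFloor Minimum identity to call a panel relative (default 40).
#' @param ntThreshold Strict nucleotide identity threshold (default 92).
#' @param abundanceFloor Relative-abundance floor (default 2e-4 = 0.02\%).
#' @param frame Reading frame of the trimmed insert (default 0).
#' @param bootstrapN Bootstrap replicates for the HcRNAV tree (0 = skip).
#' @param seed Seed for the bootstrap resampling.
#' @param mergeGap Region-segmentation merge gap (default 2).
#' @param minTypeIdentity Identity the nearest typed reference must exceed
#'   during host-range typing (default 85).
#' @param layerLevels Optional explicit layer ordering.
#' @return A list with the stage outputs: \code{ntTable}, \code{ntKept},
#'   \code{aaTable}, \code{collapseMap}, \code{aaKept},
#'   \code{classification}, \code{ntClassification} (or \code{NULL}),
#'   \code{composition}, \code{hcTable}, \code{tree}, \code{types},
#'   \code{profile}, \code{regions} and \code{manifest}.
#' @export
runPipeline <- function(reads, layers, panel, ntRefs = NULL,
                        hcThreshold = 85, relatedFloor = 40,
                        ntThreshold = 92, abundanceFloor = 2e-4,
                        frame = 0L, bootstrapN = 0L, seed = 1L,
                        mergeGap = 2L, minTypeIdentity = 85,
                        layerLevels = NULL) {
  nReads <- length(.asCharSeqs(reads))
  ntTable <- dereplicateReads(reads, layers, layerLevels)
  ntKept <- suppressMessages(removeSingletons(ntTable))
  singletonReads <- sum(asvCounts(ntTable)) - sum(asvCounts(ntKept))
  coll <- withCallingHandlers(
    collapseByTranslation(ntKept, frame = frame),
    warning = function(w) invokeRestart("muffleWarning"))
  aaTable <- coll$table
  stopDroppedReads <- sum(asvCounts(ntKept)) - sum(asvCounts(aaTable))
  classification <- classifyTable(aaTable, panel, hcThreshold, relatedFloor)
  composition <- composeLayers(aaTable, classification,
                               othersMinFraction = abundanceFloor)
  aaKept <- suppressMessages(abundanceFilter(aaTable, abundanceFloor))
  ntClassification <- if (!is.null(ntRefs))
    classifyNucleotide(ntKept, ntRefs, ntThreshold) else NULL

  hcIds <- rownames(aaKept)[classification[rownames(aaKept), "group"] ==
                              "HcRNAV_derived"]
  hcTable <- aaKept[hcIds, ]
  tree <- NULL; types <- NULL; profile <- NULL; regions <- NULL
  hcRefSeqs <- panelSequences(panel)[panelGroups(panel) == "HcRNAV"]
  hcSeqs <- SummarizedExperiment::rowData(hcTable)$sequence
  names(hcSeqs) <- rownames(hcTable)
  if (length(hcSeqs) + length(hcRefSeqs) >= 3L && length(hcSeqs) >= 1L) {
    aln <- c(hcSeqs, hcRefSeqs)
    if (length(unique(nchar(aln))) == 1L) {
      tree <- if (bootstrapN > 0L)
        bootstrapSupport(aln, nReplicates = bootstrapN, seed = seed)
      else neighborJoining(pDistanceMatrix(aln))
      types <- assignHostRangeTypes(hcTable, panel, tree = tree,
                                    minIdentity = minTypeIdentity)
    } else {
      warning("HcRNAV-derived variants and references differ in length; ",
              "provide an external alignment for the phylogenetic stages")
    }
  }
  if (length(hcSeqs) >= 2L && length(unique(nchar(hcSeqs))) == 1L) {
    profile <- columnPolymorphism(hcSeqs)
    regions <- segmentRegions(profile, mergeGap = mergeGap)
  }
  manifest <- list(
    counts = c(reads = nReads,
               nt_asvs = nrow(ntTable),
               nt_singletons_removed = nrow(ntTable) - nrow(ntKept),
               singleton_reads_removed = singletonReads,
               nt_retained = nrow(ntKept),
               internal_stop_reads_removed = stopDroppedReads,
               aa_asvs = nrow(aaTable),
               aa_below_floor = nrow(aaTable) - nrow(aaKept),
               aa_retained = nrow(aaKept),
               hcrnav_derived = length(hcIds)),
    thresholds = c(hcThreshold = hcThreshold, relatedFloor = relatedFloor,
                   ntThreshold = ntThreshold, abundanceFloor = abundanceFloor,
                   mergeGap = mergeGap, minTypeIdentity = minTypeIdentity,
                   bootstrapN = bootstrapN),
    frame = frame, seed = seed)
  list(ntTable = ntTable, ntKept = ntKept, aaTable = aaTable,
       collapseMap = coll$map, aaKept = aaKept,
       classification = classification,
       ntClassification = ntClassification, composition = composition,
       hcTable = hcTable, tree = tree, types = types, profile = profile,
       regions = regions, manifest = manifest)
}

#' Write the main pipeline outputs to a directory
#'
#' Emits the nucleotide and amino-acid ASV tables, the collapse map, the
#' classification and composition tables, the Newick tree (supports masked
#' at the conventional 50\% display cutoff), host-range types and region
#' calls, plus a manifest.
#'
#' @param result Output of \code{\link{runPipeline}}.
#' @param outDir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writePipelineOutputs <- function(result, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(outDir, f)
  writeAsvTable(result$ntKept, fp("asv_nt.tsv"))
  writeAsvTable(result$aaTable, fp("asv_aa.tsv"))
  utils::write.table(
    data.frame(aa_asv = names(result$collapseMap),
               members = vapply(result$collapseMap, paste, character(1),
                                collapse = ",")),
    fp("collapse_map.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(asv_id = rownames(result$classification),
               as.data.frame(result$classification)),
    fp("classification.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(layer = rownames(result$composition), result$composition,
               check.names = FALSE),
    fp("composition.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$tree))
    ape::write.tree(maskSupports(result$tree), fp("hcrnav_tree.nwk"))
  if (!is.null(result$types))
    utils::write.table(
      data.frame(asv_id = names(result$types), type = result$types),
      fp("host_range_types.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  if (!is.null(result$regions))
    writeRegionsTsv(result$regions, fp("regions.tsv"))
  manifest <- c(result$manifest$counts, result$manifest$thresholds,
                frame = result$manifest$frame, seed = result$manifest$seed)
  utils::write.table(
    data.frame(key = names(manifest), value = unlist(manifest)),
    fp("manifest.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outDir)
}
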