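---
title: "Surveying viral capsid-gene diversity by degenerate PCR: models and methods"
author: "capsidSurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying viral capsid-gene diversity by degenerate PCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsidSurvey)
```

## The problem

HcRNAV, the RNA virus of the bloom-forming dinoflagellate *Heterocapsa
circularisquama*, is the only cultured dinoflagellate-infecting RNA virus.
Its major capsid protein (MCP) gene carries hypervariable regions linked to
intraspecific host range: strains fall into complementary UA and CY host-range
types. Because close relatives of HcRNAV resist isolation, their diversity in
the environment is best probed by amplicon sequencing with *degenerate
primers*: oligonucleotides written in the IUPAC ambiguity alphabet that encode
every codon combination of a conserved amino-acid motif, so that a single
primer pair amplifies a whole clade of diverged genes across conserved regions
flanking a hypervariable window.

`capsidSurvey` implements that survey end to end as testable desk software:
primer design, in-silico PCR, condensation of reads into amplicon sequence
variants (ASVs), identity-based classification, per-layer community
composition, neighbor-joining (NJ) phylogenetics with host-range typing, and
conserved/variable region calling — together with a fully seeded simulator of
a layered sediment community that supplies ground truth for every stage.

## Primer design

Design starts from a protein alignment of reference MCP sequences (the
simulated panel mirrors a design set of eight: three HcRNAV strains and five
related viruses from metagenomes). `findConservedMotifs()` scans every window
of `windowLen` alignment columns (default 7 aa, i.e. 21-nt primers) and keeps
windows that are gap-free with at most `maxVariants` distinct residues per
column (default 1). `backTranslate()` pools the standard-code codons of every
residue in each column and encodes each codon position as the *minimal* IUPAC
code covering the pooled bases. Over-coverage is one-sided and expected:
leucine alone back-translates to `YTN`, 8 expansions of which 6 encode Leu.
`degeneracyOf()` is the product of per-position base-set sizes;
`designPrimerPairs()` enumerates motif pairs flanking the designated
hypervariable column interval, keeps pairs within `maxDegeneracy` (default
512, typical degenerate-PCR practice) and an expected-insert-length range, and
ranks them by degeneracy product, then insert length, then position. Melting
temperature is reported informationally (Wallace rule averaged over
expansions) but never used as a constraint.

Because columns adjacent to a planted motif can be conserved across a small
panel by chance, the top-ranked pair may extend one column into a flank that
is *not* conserved in the wider community; the simulator therefore amplifies
with the planted (known-good) pair by default, while design is validated by
the invariant that every designed primer matches all eight panel references
with zero mismatches.

## In-silico PCR

`findBindingSites()` reports every window on either strand matching a primer
with at most `maxMismatch` mismatches, where a position matches when the
template base belongs to the primer code's base set (the window search runs on
`Biostrings::matchPattern` with pattern ambiguities as wildcards).
`amplify()` pairs forward sites with reverse sites on the opposite
orientation whose 3' ends face each other — in both senses of the template,
so amplification is strand-symmetric — and reports the primer-trimmed insert
on the forward primer's strand. All insert-length-compatible site
combinations are reported; no shortest-product heuristic or thermodynamic
model is applied. Default mismatch tolerance is 0 for design validation and 1
for community simulation, since environmental templates diverge from the
design panel.

## ASV condensation

Reads are dereplicated exactly (`dereplicateReads()`): every distinct
sequence becomes a nucleotide ASV with per-layer counts. Exact dereplication
is this package's stand-in for error-model denoising; with low-error simulated
reads the singleton filter (`removeSingletons()`, total count 1 summed over
layers, since the survey pools layers into one analysis) removes the bulk of
one-off sequencing errors, and duplicated error reads that survive are
subsequently suppressed by the abundance floor. `collapseByTranslation()`
translates each variant in frame 0 — the forward primer is designed in codon
phase, so the trimmed insert starts on a codon boundary — drops variants with
internal stops, and merges synonymous variants into amino-acid ASVs named
`ASV_001, ASV_002, ...` by decreasing abundance, with an `s` suffix marking
condensed synonymous groups. `abundanceFilter()` applies the relative
abundance floor (default 0.02%, inclusive at the boundary) *after* collapsing,
since the downstream tree is drawn from amino-acid variants.

## Classification and composition

Each amino-acid ASV is scored by percent identity against a packaged
reference panel (`classifyAsv()`), replacing a database BLAST search whose
hit counts depend on database versions. Equal-length sequences are compared
positionwise; otherwise a global Needleman–Wunsch alignment is used with
match +1, mismatch 0, and a linear gap penalty of −1 that steers the path
only, identity being matches over alignment columns; the traceback prefers
diagonal, then a gap in the second sequence, so results are deterministic.
Since the survey's "homology" percentages are not tied to a specific local
alignment definition, global identity is used and recorded as this package's
choice. The rule is: HcRNAV-derived if best identity to an HcRNAV entry
*strictly exceeds* 85% (a hit at exactly 85.0 is not HcRNAV-derived);
otherwise a panel relative at ≥ `relatedFloor` (default 40%, separating
panel-related sequences from noise); otherwise unassigned. A supplementary
strict 92% nucleotide-level call is available (`classifyNucleotide()`).

`composeLayers()` sums reads per layer by group, pooling unassigned variants
and variants under the floor into an `Others` bucket, as composition figures
of this kind do. When recovery is scored against planted proportions
(`evaluateRecovery()`), composition is recomputed without the floor pooling:
the bucket is a display convention, and counting correctly classified
low-abundance error variants as `Others` would misstate classification
accuracy.

## Phylogeny, bootstrap and host-range typing

Distances are uncorrected p-distances on amino acids (`pDistanceMatrix()`);
the amplicons are short and closely related, where p-distance is standard for
NJ figures, and a Poisson correction is available behind a flag.
`neighborJoining()` is the classic Saitou–Nei agglomeration with the Q
criterion; ties in Q are broken by the lexicographically smallest pair of
cluster labels (a cluster is labeled by its smallest leaf), so trees are
bit-reproducible; negative branch-length estimates are clamped to zero with
the deficit recorded. On additive matrices the generating topology and branch
lengths are recovered exactly (the test suite checks this against `ape::nj`
and against cophenetic round trips on random trees). `bootstrapSupport()`
resamples alignment columns with replacement (default 1000 replicates),
rebuilds the tree per replicate, and scores each internal bipartition of the
full-data tree by the percentage of replicates containing it; all supports
are stored, and `maskSupports()` applies the conventional "show >50%"
display rule. `assignHostRangeType()` types an HcRNAV-derived variant UA or
CY when its nearest panel reference by identity carries that type, the
identity strictly exceeds 85%, and some bipartition of the tree groups the
variant with references of only that type — variants outside known strain
clades stay `unknown`.

## Conserved and variable regions

`columnPolymorphism()` counts distinct residues per alignment column, with
gaps excluded by default (a deletion is not a residue polymorphism;
`countGaps` flips this). `segmentRegions()` labels columns with ≥2 residues
polymorphic, takes maximal polymorphic runs, merges runs separated by at most
`mergeGap` monomorphic columns (default 2), and tiles the alignment with
alternating conserved/variable intervals (0-based, half-open). The
granularity of the published region definition is ambiguous — "≤1
polymorphism" can be read per column or per region — and the per-column run
reading implemented here is an interpretation, not an assertion about the
original analysis. `mapRegionsToReference()` converts region intervals to
ungapped reference coordinates for external structure annotation (secondary
structure and 3D placement are deliberately out of scope; the TSV output is
the hook).

## The simulator and what it does (and does not) emulate

`simulationConfig()` fixes the study conditions: five 3-cm sediment layers;
per-layer group proportions mimicking the survey's qualitative profile
(related viruses dominate the shallow layers at 0.90, HcRNAV reaches 0.60 in
the two deep layers, with a 0.05 background everywhere); 300-nt single-end
reads that cover the whole ~200-nt insert, avoiding merge logic; and a
per-base substitution error rate of 10^-3 (no indel errors, no chimeras, no
PCR bias). The ancestral MCP-like ORF is 80 codons: two frozen 7-aa primer
motifs (drawn from low-degeneracy amino acids so planted primers stay within
practical degeneracy) flanking a 66-aa insert whose central 20 columns are
the hypervariable window.

Evolution is codon-aware: a nucleotide change is proposed per site at the
branch's divergence rate, classified synonymous or nonsynonymous, and
accepted per class — synonymous changes always, nonsynonymous changes at 0.02
outside the window (strong purifying selection on the β-strand scaffold) and
50-fold higher (capped at 1) inside it, emulating the diversifying host-range
loop. Branch rates: 0.25 to the related-virus ancestor (with relaxed outside
acceptance 0.5 so the groups separate at the protein level to ~70% identity,
between the 40% relative floor and the 85% HcRNAV threshold), 0.05 per side
between the UA and CY sub-ancestors, and 0.05 from a reference to each
community strain — so community variants sit ~95% identical to their source
reference, comfortably above the strict 85% rule, and UA/CY types remain
separable. Default strain numbers (24 HcRNAV, 12 related, 4 background)
keep the HcRNAV-derived cohort at or above the ~20-variant scale at which
region segmentation is meaningful. Background strains are random inserts
carrying the intact primer motifs: they amplify but classify as unassigned.

Strain abundances are lognormal within groups; reads are multinomial per
layer at 10^5 reads per layer by default. Everything derives from the single
seed, so panels, reads and FASTQ output are byte-identical across reruns.

What passing tests show — and what they do not: exact dereplication plus the
singleton and abundance filters recover planted haplotypes exactly only at
zero sequencing error; at realistic error rates the pipeline's composition
and typing remain accurate, but real amplicon data additionally contain
chimeras, indel errors, primer bias and unequal amplification efficiency,
none of which are modeled. Planted-window recovery is scored by Jaccard
overlap between detected variable regions and the window; incidental
background polymorphisms (real, planted, but 50-fold rarer) can inflate the
detected variable territory, so the overlap fluctuates around ~0.8 across
seeds even though the window itself is essentially always fully detected.

## Numerical choices and degenerate inputs

All coordinates are 0-based, half-open; strand is `+`/`-`. Uppercase is
normalized on input and `U` maps to `T`. Degenerate sequences are never
translated (an error by design). Ties are deterministic throughout: NJ joins
by smallest label pair, best-reference reporting by accession, alignment
traceback by diagonal-first. Thresholds follow the printed rules exactly:
strict `>85` (protein) and `>92` (nucleotide) identity, inclusive `≥0.02%`
abundance. Empty tables, all-singleton inputs, zero-read layers and
primerless templates return empty results with warnings rather than errors
where the operation's contract allows it.

## Problem sizes

The default test and validation runs use 5 × 10^5 simulated reads for the
survey-scale checks, 200 random 4–8-leaf additive matrices for NJ
exactness, 500 random template/primer pairs for the in-silico PCR oracle
comparison, 500 random motifs for back-translation, and 1000 bootstrap
replicates — sizes chosen so the whole validation completes in about a
minute on one CPU while leaving the statistical checks meaningful.

## Limitations

No thermodynamic primer model (dimers, hairpins, Tm constraints); no
error-model denoising (the dereplication surrogate is documented above); no
chimera detection; no maximum-likelihood or Bayesian phylogenetics; no
dN/dS or entropy-based variability statistics; no structure prediction. The
classification is a three-way rule against a packaged panel, not taxonomy.
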