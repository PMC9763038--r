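#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom Biostrings DNAString DNAStringSet AAStringSet BStringSet
#'   readBStringSet writeXStringSet reverseComplement matchPattern
#'   GENETIC_CODE IUPAC_CODE_MAP
#' @importFrom stats setNames rbinom rlnorm runif
#' @importFrom utils read.delim write.table head
NULL

# IUPAC nucleotide algebra ----------------------------------------------------

.IUPAC <- Biostrings::IUPAC_CODE_MAP  # code -> string of bases, e.g. R -> "AG"

# reverse lookup: sorted base-set string -> minimal covering code
.IUPAC_REV <- local({
  key <- vapply(strsplit(.IUPAC, ""), function(b) paste(sort(b), collapse = ""),
                character(1))
  setNames(names(.IUPAC), key)
})

#' Expand an IUPAC nucleotide code to its base set
#'
#' @param code A single IUPAC nucleotide character (one of the 15 defined
#'   ambiguity codes, e.g. \code{"R"} for A/G, \code{"N"} for A/C/G/T).
#' @return Character vector of the unambiguous bases the code stands for.
#' @examples
#' expandIupac("R")  # A G
#' expandIupac("N")  # A C G T
#' @export
expandIupac <- function(code) {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 1L)
    stop("'code' must be a single character")
  code <- toupper(code)
  if (!code %in% names(.IUPAC))
    stop("unknown IUPAC nucleotide code: '", code, "'")
  strsplit(.IUPAC[[code]], "")[[1]]
}

#' Minimal IUPAC code covering a set of bases
#'
#' @param bases Character vector drawn from A, C, G, T.
#' @return The single IUPAC code whose base set equals \code{bases}.
#' @export
iupacCode <- function(bases) {
  bases <- unique(toupper(bases))
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("bases must be drawn from A, C, G, T")
  .IUPAC_REV[[paste(sort(bases), collapse = "")]]
}

.checkNt <- function(x, what = "sequence", allowGap = FALSE) {
  legal <- names(.IUPAC)
  if (allowGap) legal <- c(legal, "-")
  bad <- setdiff(unique(unlist(strsplit(x, ""))), legal)
  if (length(bad))
    stop("illegal nucleotide character(s) in ", what, ": ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

.AA_LETTERS <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V")

.checkAa <- function(x, what = "sequence", allowGap = TRUE) {
  legal <- c(.AA_LETTERS, "*")
  if (allowGap) legal <- c(legal, "-")
  bad <- setdiff(unique(unlist(strsplit(x, ""))), legal)
  if (length(bad))
    stop("illegal amino-acid character(s) in ", what, ": ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

# coerce XStringSet / named character to named character
.asCharSeqs <- function(x) {
  if (is(x, "XStringSet")) {
    s <- as.character(x)
    names(s) <- names(x)
    s
  } else if (is.character(x)) {
    x
  } else stop("expected a character vector or XStringSet")
}

# FASTA / FASTQ / TSV I/O -----------------------------------------------------

#' Read a FASTA file into an XStringSet with strict checks
#'
#' Headers are truncated at the first whitespace; sequences are uppercased and,
#' for nucleotide input, \code{U} is mapped to \code{T} (RNA virus genomes are
#' deposited both ways). Duplicate ids and empty files are errors.
#'
#' @param path Path to a FASTA file.
#' @param alphabet \code{"nt"} or \code{"aa"}.
#' @return A \code{DNAStringSet} (\code{nt}) or \code{AAStringSet} (\code{aa}).
#' @export
readSeqFasta <- function(path, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(x))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  s <- toupper(as.character(x))
  if (alphabet == "nt") {
    s <- chartr("U", "T", s)
    .checkNt(s, allowGap = TRUE)
    out <- Biostrings::DNAStringSet(s)
  } else {
    .checkAa(s)
    out <- Biostrings::AAStringSet(s)
  }
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param x Named character vector or XStringSet.
#' @param path Output path.
#' @export
writeSeqFasta <- function(x, path) {
  s <- .asCharSeqs(x)
  if (is.null(names(s)) || any(!nzchar(names(s))))
    stop("all sequences must be named")
  Biostrings::writeXStringSet(Biostrings::BStringSet(s), path, width = 70L)
  invisible(path)
}

#' Read amplicon reads from FASTA or FASTQ
#'
#' Format is inferred from the extension (\code{.fq}/\code{.fastq} vs
#' \code{.fa}/\code{.fasta}). An optional mean-quality cutoff drops FASTQ
#' reads whose average Phred score falls below it; qualities are otherwise
#' unused.
#'
#' @param path Reads file.
#' @param minMeanQ Optional minimum mean Phred quality (FASTQ only).
#' @return Named character vector of uppercase read sequences.
#' @export
readAmpliconReads <- function(path, minMeanQ = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  isFastq <- grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)
  if (isFastq) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    if (!is.null(minMeanQ)) {
      q <- as.character(S4Vectors::mcols(x)$qualities)
      meanQ <- vapply(q, function(ch) mean(utf8ToInt(ch) - 33L), numeric(1))
      x <- x[meanQ >= minMeanQ]
    }
  } else {
    x <- readSeqFasta(path, "nt")
  }
  if (length(x) == 0L) stop("no reads in ", path)
  s <- toupper(as.character(x))
  s <- chartr("U", "T", s)
  names(s) <- sub("\\s.*$", "", names(x))
  s
}

#' Read a sample/layer metadata table
#'
#' Expects a TSV with a read/sample id column (\code{read_id} or
#' \code{sample}) and a \code{layer} column.
#'
#' @param path TSV path.
#' @return data.frame with columns \code{id} and \code{layer}.
#' @export
readLayerTable <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  idCol <- intersect(c("read_id", "sample", "id"), names(d))[1]
  if (is.na(idCol) || !"layer" %in% names(d))
    stop("layer table must have a 'read_id'/'sample' column and a 'layer' column")
  data.frame(id = as.character(d[[idCol]]), layer = as.character(d$layer),
             stringsAsFactors = FALSE)
}

# Translation and reverse complement ------------------------------------------

#' Translate an unambiguous nucleotide sequence
#'
#' Uses the standard genetic code; the trailing partial codon is dropped and
#' stop codons are emitted as \code{*}. Degenerate (ambiguous) input is an
#' error by design: degenerate primers are never translated.
#'
#' @param nt Character vector of A/C/G/T sequences.
#' @param frame Reading frame offset, 0, 1 or 2.
#' @return Character vector of amino-acid sequences.
#' @examples
#' translateSeq("ATGAAA")      # "MK"
#' translateSeq("AATGAAA", 1)  # "MK"
#' @export
translateSeq <- function(nt, frame = 0L) {
  if (!frame %in% 0:2) stop("'frame' must be 0, 1 or 2")
  nt <- toupper(nt)
  bad <- setdiff(unique(unlist(strsplit(nt, ""))), c("A", "C", "G", "T"))
  if (length(bad))
    stop("cannot translate: ambiguous or illegal base(s): ",
         paste(bad, collapse = ", "))
  vapply(nt, function(s) {
    n <- nchar(s) - frame
    if (n < 3L) stop("sequence too short to translate in frame ", frame)
    ncod <- n %/% 3L
    starts <- frame + 1L + 3L * (seq_len(ncod) - 1L)
    codons <- substring(s, starts, starts + 2L)
    paste(Biostrings::GENETIC_CODE[codons], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' IUPAC-aware reverse complement
#'
#' Complements every IUPAC ambiguity code (R<->Y, K<->M, B<->V, D<->H,
#' S, W and N self-complementary) and reverses the sequence.
#'
#' @param nt Character vector of IUPAC nucleotide sequences.
#' @return Character vector of reverse complements.
#' @examples
#' revComp("GATTACA")  # "TGTAATC"
#' revComp("ARY")      # "RYT"
#' @export
revComp <- function(nt) {
  nt <- toupper(nt)
  .checkNt(nt)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(nt)))
}
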