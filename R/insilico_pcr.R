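# IUPAC-aware in-silico PCR: primer binding-site search and amplicon
# extraction. Window search delegates to Biostrings::matchPattern with the
# pattern's ambiguity codes treated as wildcards (fixed = "subject").

#' Count primer/template mismatches under IUPAC matching
#'
#' A position matches when the (unambiguous) template base is a member of the
#' primer code's base set.
#'
#' @param primer IUPAC nucleotide string.
#' @param window Unambiguous template window of the same length.
#' @return Integer mismatch count.
#' @examples
#' iupacMismatches("AAR", "AAG")  # 0
#' iupacMismatches("AAR", "AAC")  # 1
#' @export
iupacMismatches <- function(primer, window) {
  if (nchar(primer) != nchar(window))
    stop("primer and window must have equal length")
  pc <- strsplit(toupper(primer), "")[[1]]
  wc <- strsplit(toupper(window), "")[[1]]
  .checkNt(primer, "primer")
  bad <- setdiff(unique(wc), c("A", "C", "G", "T"))
  if (length(bad)) stop("window must be unambiguous A/C/G/T, found: ",
                        paste(bad, collapse = ", "))
  sets <- .IUPAC[pc]
  sum(!vapply(seq_along(pc), function(i) grepl(wc[i], sets[i], fixed = TRUE),
              logical(1)))
}

.primerChar <- function(primer) {
  if (is(primer, "DegeneratePrimer")) primer@iupacSeq
  else if (is.character(primer) && length(primer) == 1L) toupper(primer)
  else stop("expected a DegeneratePrimer or a single IUPAC string")
}

.templateChar <- function(template) {
  s <- .asCharSeqs(template)
  if (length(s) != 1L) stop("expected a single template sequence")
  id <- if (!is.null(names(s))) names(s) else "template"
  list(id = id, seq = toupper(unname(s)))
}

#' Find primer binding sites on both strands of a template
#'
#' Reports every window, on either strand, matching the primer with at most
#' \code{maxMismatch} mismatches under IUPAC matching. A \code{-} strand site
#' means the primer matches the reverse complement of the window (i.e. the
#' primer anneals to the plus strand and extends leftward).
#'
#' @param template Unambiguous nucleotide sequence (named character or
#'   \code{DNAStringSet} of length 1).
#' @param primer \linkS4class{DegeneratePrimer} or IUPAC string.
#' @param maxMismatch Maximum tolerated mismatches (default 0).
#' @return data.frame with columns \code{template_id}, \code{start} (0-based),
#'   \code{strand} and \code{mismatches}, sorted by start.
#' @export
findBindingSites <- function(template, primer, maxMismatch = 0L) {
  tp <- .templateChar(template)
  p <- .primerChar(primer)
  if (nchar(p) > nchar(tp$seq))
    return(data.frame(template_id = character(0), start = integer(0),
                      strand = character(0), mismatches = integer(0)))
  subj <- Biostrings::DNAString(tp$seq)
  hits <- function(pat, strand) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj,
                                  max.mismatch = maxMismatch,
                                  fixed = "subject")
    if (length(m) == 0L)
      return(NULL)
    st <- BiocGenerics::start(m) - 1L
    win <- as.character(m)
    mm <- vapply(win, function(w) iupacMismatches(pat, w), integer(1),
                 USE.NAMES = FALSE)
    data.frame(template_id = tp$id, start = st, strand = strand,
               mismatches = mm, stringsAsFactors = FALSE)
  }
  out <- rbind(hits(p, "+"), hits(revComp(p), "-"))
  if (is.null(out))
    return(data.frame(template_id = character(0), start = integer(0),
                      strand = character(0), mismatches = integer(0)))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract amplicons from a template with a degenerate primer pair
#'
#' Pairs every forward-primer site with every reverse-primer site on the
#' opposite orientation whose 3' ends face each other, in both senses of the
#' template, and reports the primer-trimmed insert on the forward primer's
#' strand. All combinations within the insert-length range are reported; no
#' shortest-product heuristic is applied.
#'
#' @param template Unambiguous nucleotide sequence.
#' @param pair \linkS4class{PrimerPair}.
#' @param maxMismatch Maximum mismatches per primer site.
#' @param insertLenRange Allowed trimmed insert length (nt), inclusive.
#' @param keepPrimers If \code{TRUE}, report the full product including the
#'   primer-binding regions instead of the trimmed insert.
#' @return data.frame with one row per product: \code{template_id},
#'   \code{insert} (sequence), \code{insert_start}/\code{insert_end}
#'   (0-based half-open, template coordinates), \code{strand},
#'   \code{fwd_start}, \code{rev_start}, \code{fwd_mismatches},
#'   \code{rev_mismatches}.
#' @export
amplify <- function(template, pair, maxMismatch = 0L,
                    insertLenRange = c(1L, 10000L), keepPrimers = FALSE) {
  stopifnot(is(pair, "PrimerPair"))
  tp <- .templateChar(template)
  lf <- nchar(pair@forward@iupacSeq)
  lr <- nchar(pair@reverse@iupacSeq)
  fSites <- findBindingSites(template, pair@forward, maxMismatch)
  rSites <- findBindingSites(template, pair@reverse, maxMismatch)
  empty <- data.frame(template_id = character(0), insert = character(0),
                      insert_start = integer(0), insert_end = integer(0),
                      strand = character(0), fwd_start = integer(0),
                      rev_start = integer(0), fwd_mismatches = integer(0),
                      rev_mismatches = integer(0))
  out <- empty
  # sense products: forward primer on '+', reverse primer on '-', downstream
  fPlus <- fSites[fSites$strand == "+", , drop = FALSE]
  rMinus <- rSites[rSites$strand == "-", , drop = FALSE]
  for (i in seq_len(nrow(fPlus))) for (j in seq_len(nrow(rMinus))) {
    a <- fPlus$start[i]; b <- rMinus$start[j]
    if (b < a + lf) next
    ins <- substr(tp$seq, a + lf + 1L, b)
    if (nchar(ins) < insertLenRange[1] || nchar(ins) > insertLenRange[2]) next
    if (keepPrimers) ins <- substr(tp$seq, a + 1L, b + lr)
    out <- rbind(out, data.frame(
      template_id = tp$id, insert = ins, insert_start = a + lf,
      insert_end = b, strand = "+", fwd_start = a, rev_start = b,
      fwd_mismatches = fPlus$mismatches[i],
      rev_mismatches = rMinus$mismatches[j], stringsAsFactors = FALSE))
  }
  # antisense products: forward primer on '-', reverse primer on '+', upstream
  fMinus <- fSites[fSites$strand == "-", , drop = FALSE]
  rPlus <- rSites[rSites$strand == "+", , drop = FALSE]
  for (i in seq_len(nrow(fMinus))) for (j in seq_len(nrow(rPlus))) {
    a <- fMinus$start[i]; b <- rPlus$start[j]
    if (b + lr > a) next
    ins <- revComp(substr(tp$seq, b + lr + 1L, a))
    if (nchar(ins) < insertLenRange[1] || nchar(ins) > insertLenRange[2]) next
    if (keepPrimers) ins <- revComp(substr(tp$seq, b + 1L, a + lf))
    out <- rbind(out, data.frame(
      template_id = tp$id, insert = ins, insert_start = b + lr,
      insert_end = a, strand = "-", fwd_start = a, rev_start = b,
      fwd_mismatches = fMinus$mismatches[i],
      rev_mismatches = rPlus$mismatches[j], stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
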