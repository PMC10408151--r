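#' Pairwise alignment scoring for isoform reconciliation
#'
#' Local affine-gap scoring used to reconcile alignment isoforms with
#' canonical sequences: match +5, mismatch -4, gap open -4, gap extend
#' -0.5, where the opening score applies to the first gapped residue and
#' the extension score to each subsequent one.
#'
#' @param match Match score.
#' @param mismatch Mismatch score.
#' @param gapOpen Score of the first residue of a gap (negative).
#' @param gapExtend Score of each further gap residue (negative).
#' @return List of class \code{"AlignmentScoring"}.
#' @export
alignmentScoring <- function(match = 5, mismatch = -4, gapOpen = -4,
                             gapExtend = -0.5) {
  structure(list(match = match, mismatch = mismatch, gapOpen = gapOpen,
                 gapExtend = gapExtend), class = "AlignmentScoring")
}

.substitutionMatrix <- function(scoring) {
  letters <- c(AA_STANDARD, .UNKNOWN)
  m <- matrix(scoring$mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- scoring$match
  m[.UNKNOWN, .UNKNOWN] <- scoring$mismatch  # unknowns never match
  m
}

#' Project an isoform-anchored MSA onto a canonical sequence
#'
#' When an alignment was built for a different isoform than the canonical
#' protein, a local pairwise alignment (affine gaps, see
#' \code{\link{alignmentScoring}}) of the alignment's query against the
#' canonical sequence defines a column map. Only the aligned fragment is
#' retained; canonical positions outside it (or opposite a gap) are
#' marked uncovered, so their alignment features are treated as missing
#' and completed later by within-gene imputation.
#'
#' @param msa \linkS4class{AnchoredMSA} anchored to the isoform query.
#' @param canonical Canonical amino-acid sequence (string).
#' @param scoring An \code{\link{alignmentScoring}}.
#' @return An \linkS4class{AnchoredMSA} anchored to \code{canonical},
#'   with \code{covered} FALSE at unmatched canonical positions. A best
#'   local score <= 0 yields an all-uncovered alignment, not an error.
#' @export
projectToQuery <- function(msa, canonical,
                           scoring = alignmentScoring()) {
  canonical <- toupper(canonical)
  L <- nchar(canonical)
  if (L < 1L) stop("canonical sequence must be non-empty")
  if (msa@query == canonical) {
    out <- msa
    out@covered <- rep(TRUE, L)
    return(out)
  }
  map <- projectionMap(msa, canonical, scoring)
  covered <- !is.na(map)
  rowMat <- do.call(rbind, strsplit(msa@rows, ""))
  out <- matrix(.GAP, nrow = nrow(rowMat), ncol = L)
  if (any(covered))
    out[, covered] <- rowMat[, map[covered], drop = FALSE]
  out[1L, ] <- strsplit(canonical, "")[[1L]]
  AnchoredMSA(gene = msa@gene, rows = apply(out, 1L, paste, collapse = ""),
              source = msa@source, covered = covered)
}

#' Column map underlying isoform projection
#'
#' The local-alignment column map used by \code{\link{projectToQuery}}:
#' for each canonical position, the isoform query position aligned to
#' it, or NA outside the aligned fragment (or opposite a gap).
#'
#' @inheritParams projectToQuery
#' @return Integer vector of length \code{nchar(canonical)}.
#' @export
projectionMap <- function(msa, canonical,
                          scoring = alignmentScoring()) {
  canonical <- toupper(canonical)
  L <- nchar(canonical)
  map <- rep(NA_integer_, L)
  if (msa@query == canonical)
    return(seq_len(L))
  subMat <- .substitutionMatrix(scoring)
  # Biostrings charges open+extend for a length-1 gap; shift so that the
  # first gap residue costs -gapOpen and each further one -gapExtend.
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(msa@query), Biostrings::AAString(canonical),
    type = "local", substitutionMatrix = subMat,
    gapOpening = -(scoring$gapOpen - scoring$gapExtend),
    gapExtension = -scoring$gapExtend)
  if (Biostrings::score(aln) <= 0)
    return(map)
  pChars <- strsplit(as.character(Biostrings::alignedPattern(aln)),
                     "")[[1L]]
  sChars <- strsplit(as.character(Biostrings::alignedSubject(aln)),
                     "")[[1L]]
  pPos <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  sPos <- Biostrings::start(Biostrings::subject(aln)) - 1L
  for (k in seq_along(pChars)) {
    if (pChars[k] != "-") pPos <- pPos + 1L
    if (sChars[k] != "-") sPos <- sPos + 1L
    if (pChars[k] != "-" && sChars[k] != "-")
      map[sPos] <- pPos
  }
  map
}

#' Wild-type, mutant and gap frequencies at a variant's column
#'
#' Counts are taken over all alignment rows (the query row included by
#' default) and divided by the number of rows. Unknown residues
#' (\code{"X"}) count toward the denominator but never toward the
#' wild-type or mutant counts.
#'
#' @param msa An \linkS4class{AnchoredMSA}.
#' @param position 1-based query position.
#' @param wt,mut Amino-acid letters.
#' @param includeQuery Include the query row in the counts (default
#'   TRUE).
#' @return Named numeric vector \code{c(wt_freq, mut_freq, gap_freq)},
#'   each in [0, 1].
#' @export
columnFrequencies <- function(msa, position, wt, mut,
                              includeQuery = TRUE) {
  col <- msaColumn(msa, position)
  if (!includeQuery) col <- col[-1L]
  if (!length(col)) stop("no alignment rows to count")
  n <- length(col)
  c(wt_freq = sum(col == wt) / n,
    mut_freq = sum(col == mut) / n,
    gap_freq = sum(col == .GAP) / n)
}

#' Frequencies of all letters at one column
#'
#' @param msa An \linkS4class{AnchoredMSA}.
#' @param position 1-based query position.
#' @param includeQuery Include the query row.
#' @return Named numeric vector over the 20 letters plus \code{gap} and
#'   \code{X}, summing to 1.
#' @export
columnProfile <- function(msa, position, includeQuery = TRUE) {
  col <- msaColumn(msa, position)
  if (!includeQuery) col <- col[-1L]
  n <- length(col)
  counts <- vapply(c(AA_STANDARD, gap = .GAP, X = .UNKNOWN),
                   function(a) sum(col == a), numeric(1))
  counts / n
}

#' Log transform with offset one
#'
#' Maps a frequency f in [0, 1] to ln(f + 1), a strictly monotone
#' transform with range [0, ln 2].
#'
#' @param freq Numeric vector of frequencies in [0, 1] (NA passed
#'   through).
#' @return ln(freq + 1).
#' @export
logOffset <- function(freq) {
  ok <- is.na(freq) | (freq >= 0 & freq <= 1)
  if (!all(ok))
    stop(sprintf("frequency %g outside [0, 1]", freq[!ok][1L]))
  log1p(freq)
}

#' Does the mutant allele occur in another species?
#'
#' TRUE iff the mutant amino acid appears at the variant's position in
#' at least one non-query alignment row. Variants observed this way in
#' other vertebrates or mammals are overwhelmingly benign, which makes
#' this simple indicator a strong baseline signal.
#'
#' @param msa An \linkS4class{AnchoredMSA}.
#' @param position 1-based query position.
#' @param mut Mutant amino-acid letter.
#' @return Logical scalar.
#' @export
variantSeenInAlignment <- function(msa, position, mut) {
  col <- msaColumn(msa, position)
  any(col[-1L] == mut)
}

#' Alignment-derived feature columns for a set of variants
#'
#' Computes log-offset-transformed wild-type, mutant and gap frequencies
#' from one alignment source for every variant key; positions not
#' covered by the alignment yield NA (to be imputed within-gene).
#'
#' @param msa An \linkS4class{AnchoredMSA}.
#' @param keys Variant keys for \code{msa@gene}
#'   (see \code{\link{variantKeys}}).
#' @param includeQuery Include the query row in counts.
#' @return Numeric matrix with columns
#'   \code{{source}_wt_freq_log}, \code{{source}_mut_freq_log},
#'   \code{{source}_gap_freq_log}.
#' @export
conservationFeatures <- function(msa, keys, includeQuery = TRUE) {
  out <- matrix(NA_real_, nrow(keys), 3L)
  colnames(out) <- paste0(msa@source,
                          c("_wt_freq_log", "_mut_freq_log",
                            "_gap_freq_log"))
  for (i in seq_len(nrow(keys))) {
    p <- keys$position[i]
    if (p > msaLength(msa) || !msa@covered[p]) next
    fr <- columnFrequencies(msa, p, keys$wt[i], keys$mut[i],
                            includeQuery = includeQuery)
    out[i, ] <- logOffset(fr)
  }
  out
}
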