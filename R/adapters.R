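#' Sliding-window plan settings for long proteins
#'
#' Masked language models score proteins directly up to
#' \code{maxDirectLength} residues; longer proteins are scored in
#' overlapping windows of \code{windowLength} residues whose starts are
#' \code{stride} apart.
#'
#' @param windowLength Window length in residues (default 1000).
#' @param stride Distance between window starts (default 250).
#' @param maxDirectLength Longest protein scored in one pass
#'   (default 1022).
#' @return List of class \code{"WindowSpec"}.
#' @export
windowSpec <- function(windowLength = 1000L, stride = 250L,
                       maxDirectLength = 1022L) {
  if (stride > windowLength) stop("stride must not exceed windowLength")
  if (min(windowLength, stride, maxDirectLength) < 1L)
    stop("all window settings must be positive")
  structure(list(windowLength = as.integer(windowLength),
                 stride = as.integer(stride),
                 maxDirectLength = as.integer(maxDirectLength)),
            class = "WindowSpec")
}

#' Log-probability difference to the wild type
#'
#' Normalises an external model's variant log-probability as
#' logP(mutant) - logP(wild type); the same normalisation applies to
#' masked-LM and inverse-folding scores.
#'
#' @param logpMut,logpWt Log-probabilities (vectors recycle).
#' @return logpMut - logpWt; NA where either input is non-finite.
#' @export
llrNormalize <- function(logpMut, logpWt) {
  out <- logpMut - logpWt
  out[!is.finite(logpMut) | !is.finite(logpWt)] <- NA_real_
  out
}

#' Plan scoring windows over a protein
#'
#' Proteins up to \code{maxDirectLength} get one full-length window.
#' Longer proteins get windows of \code{windowLength} starting at
#' 1, 1+stride, 1+2*stride, ...; the final window is right-aligned to
#' end at the protein length so the C-terminus keeps full context.
#' Every position is covered by at least one window.
#'
#' @param proteinLength Protein length (>= 1).
#' @param spec A \code{\link{windowSpec}}.
#' @return data.frame with columns \code{start}, \code{end} (1-based
#'   inclusive).
#' @export
planWindows <- function(proteinLength, spec = windowSpec()) {
  if (proteinLength < 1L) stop("proteinLength must be >= 1")
  if (proteinLength <= spec$maxDirectLength)
    return(data.frame(start = 1L, end = as.integer(proteinLength)))
  lastStart <- proteinLength - spec$windowLength + 1L
  starts <- seq.int(1L, lastStart, by = spec$stride)
  if (starts[length(starts)] != lastStart)
    starts <- c(starts, lastStart)
  data.frame(start = as.integer(starts),
             end = as.integer(starts + spec$windowLength - 1L))
}

#' Pick the window score for one variant
#'
#' Among windows containing the position (and holding a score for it),
#' the window whose centre is closest to the position is used; the
#' centre of a window (start, end) is (start + end) / 2 and distance
#' ties go to the earlier window.
#'
#' @param windows Window plan from \code{\link{planWindows}}.
#' @param perWindowScores Numeric vector parallel to \code{windows}
#'   rows: this variant's score in each window (NA where the window has
#'   no score).
#' @param position 1-based residue position.
#' @return The chosen window's score, or NA when no covering window has
#'   one.
#' @export
stitchWindowScores <- function(windows, perWindowScores, position) {
  covering <- which(windows$start <= position & position <= windows$end &
                      !is.na(perWindowScores))
  if (!length(covering)) return(NA_real_)
  centers <- (windows$start[covering] + windows$end[covering]) / 2
  perWindowScores[covering[which.min(abs(position - centers))]]
}

#' Amino-acid descriptor differences
#'
#' For a substitution wt -> mut, returns the component-wise difference
#' table[mut, ] - table[wt, ] over the named descriptor scales.
#'
#' @param wt,mut Amino-acid letters.
#' @param table Descriptor matrix, rows named by amino-acid letter
#'   (see \code{\link{readDescriptorTable}} /
#'   \code{\link{defaultDescriptorTable}}).
#' @return Named numeric vector, one entry per scale.
#' @export
descriptorDelta <- function(wt, mut, table = defaultDescriptorTable()) {
  for (a in c(wt, mut))
    if (!a %in% rownames(table))
      stop(sprintf("amino acid '%s' not present in descriptor table", a))
  table[mut, ] - table[wt, ]
}

#' Descriptor-delta feature columns for a set of variants
#'
#' @param keys Variant keys.
#' @param table Descriptor matrix.
#' @param prefix Column-name prefix (default \code{"d_"}).
#' @return Numeric matrix, one column per descriptor scale.
#' @export
descriptorFeatures <- function(keys, table = defaultDescriptorTable(),
                               prefix = "d_") {
  out <- table[keys$mut, , drop = FALSE] - table[keys$wt, , drop = FALSE]
  colnames(out) <- paste0(prefix, colnames(table))
  rownames(out) <- NULL
  out
}

#' Attach external predictor score columns to variant keys
#'
#' Joins keyed score tables (gene, position, wt, mut, value) onto a set
#' of variant keys; variants absent from a table get NA in that column.
#'
#' @param keys Variant keys.
#' @param scoreTables Named list of data.frames as returned by
#'   \code{\link{readScoreTable}}; list names become column names
#'   (e.g. \code{esm_llr}, \code{eve_logp}, \code{mpnn_llr}).
#' @return Numeric matrix with one column per score table.
#' @export
externalScoreFeatures <- function(keys, scoreTables) {
  ks <- .keyString(keys)
  out <- matrix(NA_real_, nrow(keys), length(scoreTables))
  colnames(out) <- names(scoreTables)
  for (nm in names(scoreTables)) {
    tab <- scoreTables[[nm]]
    valueCol <- setdiff(names(tab), c("gene", "position", "wt", "mut"))[1L]
    idx <- match(ks, .keyString(tab))
    out[, nm] <- tab[[valueCol]][idx]
  }
  out
}
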