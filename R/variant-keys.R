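#' Build and validate variant keys
#'
#' A variant key identifies a missense variant by gene, 1-based residue
#' position on the canonical protein sequence, and wild-type/mutant
#' amino-acid letters.
#'
#' @param gene Character vector of gene identifiers.
#' @param position Integer vector of 1-based residue positions.
#' @param wt,mut Single-letter amino-acid codes.
#' @param query Optional named character vector of canonical sequences
#'   (one per gene); when supplied, \code{wt} is checked against the
#'   sequence at \code{position}.
#' @param requireSubstitution Reject keys with \code{wt == mut}
#'   (default TRUE; scored variants are proper substitutions).
#' @return data.frame with columns gene, position, wt, mut.
#' @examples
#' variantKeys("G1", 3, "A", "V")
#' @export
variantKeys <- function(gene, position, wt, mut, query = NULL,
                        requireSubstitution = TRUE) {
  k <- data.frame(gene = as.character(gene),
                  position = as.integer(position),
                  wt = toupper(as.character(wt)),
                  mut = toupper(as.character(mut)),
                  stringsAsFactors = FALSE)
  if (any(k$position < 1L))
    stop("variant positions must be >= 1")
  bad <- !(k$wt %in% AA_STANDARD) | !(k$mut %in% AA_STANDARD)
  if (any(bad))
    stop(sprintf("non-standard amino-acid letter in key %d (%s%d%s)",
                 which(bad)[1L], k$wt[which(bad)[1L]],
                 k$position[which(bad)[1L]], k$mut[which(bad)[1L]]))
  if (requireSubstitution && any(k$wt == k$mut))
    stop("wild-type and mutant amino acids must differ")
  if (!is.null(query)) {
    for (g in unique(k$gene)) {
      if (!g %in% names(query)) next
      idx <- which(k$gene == g)
      seqAA <- substring(query[[g]], k$position[idx], k$position[idx])
      mismatch <- seqAA != k$wt[idx]
      if (any(mismatch))
        stop(sprintf(
          "wild-type mismatch for gene %s at position %d: key says %s, sequence says %s",
          g, k$position[idx][mismatch][1L], k$wt[idx][mismatch][1L],
          seqAA[mismatch][1L]))
    }
  }
  k
}

.keyString <- function(keys)
  paste(keys$gene, keys$position, keys$wt, keys$mut, sep = "|")
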