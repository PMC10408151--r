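#' Contact extraction settings
#'
#' @param mode \code{"precomputed"} (contact TSV passthrough) or
#'   \code{"distance_fallback"} (heavy-atom distance rule).
#' @param cutoffA Sidechain heavy-atom distance threshold in Angstroms
#'   used in fallback mode (default 4.5).
#' @return List of class \code{"ContactSpec"}.
#' @export
contactSpec <- function(mode = c("distance_fallback", "precomputed"),
                        cutoffA = 4.5) {
  mode <- match.arg(mode)
  if (cutoffA <= 0) stop("cutoffA must be positive")
  structure(list(mode = mode, cutoffA = cutoffA), class = "ContactSpec")
}

#' Structure-conditioning settings
#'
#' Controls the structure-conditioned frequency features: at most
#' \code{maxResidues} contact residues are used for conditioning, only
#' residues with pLDDT above \code{plddtThreshold} may condition (and a
#' position at or below the threshold gets no conditioning at all), and
#' fewer than \code{minFilteredRows} retained alignment rows marks the
#' feature missing for imputation.
#'
#' @param maxResidues Maximum conditioning residues (default 2).
#' @param plddtThreshold Confidence threshold (default 70).
#' @param minFilteredRows Minimum retained alignment depth (default 1).
#' @return List of class \code{"ConditioningSpec"}.
#' @export
conditioningSpec <- function(maxResidues = 2L, plddtThreshold = 70,
                             minFilteredRows = 1L) {
  if (maxResidues < 0) stop("maxResidues must be >= 0")
  if (plddtThreshold < 0 || plddtThreshold > 100)
    stop("plddtThreshold must lie in [0, 100]")
  structure(list(maxResidues = as.integer(maxResidues),
                 plddtThreshold = plddtThreshold,
                 minFilteredRows = as.integer(minFilteredRows)),
            class = "ConditioningSpec")
}

#' Sidechain-sidechain contact adjacency from coordinates
#'
#' Distance-based dialect: residues i and j (i != j) are in contact iff
#' some sidechain heavy atom of i lies within \code{spec$cutoffA} of
#' some sidechain heavy atom of j. Residues without sidechain heavy
#' atoms (glycine) never form contacts.
#'
#' @param sidechains List with one element per residue: a matrix of
#'   sidechain heavy-atom xyz coordinates (0 rows or NULL for none), or
#'   a single n x 3 matrix of one representative sidechain point per
#'   residue.
#' @param spec A \code{\link{contactSpec}}.
#' @return Symmetric logical adjacency matrix.
#' @export
extractContacts <- function(sidechains, spec = contactSpec()) {
  if (is.matrix(sidechains))
    sidechains <- lapply(seq_len(nrow(sidechains)), function(i)
      sidechains[i, , drop = FALSE])
  n <- length(sidechains)
  adj <- matrix(FALSE, n, n)
  nat <- vapply(sidechains, function(m) if (is.null(m)) 0L else nrow(m),
                integer(1))
  cut2 <- spec$cutoffA^2
  for (i in seq_len(n)) {
    if (!nat[i]) next
    for (j in seq_len(n)) {
      if (j <= i || !nat[j]) next
      a <- sidechains[[i]]
      b <- sidechains[[j]]
      d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
      if (min(d2) <= cut2) {
        adj[i, j] <- TRUE
        adj[j, i] <- TRUE
      }
    }
  }
  adj
}

#' Resolve multi-fragment structures at one position
#'
#' Proteins released as several structure fragments use, at each
#' position, the fragment that maximises the pLDDT there; ties go to
#' the lowest fragment identifier.
#'
#' @param fragments List of \linkS4class{StructureInfo} objects.
#' @param position 1-based residue index.
#' @return The selected \linkS4class{StructureInfo}, or NULL when no
#'   fragment covers the position.
#' @export
resolveFragments <- function(fragments, position) {
  best <- NULL
  bestP <- -Inf
  bestId <- Inf
  for (f in fragments) {
    p <- if (position <= length(f@plddt)) f@plddt[position] else NA_real_
    if (is.na(p)) next
    if (p > bestP || (p == bestP && f@fragmentId < bestId)) {
      best <- f
      bestP <- p
      bestId <- f@fragmentId
    }
  }
  best
}

#' Choose conditioning residues for a position
#'
#' Candidates are the contacts of \code{position} whose pLDDT exceeds
#' the threshold; they are ranked by the frequency of the query (human)
#' amino acid at that contact position in the deep alignment, and the
#' top \code{spec$maxResidues} are returned. If the position's own
#' pLDDT is at or below the threshold, no conditioning is used. Ties in
#' frequency break to the lower residue index.
#'
#' @param position 1-based residue index.
#' @param structure A \linkS4class{StructureInfo}.
#' @param deepMsa Deep \linkS4class{AnchoredMSA} anchored to the same
#'   canonical sequence.
#' @param spec A \code{\link{conditioningSpec}}.
#' @param includeQuery Denominator convention for the ranking
#'   frequencies.
#' @return Integer vector of at most \code{spec$maxResidues} residue
#'   indices (possibly empty).
#' @export
pickConditioningResidues <- function(position, structure, deepMsa,
                                     spec = conditioningSpec(),
                                     includeQuery = TRUE) {
  n <- length(structure@plddt)
  if (position < 1L || position > n)
    stop(sprintf("position %d outside structure (1..%d)", position, n))
  own <- structure@plddt[position]
  if (is.na(own) || own <= spec$plddtThreshold) return(integer(0))
  cand <- which(structure@contacts[position, ])
  cand <- cand[!is.na(structure@plddt[cand]) &
                 structure@plddt[cand] > spec$plddtThreshold]
  cand <- cand[cand <= msaLength(deepMsa)]
  if (!length(cand)) return(integer(0))
  queryAA <- substring(deepMsa@query, cand, cand)
  freq <- vapply(seq_along(cand), function(k) {
    col <- msaColumn(deepMsa, cand[k])
    if (!includeQuery) col <- col[-1L]
    sum(col == queryAA[k]) / length(col)
  }, numeric(1))
  ord <- order(-freq, cand)
  utils::head(cand[ord], spec$maxResidues)
}

#' Structure-conditioned wild-type and mutant scores
#'
#' The deep alignment is filtered to rows whose residues at every
#' conditioning position match the query (human) amino acid there; the
#' wild-type and mutant frequencies at the variant's column are then
#' computed over the retained rows (same denominator convention as
#' \code{\link{columnFrequencies}}) and log-offset transformed. With an
#' empty conditioning list this equals the unconditioned transformed
#' frequencies exactly. Fewer retained rows than
#' \code{spec$minFilteredRows} yields NA for both scores.
#'
#' @param deepMsa Deep \linkS4class{AnchoredMSA}.
#' @param position,wt,mut Variant key fields.
#' @param conditioning Integer vector of conditioning residue indices.
#' @param spec A \code{\link{conditioningSpec}}.
#' @param includeQuery Include the query row in counts.
#' @return Named numeric vector \code{c(cond_wt_score, cond_mut_score)}.
#' @export
conditionedScores <- function(deepMsa, position, wt, mut,
                              conditioning = integer(0),
                              spec = conditioningSpec(),
                              includeQuery = TRUE) {
  if (position < 1L || position > msaLength(deepMsa))
    stop(sprintf("position %d out of range 1..%d", position,
                 msaLength(deepMsa)))
  keep <- rep(TRUE, msaDepth(deepMsa))
  for (cpos in conditioning) {
    queryAA <- substring(deepMsa@query, cpos, cpos)
    keep <- keep & (msaColumn(deepMsa, cpos) == queryAA)
  }
  if (!includeQuery) keep[1L] <- FALSE
  col <- msaColumn(deepMsa, position)[keep]
  if (length(col) < spec$minFilteredRows || !length(col))
    return(c(cond_wt_score = NA_real_, cond_mut_score = NA_real_))
  c(cond_wt_score = logOffset(sum(col == wt) / length(col)),
    cond_mut_score = logOffset(sum(col == mut) / length(col)))
}

#' Per-site structural features
#'
#' @param structure A \linkS4class{StructureInfo}.
#' @param position 1-based residue index.
#' @return Named numeric vector \code{c(contact_count, plddt)}; NA at
#'   positions the structure does not cover.
#' @export
siteFeatures <- function(structure, position) {
  n <- length(structure@plddt)
  if (position < 1L || position > n)
    return(c(contact_count = NA_real_, plddt = NA_real_))
  p <- structure@plddt[position]
  if (is.na(p))
    return(c(contact_count = NA_real_, plddt = NA_real_))
  c(contact_count = sum(structure@contacts[position, ]), plddt = p)
}

#' Structure-derived feature columns for a set of variants
#'
#' Combines fragment resolution, conditioning-residue selection,
#' conditioned scores and per-site features into the four structure
#' feature columns.
#'
#' @param fragments List of \linkS4class{StructureInfo} fragments for
#'   one gene (a single object is promoted to a list).
#' @param deepMsa Deep \linkS4class{AnchoredMSA} for the gene.
#' @param keys Variant keys for the gene.
#' @param spec A \code{\link{conditioningSpec}}.
#' @param includeQuery Denominator convention.
#' @return Numeric matrix with columns cond_wt_score, cond_mut_score,
#'   contact_count, plddt.
#' @export
structureFeatures <- function(fragments, deepMsa, keys,
                              spec = conditioningSpec(),
                              includeQuery = TRUE) {
  if (is(fragments, "StructureInfo")) fragments <- list(fragments)
  out <- matrix(NA_real_, nrow(keys), 4L)
  colnames(out) <- c("cond_wt_score", "cond_mut_score", "contact_count",
                     "plddt")
  positions <- sort(unique(keys$position))
  condCache <- list()
  for (p in positions) {
    frag <- resolveFragments(fragments, p)
    if (is.null(frag)) next
    cond <- pickConditioningResidues(p, frag, deepMsa, spec,
                                     includeQuery = includeQuery)
    condCache[[as.character(p)]] <- list(frag = frag, cond = cond)
  }
  for (i in seq_len(nrow(keys))) {
    entry <- condCache[[as.character(keys$position[i])]]
    if (is.null(entry)) next
    cs <- conditionedScores(deepMsa, keys$position[i], keys$wt[i],
                            keys$mut[i], entry$cond, spec,
                            includeQuery = includeQuery)
    sf <- siteFeatures(entry$frag, keys$position[i])
    out[i, ] <- c(cs, sf)
  }
  out
}
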