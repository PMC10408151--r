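#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random pathogenic
#' (label 1) variant outranks a random benign (label 0) one, with ties
#' counting one half. Higher score means more pathogenic.
#'
#' @param labels Binary vector (0 benign, 1 pathogenic).
#' @param scores Real-valued predictions.
#' @return AUROC in [0, 1]; NA when only one class is present.
#' @export
rocAuc <- function(labels, scores) {
  ok <- !is.na(labels) & !is.na(scores)
  labels <- labels[ok]
  scores <- scores[ok]
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Specificity at a target sensitivity
#'
#' The decision threshold is the most stringent (largest) score cutoff
#' that still classifies at least a fraction \code{s} of pathogenic
#' variants as pathogenic (score >= threshold); the returned
#' specificity is the fraction of benign variants strictly below that
#' threshold.
#'
#' @param labels Binary vector (0 benign, 1 pathogenic).
#' @param scores Real-valued predictions (higher = more pathogenic).
#' @param s Target sensitivity in (0, 1].
#' @return Specificity in [0, 1].
#' @export
specificityAtSensitivity <- function(labels, scores, s = 0.95) {
  if (s <= 0 || s > 1) stop("target sensitivity must lie in (0, 1]")
  ok <- !is.na(labels) & !is.na(scores)
  labels <- labels[ok]
  scores <- scores[ok]
  path <- scores[labels == 1]
  ben <- scores[labels == 0]
  if (!length(path) || !length(ben))
    stop("both classes must be present")
  k <- ceiling(s * length(path))
  threshold <- sort(path, decreasing = TRUE)[k]
  mean(ben < threshold)
}

#' Per-gene AUROC over eligible genes
#'
#' Genes with fewer than \code{minBenign} benign or \code{minPathogenic}
#' pathogenic variants are excluded; \code{\link{rocAuc}} is computed
#' within each remaining gene.
#'
#' @param labeled A \linkS4class{LabeledVariantSet}.
#' @param scores Numeric vector parallel to the labelled records.
#' @param minBenign,minPathogenic Eligibility thresholds (default 4).
#' @return Named numeric vector, one AUROC per eligible gene.
#' @export
perGeneAuroc <- function(labeled, scores, minBenign = 4L,
                         minPathogenic = 4L) {
  r <- labeled@records
  out <- numeric(0)
  for (g in unique(r$gene)) {
    idx <- r$gene == g
    nb <- sum(r$label[idx] == 0)
    np <- sum(r$label[idx] == 1)
    if (nb < minBenign || np < minPathogenic) next
    out[g] <- rocAuc(r$label[idx], scores[idx])
  }
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; NA for constant input
#' or fewer than 3 pairs.
#'
#' @param x,y Numeric vectors.
#' @return Spearman's rho in [-1, 1], or NA.
#' @export
spearmanRho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  suppressWarnings(stats::cor(x, y, method = "spearman"))
}

#' Build an evaluation report
#'
#' Combines the clinical-style metrics (global AUROC, per-gene AUROC
#' over eligible genes, specificity at the requested sensitivities) and
#' optionally assay-style Spearman correlations per DMS dataset.
#'
#' @param labeled A \linkS4class{LabeledVariantSet}.
#' @param scores Numeric predictions parallel to the labelled records
#'   (higher = more pathogenic).
#' @param sensitivities Target sensitivities (default 0.90, 0.95, 0.99).
#' @param spearman Optional named numeric vector of per-dataset
#'   Spearman correlations to embed.
#' @param minBenign,minPathogenic Per-gene eligibility thresholds.
#' @return An \linkS4class{EvaluationReport}.
#' @export
evaluationReport <- function(labeled, scores,
                             sensitivities = c(0.90, 0.95, 0.99),
                             spearman = numeric(0), minBenign = 4L,
                             minPathogenic = 4L) {
  r <- labeled@records
  spec <- vapply(sensitivities, function(s)
    specificityAtSensitivity(r$label, scores, s), numeric(1))
  names(spec) <- format(sensitivities, trim = TRUE)
  new("EvaluationReport",
      globalAuroc = rocAuc(r$label, scores),
      perGeneAuroc = perGeneAuroc(labeled, scores, minBenign,
                                  minPathogenic),
      specAtSens = spec,
      spearman = spearman,
      n = nrow(r))
}

#' Serialize an evaluation report to JSON
#'
#' @param report An \linkS4class{EvaluationReport}.
#' @param path Output JSON file.
#' @return \code{path}, invisibly.
#' @export
writeEvaluationReport <- function(report, path) {
  obj <- list(schema = "cpt-evaluation/1",
              n = report@n,
              global_auroc = report@globalAuroc,
              per_gene_auroc = as.list(report@perGeneAuroc),
              specificity_at_sensitivity = as.list(report@specAtSens),
              spearman = as.list(report@spearman))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
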