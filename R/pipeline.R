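#' Default feature set of the transfer model
#'
#' Nine columns spanning the feature categories: the two protein
#' homology scores (always included), vertebrate and mammal alignment
#' frequencies, the inverse-folding score, and the structure-conditioned
#' scores.
#'
#' @return Character vector of feature column names.
#' @export
defaultFeatureSet <- function() {
  c("esm_llr", "eve_logp",
    "vert100_wt_freq_log", "vert100_mut_freq_log",
    "mamm30_wt_freq_log", "mamm30_mut_freq_log",
    "mpnn_llr", "cond_wt_score", "cond_mut_score")
}

#' Assemble per-gene feature tables for a family
#'
#' Computes, for every DMS variant of every gene, the alignment
#' frequency features from each shallow source, the structure features
#' (conditioned scores, contact count, pLDDT), the external predictor
#' score columns, and the descriptor deltas. Cells that cannot be
#' computed (uncovered alignment columns, conditioning filters that
#' empty the deep alignment) are NA and flow to imputation.
#'
#' @param family A \code{\link{generateFamily}} bundle or the list
#'   returned by \code{\link{readFamily}}.
#' @param descriptorTable Descriptor matrix (default
#'   \code{\link{defaultDescriptorTable}}).
#' @param conditioning A \code{\link{conditioningSpec}}.
#' @param includeQuery Frequency denominator convention.
#' @return Named list of per-gene \linkS4class{FeatureTable}s.
#' @export
featurizeFamily <- function(family,
                            descriptorTable = defaultDescriptorTable(),
                            conditioning = conditioningSpec(),
                            includeQuery = TRUE) {
  tables <- list()
  for (g in names(family$dms)) {
    rec <- family$dms[[g]]@records
    keys <- data.frame(gene = g, rec[, c("position", "wt", "mut")],
                       stringsAsFactors = FALSE)
    cons <- cbind(
      conservationFeatures(family$msas$vert100[[g]], keys,
                           includeQuery = includeQuery),
      conservationFeatures(family$msas$mamm30[[g]], keys,
                           includeQuery = includeQuery))
    struct <- structureFeatures(family$structures[[g]],
                                family$msas$deep[[g]], keys,
                                spec = conditioning,
                                includeQuery = includeQuery)
    ext <- externalScoreFeatures(keys, family$scoreTables)
    desc <- descriptorFeatures(keys, descriptorTable)
    feats <- cbind(cons, struct, ext, desc)
    freqCols <- c(colnames(cons), "cond_wt_score", "cond_mut_score")
    categories <- c(
      stats::setNames(rep("vert100", 3L), colnames(cons)[1:3]),
      stats::setNames(rep("mamm30", 3L), colnames(cons)[4:6]),
      cond_wt_score = "conditioned", cond_mut_score = "conditioned",
      contact_count = "site", plddt = "site",
      esm_llr = "homology", eve_logp = "homology",
      mpnn_llr = "inverse_folding",
      stats::setNames(rep("descriptor", ncol(desc)), colnames(desc)))
    tables[[g]] <- FeatureTable(keys, feats, categories = categories,
                                frequency = freqCols)
  }
  tables
}

#' Leave-one-protein-out predictions over a family
#'
#' For each gene in turn, fits a transfer model on the remaining genes
#' and predicts the held-out gene's variants.
#'
#' @param tables Named list of completed per-gene
#'   \linkS4class{FeatureTable}s.
#' @param dms Named list of \linkS4class{DMSDataset}s.
#' @param features Feature names (default \code{\link{defaultFeatureSet}}).
#' @param config A \code{\link{trainingConfig}}.
#' @return Named list per gene with elements \code{model},
#'   \code{predictions} (parallel to the gene's feature-table rows) and
#'   \code{keys}.
#' @export
lopoPredict <- function(tables, dms, features = defaultFeatureSet(),
                        config = trainingConfig()) {
  out <- list()
  for (fold in lopoFolds(names(tables))) {
    model <- fitCPT(tables[fold$train], dms[fold$train], features,
                    config)
    vt <- tables[[fold$validation]]
    out[[fold$validation]] <- list(
      model = model,
      predictions = predictEnsemble(model, vt),
      keys = variantKeysOf(vt))
  }
  out
}

#' Run the full synthetic study end to end
#'
#' simulate -> featurize -> impute -> train -> predict -> evaluate.
#' Classification models produce the clinical-style metrics against the
#' family's benign/pathogenic labels; regression models produce the
#' per-gene Spearman correlations against the held-out assay scores.
#'
#' @param config A \code{\link{generatorConfig}}.
#' @param features Feature names (default \code{\link{defaultFeatureSet}}).
#' @param sensitivities Sensitivity operating points for the report.
#' @return List with \code{bundle}, \code{tables} (completed),
#'   \code{classification} and \code{regression} LOPO results, pooled
#'   \code{scores}, and the \linkS4class{EvaluationReport}.
#' @export
runPipeline <- function(config = generatorConfig(),
                        features = defaultFeatureSet(),
                        sensitivities = c(0.90, 0.95, 0.99)) {
  bundle <- generateFamily(config)
  tables <- featurizeFamily(bundle)
  tables <- completeFeatures(tables)
  cls <- lopoPredict(tables, bundle$dms, features,
                     trainingConfig(task = "classification"))
  reg <- lopoPredict(tables, bundle$dms, features,
                     trainingConfig(task = "regression"))
  lab <- bundle$labels@records
  scoreMap <- do.call(c, unname(lapply(cls, function(f)
    stats::setNames(f$predictions, .keyString(f$keys)))))
  scores <- unname(scoreMap[.keyString(lab)])
  spear <- vapply(names(reg), function(g) {
    r <- bundle$dms[[g]]@records
    spearmanRho(reg[[g]]$predictions, r$score)
  }, numeric(1))
  report <- evaluationReport(bundle$labels, scores,
                             sensitivities = sensitivities,
                             spearman = spear)
  list(bundle = bundle, tables = tables, classification = cls,
       regression = reg, scores = scores, report = report)
}
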