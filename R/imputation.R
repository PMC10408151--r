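#' Weighted-KNN imputer settings
#'
#' @param nNeighbors Number of nearest neighbours averaged (default 10).
#' @param nHelperFeatures Number of helper columns ranked by absolute
#'   Spearman correlation with the target (default 5).
#' @param signedWeights Use signed Spearman rho as the helper weight
#'   instead of its absolute value (default FALSE; sign is irrelevant to
#'   Euclidean geometry).
#' @return List of class \code{"ImputerSpec"}.
#' @export
imputerSpec <- function(nNeighbors = 10L, nHelperFeatures = 5L,
                        signedWeights = FALSE) {
  if (nNeighbors < 1L || nHelperFeatures < 1L)
    stop("nNeighbors and nHelperFeatures must be >= 1")
  structure(list(nNeighbors = as.integer(nNeighbors),
                 nHelperFeatures = as.integer(nHelperFeatures),
                 signedWeights = signedWeights),
            class = "ImputerSpec")
}

.spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) return(0)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(0)
  suppressWarnings(stats::cor(x[ok], y[ok], method = "spearman"))
}

#' Fit a weighted-KNN imputer on one gene
#'
#' The helper columns are the \code{nHelperFeatures} features most
#' highly Spearman-correlated with the target over the gene's rows where
#' both are observed. Each helper is standardised by its observed mean
#' and standard deviation, then multiplied by its correlation weight;
#' the target itself is standardised and given weight 1. Rows with an
#' observed target form the weighted reference matrix used for
#' neighbour search.
#'
#' @param table A \linkS4class{FeatureTable} (restricted to one gene, or
#'   filtered by \code{gene}).
#' @param target Target column name.
#' @param spec An \code{\link{imputerSpec}}.
#' @param gene Optional gene to filter \code{table} to.
#' @return Object of class \code{"WeightedKnnImputer"}.
#' @export
fitWeightedKnn <- function(table, target, spec = imputerSpec(),
                           gene = NULL) {
  if (!is.null(gene))
    table <- subsetFeatureTable(table, table@keys$gene == gene)
  X <- featureMatrix(table)
  if (!target %in% colnames(X))
    stop(sprintf("target column '%s' not in table", target))
  y <- X[, target]
  obs <- !is.na(y)
  if (sum(obs) < spec$nNeighbors + 1L)
    stop(structure(class = c("cptTooFewObserved", "error", "condition"),
                   list(message = sprintf(
                     "target '%s' has %d observed values (< %d); use cross-gene imputation",
                     target, sum(obs), spec$nNeighbors + 1L),
                     call = sys.call())))
  candidates <- setdiff(colnames(X), target)
  rho <- vapply(candidates, function(cn) .spearman(X[, cn], y),
                numeric(1))
  w <- if (spec$signedWeights) rho else abs(rho)
  ord <- order(-abs(rho), match(candidates, colnames(X)))
  helpers <- candidates[ord][seq_len(min(spec$nHelperFeatures,
                                         length(candidates)))]
  weights <- w[helpers]
  keep <- abs(weights) > 0  # zero-variance / uncorrelated helpers drop out
  helpers <- helpers[keep]
  weights <- weights[keep]
  stdStats <- function(v) {
    m <- mean(v, na.rm = TRUE)
    s <- stats::sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) s <- 1
    c(center = m, scale = s)
  }
  helperStats <- matrix(numeric(0), 0, 2,
                        dimnames = list(NULL, c("center", "scale")))
  if (length(helpers))
    helperStats <- t(vapply(helpers, function(cn) stdStats(X[, cn]),
                            numeric(2)))
  targetStats <- stdStats(y[obs])
  weightRow <- function(xrow) {
    h <- (xrow[helpers] - helperStats[, "center"]) /
      helperStats[, "scale"] * weights
    t <- (xrow[target] - targetStats["center"]) / targetStats["scale"]
    c(h, t)
  }
  refRaw <- apply(X[obs, , drop = FALSE], 1L, weightRow)
  ref <- if (is.matrix(refRaw)) t(refRaw) else matrix(refRaw, ncol = 1L)
  colnames(ref) <- c(helpers, target)
  structure(list(target = target, helpers = helpers, weights = weights,
                 helperStats = helperStats, targetStats = targetStats,
                 reference = ref, referenceTarget = y[obs],
                 spec = spec),
            class = "WeightedKnnImputer")
}

#' @export
print.WeightedKnnImputer <- function(x, ...) {
  cat(sprintf("WeightedKnnImputer target=%s: %d reference rows, helpers [%s]\n",
              x$target, nrow(x$reference),
              paste(sprintf("%s(%.2f)", x$helpers, x$weights),
                    collapse = ", ")))
  invisible(x)
}

# nan-Euclidean distances from one weighted query row to the reference
# matrix: squared differences over mutually observed dimensions, scaled
# by total/observed dimension count.
.knnDistances <- function(imputer, qWeighted) {
  ref <- imputer$reference
  total <- ncol(ref)
  diffs <- sweep(ref, 2L, qWeighted)^2
  obsCount <- rowSums(!is.na(diffs))
  ss <- rowSums(diffs, na.rm = TRUE)
  d <- sqrt(total / obsCount * ss)
  d[obsCount == 0L] <- NA_real_
  d
}

.knnPredictRow <- function(imputer, xrow) {
  k0 <- imputer$spec$nNeighbors
  if (!length(imputer$helpers)) {
    # zero-dimensional helper space (all candidates uncorrelated or
    # constant): every reference row is equidistant; the deterministic
    # low-index tie-break averages the first k target values
    k <- min(k0, length(imputer$referenceTarget))
    return(mean(imputer$referenceTarget[seq_len(k)]))
  }
  h <- (xrow[imputer$helpers] -
          imputer$helperStats[, "center"]) /
    imputer$helperStats[, "scale"] * imputer$weights
  q <- c(h, NA_real_)  # target dimension is missing for a query row
  d <- .knnDistances(imputer, q)
  if (all(is.na(d))) return(NA_real_)
  ord <- order(d, seq_along(d), na.last = TRUE)  # tie -> lower row index
  ord <- ord[!is.na(d[ord])]
  k <- min(imputer$spec$nNeighbors, length(ord))
  mean(imputer$referenceTarget[ord[seq_len(k)]])
}

#' Impute a target column within one gene
#'
#' Each missing cell becomes the unweighted mean of the target values of
#' the nearest reference rows under the nan-Euclidean distance in the
#' weighted helper space; observed cells are untouched. Rows whose
#' helpers are all missing stay NA with a warning.
#'
#' @param imputer A fitted \code{\link{fitWeightedKnn}} imputer (same
#'   gene).
#' @param table \linkS4class{FeatureTable} for the gene.
#' @param gene Optional gene filter.
#' @return Completed numeric target column.
#' @export
imputeWithinGene <- function(imputer, table, gene = NULL) {
  if (!is.null(gene))
    table <- subsetFeatureTable(table, table@keys$gene == gene)
  X <- featureMatrix(table)
  y <- X[, imputer$target]
  missing <- which(is.na(y))
  for (i in missing)
    y[i] <- .knnPredictRow(imputer, X[i, ])
  if (anyNA(y[missing]))
    warning(sprintf("%d row(s) had no observed helper and stay missing",
                    sum(is.na(y[missing]))))
  y
}

#' Impute a target column for a new gene from training-gene imputers
#'
#' Every cell of the target (assumed entirely unobserved in the new
#' gene) is the arithmetic mean of the predictions of the imputers
#' fitted on the training genes. Imputers whose helper columns are
#' absent from the new gene are skipped with a warning; all failing is
#' an error.
#'
#' @param imputers List of fitted \code{\link{fitWeightedKnn}} imputers
#'   (one per training gene).
#' @param table \linkS4class{FeatureTable} for the new gene.
#' @param gene Optional gene filter.
#' @return Completed numeric target column (observed cells untouched).
#' @export
imputeCrossGene <- function(imputers, table, gene = NULL) {
  if (!is.null(gene))
    table <- subsetFeatureTable(table, table@keys$gene == gene)
  X <- featureMatrix(table)
  preds <- matrix(NA_real_, nrow(X), length(imputers))
  used <- 0L
  for (k in seq_along(imputers)) {
    imp <- imputers[[k]]
    if (!all(imp$helpers %in% colnames(X))) {
      warning(sprintf(
        "imputer %d skipped: helper column(s) absent from the new gene", k))
      next
    }
    used <- used + 1L
    preds[, k] <- vapply(seq_len(nrow(X)), function(i)
      .knnPredictRow(imp, X[i, ]), numeric(1))
  }
  if (!used)
    stop("all cross-gene imputers failed: no usable helper columns")
  y <- X[, imputers[[1L]]$target]
  fill <- is.na(y)
  y[fill] <- rowMeans(preds[fill, , drop = FALSE], na.rm = TRUE)
  y
}

#' Complete all missing feature cells across a gene family
#'
#' For each gene and each column with missing cells, fits a within-gene
#' weighted-KNN imputer when the gene has enough observed target values;
#' otherwise falls back to cross-gene imputation with imputers fitted on
#' the other genes (those with enough observations). Columns missing
#' everywhere are dropped with a warning.
#'
#' @param tables Named list of per-gene \linkS4class{FeatureTable}s.
#' @param spec An \code{\link{imputerSpec}}.
#' @return The list of tables with completed feature matrices.
#' @export
completeFeatures <- function(tables, spec = imputerSpec()) {
  cols <- colnames(featureMatrix(tables[[1L]]))
  for (target in cols) {
    needs <- names(tables)[vapply(tables, function(t)
      anyNA(featureMatrix(t)[, target]), logical(1))]
    if (!length(needs)) next
    donors <- list()
    for (g in names(tables)) {
      fit <- tryCatch(fitWeightedKnn(tables[[g]], target, spec),
                      cptTooFewObserved = function(e) NULL)
      if (!is.null(fit)) donors[[g]] <- fit
    }
    for (g in needs) {
      t <- tables[[g]]
      y <- if (g %in% names(donors))
        imputeWithinGene(donors[[g]], t)
      else if (length(donors[setdiff(names(donors), g)]))
        imputeCrossGene(donors[setdiff(names(donors), g)], t)
      else {
        warning(sprintf(
          "column '%s' cannot be imputed for gene %s (no donors)",
          target, g))
        next
      }
      t@features[, target] <- y
      tables[[g]] <- t
    }
  }
  tables
}
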