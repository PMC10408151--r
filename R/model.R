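#' Training configuration for cross-protein transfer models
#'
#' @param topFraction Fraction of each protein's best-scoring variants
#'   labelled functionally normal (default 0.40).
#' @param bottomFraction Fraction labelled functionally abnormal
#'   (default 0.40); the middle band is discarded.
#' @param task \code{"classification"} (logistic on binarised labels)
#'   or \code{"regression"} (least squares on raw assay scores).
#' @param l2 Ridge penalty stabilising collinear features (default
#'   1e-6; set 0 for exact least squares).
#' @param averageProbabilities For classification ensembles, average
#'   predicted probabilities (default) rather than linear predictors.
#' @return List of class \code{"TrainingConfig"}.
#' @export
trainingConfig <- function(topFraction = 0.40, bottomFraction = 0.40,
                           task = c("classification", "regression"),
                           l2 = 1e-6, averageProbabilities = TRUE) {
  task <- match.arg(task)
  if (topFraction + bottomFraction > 1)
    stop("topFraction + bottomFraction must be <= 1")
  if (topFraction <= 0 || topFraction > 0.5 ||
      bottomFraction <= 0 || bottomFraction > 0.5)
    stop("fractions must lie in (0, 0.5]")
  structure(list(topFraction = topFraction,
                 bottomFraction = bottomFraction, task = task, l2 = l2,
                 averageProbabilities = averageProbabilities),
            class = "TrainingConfig")
}

#' Percentile-binarise a DMS dataset
#'
#' Assay score distributions differ between proteins, so scores are
#' standardised by rank: the bottom \code{floor(bottomFraction * n)}
#' variants are labelled functionally abnormal (1) and the top
#' \code{floor(topFraction * n)} functionally normal (0); the middle
#' band is discarded. Ties are broken by stable input order, so label
#' counts are exact even for heavily tied scores.
#'
#' @param dms A \linkS4class{DMSDataset} with at least 10 records.
#' @param config A \code{\link{trainingConfig}}.
#' @return data.frame of the retained records (original order) with a
#'   \code{label} column.
#' @export
binarizeDMS <- function(dms, config = trainingConfig()) {
  r <- dms@records
  n <- nrow(r)
  if (n < 10L)
    stop(sprintf("gene %s: %d records (< 10) is too few to binarise",
                 dms@gene, n))
  kBottom <- floor(config$bottomFraction * n)
  kTop <- floor(config$topFraction * n)
  ord <- order(r$score)  # stable: ties keep input order
  label <- rep(NA_real_, n)
  label[ord[seq_len(kBottom)]] <- 1
  label[ord[seq.int(n - kTop + 1L, n)]] <- 0
  out <- r[!is.na(label), , drop = FALSE]
  out$label <- label[!is.na(label)]
  rownames(out) <- NULL
  out
}

#' Protein-reweighted global feature scales
#'
#' Per-feature standard deviations are computed with every row of
#' protein p weighted 1/n_p, so each training protein contributes total
#' weight one and large proteins do not dominate. The returned scale is
#' the reciprocal standard deviation; frequency-flagged features are
#' left unscaled (scale exactly 1), and features are never
#' mean-centred (intercepts absorb location).
#'
#' @param tables Named list of per-protein \linkS4class{FeatureTable}s.
#' @param features Feature names to scale (default: all columns of the
#'   first table).
#' @return Named numeric scale vector (multipliers).
#' @export
fitRescaler <- function(tables, features = NULL) {
  if (is.null(features))
    features <- colnames(featureMatrix(tables[[1L]]))
  freqCols <- unique(unlist(lapply(tables, frequencyColumns)))
  scale <- stats::setNames(rep(1, length(features)), features)
  for (f in setdiff(features, freqCols)) {
    vals <- numeric()
    wts <- numeric()
    for (t in tables) {
      v <- featureMatrix(t)[, f]
      ok <- !is.na(v)
      if (!any(ok)) next
      vals <- c(vals, v[ok])
      wts <- c(wts, rep(1 / sum(ok), sum(ok)))
    }
    if (length(vals) < 2L) {
      warning(sprintf("feature '%s': too few values to scale; scale 1", f))
      next
    }
    mu <- sum(wts * vals) / sum(wts)
    sd <- sqrt(sum(wts * (vals - mu)^2) / sum(wts))
    if (sd == 0) {
      warning(sprintf("feature '%s' has zero weighted sd; scale 1", f))
      next
    }
    scale[f] <- 1 / sd
  }
  scale
}

# Ridge least squares with unpenalised intercept; l2 = 0 gives exact
# ordinary least squares.
.ridgeLS <- function(X, y, l2) {
  Xi <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xi)
  pen <- diag(c(0, rep(l2, p - 1L)), p)
  beta <- solve(crossprod(Xi) + pen, crossprod(Xi, y))
  drop(beta)
}

# Ridge logistic regression by iteratively reweighted least squares.
.ridgeLogistic <- function(X, y, l2, maxIter = 100L, tol = 1e-10) {
  Xi <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xi)
  pen <- diag(c(0, rep(l2, p - 1L)), p)
  beta <- rep(0, p)
  for (it in seq_len(maxIter)) {
    eta <- drop(Xi %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    newBeta <- tryCatch(
      drop(solve(crossprod(Xi, Xi * w) + pen, crossprod(Xi, w * z))),
      error = function(e) beta)
    if (max(abs(newBeta - beta)) < tol) {
      beta <- newBeta
      break
    }
    beta <- newBeta
  }
  names(beta) <- colnames(Xi)
  beta
}

# Align a protein's FeatureTable rows with its DMS records; returns the
# design matrix (selected features, scaled) and the matched record rows.
.alignDesign <- function(table, dms, features, scale) {
  tk <- paste(table@keys$position, table@keys$wt, table@keys$mut)
  dk <- paste(dms@records$position, dms@records$wt, dms@records$mut)
  idx <- match(dk, tk)
  if (anyNA(idx))
    stop(sprintf("gene %s: %d DMS variant(s) missing from the feature table",
                 dms@gene, sum(is.na(idx))))
  X <- featureMatrix(table)[idx, features, drop = FALSE]
  if (anyNA(X))
    stop(sprintf(
      "gene %s: missing feature cells in the design; run imputation first",
      dms@gene))
  X <- sweep(X, 2L, scale[features], `*`)
  list(X = X, records = dms@records)
}

#' Fit a cross-protein transfer model
#'
#' Fits one linear sub-model per training protein on the globally
#' rescaled features (classification: ridge-logistic on
#' percentile-binarised labels; regression: ridge least squares on raw
#' assay scores) and stores them for prediction-averaging at test time.
#' Proteins reduced to a single class by binarisation are excluded with
#' a warning.
#'
#' @param tables Named list of per-protein \linkS4class{FeatureTable}s
#'   (post-imputation: no missing cells in \code{features}).
#' @param dms Named list of \linkS4class{DMSDataset}s, parallel to
#'   \code{tables}.
#' @param features Ordered feature names to use.
#' @param config A \code{\link{trainingConfig}}.
#' @param scale Optional precomputed scale vector (default: fit with
#'   \code{\link{fitRescaler}} on \code{tables}).
#' @return A \linkS4class{CPTModel}.
#' @export
fitCPT <- function(tables, dms, features, config = trainingConfig(),
                   scale = NULL) {
  genes <- names(tables)
  if (is.null(scale)) scale <- fitRescaler(tables, features)
  scale <- scale[features]
  models <- list()
  for (g in genes) {
    al <- .alignDesign(tables[[g]], dms[[g]], features, scale)
    if (config$task == "classification") {
      lab <- binarizeDMS(dms[[g]], config)
      lk <- paste(lab$position, lab$wt, lab$mut)
      rk <- paste(al$records$position, al$records$wt, al$records$mut)
      idx <- match(lk, rk)
      X <- al$X[idx, , drop = FALSE]
      y <- lab$label
      if (length(unique(y)) < 2L) {
        warning(sprintf("gene %s: single class after binarisation; excluded",
                        g))
        next
      }
      beta <- .ridgeLogistic(X, y, config$l2)
    } else {
      beta <- .ridgeLS(al$X, al$records$score, config$l2)
    }
    models[[g]] <- list(coefficients = beta[features],
                        intercept = unname(beta["(Intercept)"]))
  }
  if (!length(models))
    stop("no trainable protein remained after binarisation")
  new("CPTModel", selectedFeatures = features, scale = scale,
      perProteinModels = models, task = config$task,
      config = list(topFraction = config$topFraction,
                    bottomFraction = config$bottomFraction,
                    l2 = config$l2,
                    averageProbabilities = config$averageProbabilities))
}

#' Ensemble prediction for a feature table
#'
#' Averages the per-protein sub-model predictions: predicted
#' probabilities for classification (linear predictors when the model
#' was configured with \code{averageProbabilities = FALSE}), linear
#' predictions for regression. Higher values mean more damaging.
#'
#' @param model A \linkS4class{CPTModel}.
#' @param table A \linkS4class{FeatureTable} with all selected features
#'   present and non-missing.
#' @return Numeric prediction per variant row.
#' @export
predictEnsemble <- function(model, table) {
  feats <- model@selectedFeatures
  X <- featureMatrix(table)
  absent <- setdiff(feats, colnames(X))
  if (length(absent))
    stop(sprintf("feature column(s) %s absent from the table",
                 paste(absent, collapse = ", ")))
  X <- X[, feats, drop = FALSE]
  if (anyNA(X))
    stop("missing feature cells: complete the table with imputation first")
  X <- sweep(X, 2L, model@scale[feats], `*`)
  avgProb <- !identical(model@config$averageProbabilities, FALSE)
  preds <- vapply(model@perProteinModels, function(m) {
    eta <- drop(X %*% m$coefficients) + m$intercept
    if (model@task == "classification" && avgProb)
      stats::plogis(eta)
    else eta
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) preds <- matrix(preds, nrow = 1L)
  rowMeans(preds)
}

#' Leave-one-protein-out folds
#'
#' @param proteins Character vector of protein names (>= 2).
#' @return List of folds, each \code{list(train = ..., validation = ...)};
#'   every protein validates exactly once.
#' @export
lopoFolds <- function(proteins) {
  proteins <- as.character(proteins)
  if (length(proteins) < 2L)
    stop("leave-one-protein-out needs at least 2 proteins")
  lapply(proteins, function(p)
    list(train = setdiff(proteins, p), validation = p))
}

# Mean LOPO validation metric (AUROC for classification, Spearman for
# regression) of a candidate feature set.
.lopoMetric <- function(features, tables, dms, config, scale) {
  folds <- lopoFolds(names(tables))
  vals <- vapply(folds, function(fold) {
    model <- fitCPT(tables[fold$train], dms[fold$train], features,
                    config, scale = scale)
    vt <- tables[[fold$validation]]
    vd <- dms[[fold$validation]]
    tk <- paste(vt@keys$position, vt@keys$wt, vt@keys$mut)
    if (config$task == "classification") {
      lab <- binarizeDMS(vd, config)
      idx <- match(paste(lab$position, lab$wt, lab$mut), tk)
      preds <- predictEnsemble(model, subsetFeatureTable(vt, idx))
      rocAuc(lab$label, preds)
    } else {
      idx <- match(paste(vd@records$position, vd@records$wt,
                         vd@records$mut), tk)
      preds <- predictEnsemble(model, subsetFeatureTable(vt, idx))
      spearmanRho(preds, vd@records$score)
    }
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

.nonEmptySubsets <- function(x) {
  n <- length(x)
  out <- list()
  for (mask in seq_len(2^n - 1L))
    out[[mask]] <- x[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L]
  out
}

#' Two-step leave-one-protein-out feature selection
#'
#' The two protein-homology score columns are always included first.
#' Step one walks the feature categories in fixed order (100-vertebrate
#' alignment, 30-mammal alignment, inverse-folding scores,
#' structure-conditioned scores), exhaustively evaluating every
#' non-empty subset of each non-empty category by mean LOPO validation
#' metric and appending the best subset. Step two greedily appends
#' descriptor features one at a time while the metric strictly
#' improves. Deterministic given the data: metric ties resolve to the
#' earliest candidate in enumeration order.
#'
#' @param tables Named list of per-protein \linkS4class{FeatureTable}s.
#' @param dms Named list of \linkS4class{DMSDataset}s.
#' @param candidates Named list of candidate feature names per category:
#'   \code{homology} (always included), \code{vert100}, \code{mamm30},
#'   \code{inverse_folding}, \code{conditioned}, \code{descriptor}.
#'   Defaults are derived from the first table's column metadata.
#' @param config A \code{\link{trainingConfig}}.
#' @return List with \code{selected} (ordered feature names) and
#'   \code{trace} (data.frame of evaluated steps and metrics).
#' @export
selectFeatures <- function(tables, dms, candidates = NULL,
                           config = trainingConfig()) {
  if (is.null(candidates)) {
    meta <- columnMeta(tables[[1L]])
    candidates <- split(meta$name, meta$category)
  }
  if (is.null(candidates$homology) || !length(candidates$homology))
    stop("candidates must include the homology score columns")
  scale <- fitRescaler(tables)
  selected <- candidates$homology
  trace <- data.frame(step = character(), added = character(),
                      metric = numeric(), stringsAsFactors = FALSE)
  for (cat in c("vert100", "mamm30", "inverse_folding", "conditioned")) {
    pool <- candidates[[cat]]
    if (is.null(pool) || !length(pool)) next
    subsets <- .nonEmptySubsets(pool)
    metrics <- vapply(subsets, function(s)
      .lopoMetric(c(selected, s), tables, dms, config, scale),
      numeric(1))
    best <- which.max(metrics)  # ties -> earliest enumerated subset
    selected <- c(selected, subsets[[best]])
    trace <- rbind(trace, data.frame(
      step = cat, added = paste(subsets[[best]], collapse = "+"),
      metric = metrics[best], stringsAsFactors = FALSE))
  }
  pool <- setdiff(candidates$descriptor, selected)
  current <- .lopoMetric(selected, tables, dms, config, scale)
  while (length(pool)) {
    metrics <- vapply(pool, function(f)
      .lopoMetric(c(selected, f), tables, dms, config, scale),
      numeric(1))
    best <- which.max(metrics)
    if (metrics[best] <= current) break
    selected <- c(selected, pool[best])
    current <- metrics[best]
    trace <- rbind(trace, data.frame(step = "descriptor",
                                     added = pool[best],
                                     metric = current,
                                     stringsAsFactors = FALSE))
    pool <- pool[-best]
  }
  list(selected = selected, trace = trace)
}
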