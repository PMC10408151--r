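#' @import methods
NULL

#' Standard amino-acid alphabet
#'
#' The 20 standard amino-acid one-letter codes, in alphabetical order.
#' Nonstandard residues and ambiguity codes are represented as \code{"X"}
#' throughout the package; \code{"-"} denotes an alignment gap.
#'
#' @format Character vector of length 20.
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.GAP <- "-"
.UNKNOWN <- "X"

#' Query-anchored multiple sequence alignment
#'
#' An alignment whose columns correspond one-to-one to residues of a
#' designated query protein (A2M style: insertions relative to the query
#' must have been removed). Row 1 is always the ungapped query itself.
#' The \code{covered} slot marks query positions that are backed by
#' alignment data; positions dropped during isoform reconciliation
#' (\code{\link{projectToQuery}}) are uncovered and their features flow to
#' KNN imputation downstream.
#'
#' @slot gene Gene/protein identifier.
#' @slot query Ungapped query amino-acid sequence (length L).
#' @slot rows Character vector of aligned rows, each of length L over the
#'   20 amino-acid letters, \code{"-"} (gap) and \code{"X"} (unknown).
#'   Row 1 is the query.
#' @slot source Alignment source label, e.g. \code{"vert100"},
#'   \code{"mamm30"} or \code{"deep"}.
#' @slot covered Logical vector of length L; \code{FALSE} marks columns
#'   with no usable alignment information.
#' @export
setClass("AnchoredMSA",
  representation(gene = "character", query = "character",
                 rows = "character", source = "character",
                 covered = "logical"))

setValidity("AnchoredMSA", function(object) {
  L <- nchar(object@query)
  msg <- character()
  if (length(object@query) != 1L || L < 1L)
    msg <- c(msg, "query must be a single non-empty string")
  if (length(object@rows) < 1L)
    msg <- c(msg, "alignment must contain at least the query row")
  if (any(nchar(object@rows) != L))
    msg <- c(msg, sprintf("all rows must have the query length (%d)", L))
  if (length(object@rows) >= 1L && object@rows[1L] != object@query)
    msg <- c(msg, "row 1 must equal the query")
  if (grepl("-", object@query, fixed = TRUE))
    msg <- c(msg, "query must not contain gaps")
  if (length(object@covered) != L)
    msg <- c(msg, "covered must have one entry per query position")
  bad <- grepl(paste0("[^", paste(AA_STANDARD, collapse = ""), "X-]"),
               object@rows)
  if (any(bad))
    msg <- c(msg, sprintf("row %d contains characters outside the alphabet",
                          which(bad)[1L]))
  if (length(msg)) msg else TRUE
})

#' Construct an AnchoredMSA
#'
#' @param gene Gene identifier.
#' @param rows Character vector of aligned rows; row 1 is the ungapped
#'   query. Lowercase letters are uppercased.
#' @param source Source label (\code{"vert100"}, \code{"mamm30"},
#'   \code{"deep"}, ...).
#' @param covered Optional logical coverage vector (default: all covered).
#' @return An \linkS4class{AnchoredMSA}.
#' @export
AnchoredMSA <- function(gene, rows, source = "vert100", covered = NULL) {
  rows <- toupper(as.character(rows))
  rows <- gsub("\\.", "-", rows)
  query <- rows[1L]
  if (is.null(covered)) covered <- rep(TRUE, nchar(query))
  new("AnchoredMSA", gene = as.character(gene), query = query,
      rows = rows, source = as.character(source), covered = covered)
}

#' @describeIn AnchoredMSA Number of aligned rows (including the query).
#' @param x,object An \code{AnchoredMSA}.
#' @export
msaDepth <- function(x) length(x@rows)

#' @describeIn AnchoredMSA Query length (number of columns).
#' @export
msaLength <- function(x) nchar(x@query)

#' @describeIn AnchoredMSA Characters of one alignment column.
#' @param position 1-based query position.
#' @export
msaColumn <- function(x, position) {
  if (position < 1L || position > msaLength(x))
    stop(sprintf("position %d out of range 1..%d for gene %s",
                 position, msaLength(x), x@gene))
  substr(x@rows, position, position)
}

setMethod("show", "AnchoredMSA", function(object) {
  cat(sprintf("AnchoredMSA [%s] gene=%s: %d rows x %d columns (%d covered)\n",
              object@source, object@gene, msaDepth(object),
              msaLength(object), sum(object@covered)))
})

#' Per-residue structure information
#'
#' Holds the per-residue model confidence (pLDDT, 0-100), the symmetric
#' sidechain-sidechain contact adjacency, and a fragment identifier for
#' proteins whose predicted structure is released as several overlapping
#' fragments. Positions not covered by the fragment carry \code{NA} pLDDT.
#'
#' @slot gene Gene identifier.
#' @slot plddt Numeric vector of per-residue confidences in [0, 100];
#'   \code{NA} where the fragment does not cover the residue.
#' @slot contacts Symmetric logical adjacency matrix (no self-contacts).
#' @slot fragmentId Integer fragment identifier (1 for single-fragment
#'   proteins).
#' @export
setClass("StructureInfo",
  representation(gene = "character", plddt = "numeric",
                 contacts = "matrix", fragmentId = "integer"))

setValidity("StructureInfo", function(object) {
  msg <- character()
  n <- length(object@plddt)
  if (!all(dim(object@contacts) == c(n, n)))
    msg <- c(msg, "contacts must be n x n for n residues")
  else {
    if (!isTRUE(all(object@contacts == t(object@contacts))))
      msg <- c(msg, "contacts must be symmetric")
    if (any(diag(object@contacts)))
      msg <- c(msg, "self-contacts are not allowed")
  }
  p <- object@plddt[!is.na(object@plddt)]
  if (length(p) && (any(p < 0) || any(p > 100)))
    msg <- c(msg, "pLDDT values must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' Construct a StructureInfo
#'
#' @param gene Gene identifier.
#' @param plddt Per-residue confidence values; clamped to [0, 100].
#' @param contacts Logical adjacency matrix, or a 2-column matrix of
#'   contact pairs (symmetrised automatically).
#' @param fragmentId Fragment identifier (default 1).
#' @return A \linkS4class{StructureInfo}.
#' @export
StructureInfo <- function(gene, plddt, contacts, fragmentId = 1L) {
  n <- length(plddt)
  plddt <- pmin(pmax(as.numeric(plddt), 0), 100)
  if (is.matrix(contacts) && ncol(contacts) == 2L && !is.logical(contacts)) {
    adj <- matrix(FALSE, n, n)
    if (nrow(contacts)) {
      ij <- contacts[contacts[, 1L] != contacts[, 2L], , drop = FALSE]
      adj[ij] <- TRUE
      adj[ij[, 2:1, drop = FALSE]] <- TRUE
    }
    contacts <- adj
  }
  diag(contacts) <- FALSE
  new("StructureInfo", gene = as.character(gene), plddt = plddt,
      contacts = contacts, fragmentId = as.integer(fragmentId))
}

setMethod("show", "StructureInfo", function(object) {
  cat(sprintf(
    "StructureInfo gene=%s fragment=%d: %d residues, %d contacts, mean pLDDT %.1f\n",
    object@gene, object@fragmentId, length(object@plddt),
    sum(object@contacts) / 2, mean(object@plddt, na.rm = TRUE)))
})

#' Variants-by-features table with explicit missingness
#'
#' The central container: one row per missense variant (gene, position,
#' wild-type, mutant), one column per named numeric feature. Missing
#' cells are \code{NA} and are completed by weighted-KNN imputation.
#' Column metadata records each feature's category (used by the staged
#' feature-selection procedure) and whether it is a frequency-derived
#' column, which is exempted from global rescaling.
#'
#' @slot keys data.frame with columns \code{gene}, \code{position},
#'   \code{wt}, \code{mut}.
#' @slot features Numeric matrix, rows parallel to \code{keys};
#'   \code{NA} marks a missing cell.
#' @slot columnMeta data.frame with columns \code{name}, \code{category}
#'   (homology | vert100 | mamm30 | inverse_folding | conditioned | site
#'   | descriptor) and \code{frequency} (logical).
#' @export
setClass("FeatureTable",
  representation(keys = "data.frame", features = "matrix",
                 columnMeta = "data.frame"))

setValidity("FeatureTable", function(object) {
  msg <- character()
  if (!all(c("gene", "position", "wt", "mut") %in% names(object@keys)))
    msg <- c(msg, "keys must have columns gene, position, wt, mut")
  if (nrow(object@features) != nrow(object@keys))
    msg <- c(msg, "features must have one row per key")
  if (!identical(colnames(object@features), object@columnMeta$name))
    msg <- c(msg, "columnMeta rows must match feature columns in order")
  if (!all(c("name", "category", "frequency") %in% names(object@columnMeta)))
    msg <- c(msg, "columnMeta needs name, category, frequency")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureTable
#'
#' @param keys Variant key data.frame (see \code{\link{variantKeys}}).
#' @param features Numeric matrix with named columns; \code{NA} = missing.
#' @param categories Named character vector mapping column name to
#'   category; unnamed columns default to \code{"descriptor"}.
#' @param frequency Character vector of column names flagged as
#'   frequency features (exempt from rescaling).
#' @return A \linkS4class{FeatureTable}.
#' @export
FeatureTable <- function(keys, features, categories = character(),
                         frequency = character()) {
  features <- as.matrix(features)
  cn <- colnames(features)
  cat <- ifelse(cn %in% names(categories), categories[cn], "descriptor")
  meta <- data.frame(name = cn, category = unname(cat),
                     frequency = cn %in% frequency,
                     stringsAsFactors = FALSE)
  new("FeatureTable", keys = keys, features = features, columnMeta = meta)
}

#' @describeIn FeatureTable Feature matrix accessor.
#' @param x,object A \code{FeatureTable}.
#' @export
featureMatrix <- function(x) x@features

#' @describeIn FeatureTable Variant keys accessor.
#' @export
variantKeysOf <- function(x) x@keys

#' @describeIn FeatureTable Column metadata accessor.
#' @export
columnMeta <- function(x) x@columnMeta

#' @describeIn FeatureTable Names of frequency-flagged columns.
#' @export
frequencyColumns <- function(x) x@columnMeta$name[x@columnMeta$frequency]

#' @describeIn FeatureTable Subset rows (and optionally columns).
#' @param i Row indices.
#' @param j Optional column names or indices.
#' @export
subsetFeatureTable <- function(x, i, j = NULL) {
  f <- x@features[i, , drop = FALSE]
  m <- x@columnMeta
  if (!is.null(j)) {
    f <- f[, j, drop = FALSE]
    m <- m[match(colnames(f), m$name), , drop = FALSE]
    rownames(m) <- NULL
  }
  new("FeatureTable", keys = x@keys[i, , drop = FALSE], features = f,
      columnMeta = m)
}

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d variants x %d features (%.1f%% missing), %d gene(s)\n",
              nrow(object@keys), ncol(object@features),
              100 * mean(is.na(object@features)),
              length(unique(object@keys$gene))))
})

#' Deep mutational scanning dataset for one protein
#'
#' @slot gene Gene identifier.
#' @slot records data.frame with columns \code{position}, \code{wt},
#'   \code{mut}, \code{score} (real-valued assay fitness).
#' @export
setClass("DMSDataset",
  representation(gene = "character", records = "data.frame"))

setValidity("DMSDataset", function(object) {
  msg <- character()
  r <- object@records
  if (!all(c("position", "wt", "mut", "score") %in% names(r)))
    msg <- c(msg, "records need position, wt, mut, score")
  else {
    key <- paste(r$position, r$wt, r$mut)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate variant keys in DMS records")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DMSDataset
#' @param gene Gene identifier.
#' @param records data.frame with position, wt, mut, score.
#' @return A \linkS4class{DMSDataset}.
#' @export
DMSDataset <- function(gene, records) {
  new("DMSDataset", gene = as.character(gene),
      records = as.data.frame(records))
}

setMethod("show", "DMSDataset", function(object) {
  cat(sprintf("DMSDataset gene=%s: %d variants, score range [%.3g, %.3g]\n",
              object@gene, nrow(object@records),
              min(object@records$score), max(object@records$score)))
})

#' Benign/pathogenic labelled variant set
#'
#' @slot records data.frame with columns \code{gene}, \code{position},
#'   \code{wt}, \code{mut}, \code{label} (0 = benign, 1 = pathogenic).
#' @export
setClass("LabeledVariantSet", representation(records = "data.frame"))

setValidity("LabeledVariantSet", function(object) {
  r <- object@records
  msg <- character()
  if (!all(c("gene", "position", "wt", "mut", "label") %in% names(r)))
    msg <- c(msg, "records need gene, position, wt, mut, label")
  else {
    if (!all(r$label %in% c(0, 1)))
      msg <- c(msg, "labels must be 0 (benign) or 1 (pathogenic)")
    if (anyDuplicated(paste(r$gene, r$position, r$wt, r$mut)))
      msg <- c(msg, "duplicate variant keys")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LabeledVariantSet
#' @param records data.frame with gene, position, wt, mut, label.
#' @return A \linkS4class{LabeledVariantSet}.
#' @export
LabeledVariantSet <- function(records) {
  records <- as.data.frame(records)
  rownames(records) <- NULL
  new("LabeledVariantSet", records = records)
}

setMethod("show", "LabeledVariantSet", function(object) {
  r <- object@records
  cat(sprintf("LabeledVariantSet: %d variants (%d benign / %d pathogenic), %d gene(s)\n",
              nrow(r), sum(r$label == 0), sum(r$label == 1),
              length(unique(r$gene))))
})

#' Fitted cross-protein transfer model
#'
#' One linear (regression) or logistic (classification) sub-model per
#' training protein, all sharing a global feature scale vector; ensemble
#' predictions average the sub-model outputs.
#'
#' @slot selectedFeatures Ordered feature names; always starts with the
#'   two protein-homology score columns.
#' @slot scale Named per-feature divisor-inverse (multiplier); frequency
#'   features carry scale exactly 1.
#' @slot perProteinModels Named list; each element has \code{coefficients}
#'   (named, on the scaled feature space) and \code{intercept}.
#' @slot task \code{"classification"} or \code{"regression"}.
#' @slot config List of training settings used.
#' @export
setClass("CPTModel",
  representation(selectedFeatures = "character", scale = "numeric",
                 perProteinModels = "list", task = "character",
                 config = "list"))

setValidity("CPTModel", function(object) {
  msg <- character()
  if (!object@task %in% c("classification", "regression"))
    msg <- c(msg, "task must be classification or regression")
  if (any(object@scale <= 0))
    msg <- c(msg, "scale entries must be positive")
  if (!identical(names(object@scale), object@selectedFeatures))
    msg <- c(msg, "scale must be named by selectedFeatures")
  ok <- vapply(object@perProteinModels, function(m)
    identical(names(m$coefficients), object@selectedFeatures), logical(1))
  if (length(ok) && !all(ok))
    msg <- c(msg, "sub-model coefficients must be named by selectedFeatures")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CPTModel", function(object) {
  cat(sprintf("CPTModel (%s): %d sub-models [%s], %d features\n",
              object@task, length(object@perProteinModels),
              paste(names(object@perProteinModels), collapse = ", "),
              length(object@selectedFeatures)))
  cat("  features:", paste(object@selectedFeatures, collapse = ", "), "\n")
})

#' Evaluation report
#'
#' @slot globalAuroc Pooled AUROC over all labelled variants.
#' @slot perGeneAuroc Named per-gene AUROC over eligible genes.
#' @slot specAtSens Named specificity at each target sensitivity.
#' @slot spearman Named per-dataset Spearman rank correlation.
#' @slot n Number of labelled variants evaluated.
#' @export
setClass("EvaluationReport",
  representation(globalAuroc = "numeric", perGeneAuroc = "numeric",
                 specAtSens = "numeric", spearman = "numeric",
                 n = "integer"))

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport (n=%d): global AUROC %.3f, %d eligible genes (mean AUROC %.3f)\n",
              object@n, object@globalAuroc, length(object@perGeneAuroc),
              mean(object@perGeneAuroc)))
  for (s in names(object@specAtSens))
    cat(sprintf("  specificity at %s sensitivity: %.3f\n", s,
                object@specAtSens[[s]]))
  if (length(object@spearman))
    cat(sprintf("  mean Spearman over %d dataset(s): %.3f\n",
                length(object@spearman), mean(object@spearman)))
})
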