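#' Run code with a locally seeded RNG
#'
#' All generator randomness flows through one seeded RNG; the global
#' RNG state is restored afterwards.
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return Value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic gene-family generator settings
#'
#' The generator emulates the study conditions of a small training
#' family assayed with one fitness readout: a handful of proteins, a
#' shallow 100-row vertebrate and 30-row mammal alignment plus a deeper
#' alignment per gene, a compact predicted structure with per-residue
#' confidence, external predictor score columns, and a DMS table whose
#' scores are a per-protein affine transform of a linear latent fitness
#' (mirroring the between-protein batch effects that motivate the
#' per-protein-model ensemble).
#'
#' @param seed Integer seed; identical seeds give identical bundles.
#' @param nGenes Number of genes (default 6: five training proteins
#'   plus one held-out, as in a LOPO study).
#' @param lengthRange Protein length range (default 60-90 residues).
#' @param msaDepths Named depths for the three alignment sources
#'   (default vert100 = 100, mamm30 = 30, deep = 120 rows).
#' @param conservationRange Per-position conservation strength range;
#'   each position draws its row-level query-retention probability
#'   uniformly from it.
#' @param gapRate Probability that a non-conserved alignment cell is a
#'   gap (default 0.08).
#' @param contactCutoffA Distance cutoff on the synthetic backbone
#'   chain defining contacts (default 6.0; one pseudo-atom per residue
#'   3.8 apart along a random chain).
#' @param mutsPerPosition Mutant amino acids drawn per position
#'   (default 3).
#' @param latentWeights Named generative coefficients over feature
#'   columns; the latent fitness is their inner product with the
#'   realised feature values (higher = more fit).
#' @param offsetSd SD of the per-protein additive batch offset.
#' @param scaleRange Range of the positive per-protein multiplicative
#'   batch factor.
#' @param noiseSd DMS noise SD, expressed relative to the per-protein
#'   latent SD (default 0.2; 0 gives noise-free assays).
#' @param labelFraction Per-gene fraction of lowest-latent variants
#'   labelled pathogenic (default 0.35).
#' @return List of class \code{"GeneratorConfig"}.
#' @export
generatorConfig <- function(seed = 1L, nGenes = 6L,
                            lengthRange = c(60L, 90L),
                            msaDepths = c(vert100 = 100L, mamm30 = 30L,
                                          deep = 120L),
                            conservationRange = c(0.30, 0.98),
                            gapRate = 0.08, contactCutoffA = 6.0,
                            mutsPerPosition = 3L,
                            latentWeights = c(
                              vert100_wt_freq_log = -1.5,
                              mamm30_mut_freq_log = 1.0,
                              esm_llr = 1.0,
                              eve_logp = 0.8,
                              mpnn_llr = 0.5),
                            offsetSd = 0.5,
                            scaleRange = c(0.8, 1.3),
                            noiseSd = 0.2, labelFraction = 0.35) {
  if (nGenes < 1L || any(msaDepths < 2L))
    stop("infeasible generator config: need >= 1 gene and depths >= 2")
  if (min(lengthRange) < 5L)
    stop("proteins must have at least 5 residues")
  structure(list(seed = as.integer(seed), nGenes = as.integer(nGenes),
                 lengthRange = lengthRange, msaDepths = msaDepths,
                 conservationRange = conservationRange,
                 gapRate = gapRate, contactCutoffA = contactCutoffA,
                 mutsPerPosition = as.integer(mutsPerPosition),
                 latentWeights = latentWeights, offsetSd = offsetSd,
                 scaleRange = scaleRange, noiseSd = noiseSd,
                 labelFraction = labelFraction),
            class = "GeneratorConfig")
}

.generateMsa <- function(gene, query, conservation, depth, gapRate,
                         source) {
  L <- nchar(query)
  qChars <- strsplit(query, "")[[1L]]
  rows <- character(depth)
  rows[1L] <- query
  for (r in seq_len(depth)[-1L]) {
    keep <- stats::runif(L) < conservation
    cells <- qChars
    nMut <- sum(!keep)
    if (nMut) {
      gap <- stats::runif(nMut) < gapRate
      repl <- sample(AA_STANDARD, nMut, replace = TRUE)
      repl[gap] <- "-"
      cells[!keep] <- repl
    }
    rows[r] <- paste(cells, collapse = "")
  }
  AnchoredMSA(gene = gene, rows = rows, source = source)
}

.generateStructure <- function(gene, L, cutoffA) {
  # compact random chain: consecutive pseudo-atoms 3.8 apart, direction
  # biased back toward the origin so the chain folds on itself
  coords <- matrix(0, L, 3L)
  for (i in seq_len(L)[-1L]) {
    dir <- stats::rnorm(3L) - 0.12 * coords[i - 1L, ]
    dir <- dir / sqrt(sum(dir^2))
    coords[i, ] <- coords[i - 1L, ] + 3.8 * dir
  }
  contacts <- extractContacts(coords, contactSpec(cutoffA = cutoffA))
  degree <- rowSums(contacts)
  plddt <- 45 + 50 * degree / max(max(degree), 1L) +
    stats::rnorm(L, 0, 3)
  StructureInfo(gene = gene, plddt = pmin(pmax(plddt, 0), 100),
                contacts = contacts)
}

#' Generate a complete synthetic gene family
#'
#' Produces internally consistent alignments, structures, external
#' predictor score columns, DMS tables and benign/pathogenic labels
#' with known generative structure: external scores are noisy monotone
#' functions of a conservation/structure-derived fitness axis; the DMS
#' score of each variant is a per-protein affine transform of the
#' linear latent \code{latentWeights . features} plus Gaussian noise;
#' labels threshold the noise-free latent within each gene.
#'
#' @param config A \code{\link{generatorConfig}}.
#' @return List of class \code{"CPTFamily"} with elements
#'   \code{genes}, \code{queries}, \code{msas} (per source, per gene),
#'   \code{structures}, \code{scoreTables} (esm_llr, eve_logp,
#'   mpnn_llr), \code{dms}, \code{labels}, \code{truth} and
#'   \code{config}.
#' @export
generateFamily <- function(config = generatorConfig()) {
  withSeed(config$seed, {
    genes <- sprintf("G%02d", seq_len(config$nGenes))
    queries <- character()
    msas <- list(vert100 = list(), mamm30 = list(), deep = list())
    structures <- list()
    keysList <- list()
    featList <- list()
    truth <- list(latentWeights = config$latentWeights,
                  offsets = numeric(), scales = numeric(),
                  thresholds = numeric(), latent = list())
    esm <- eve <- mpnn <- dmsTabs <- labTabs <- list()
    for (g in genes) {
      L <- sample(seq.int(config$lengthRange[1L], config$lengthRange[2L]),
                  1L)
      query <- paste(sample(AA_STANDARD, L, replace = TRUE),
                     collapse = "")
      queries[g] <- query
      conservation <- stats::runif(L, config$conservationRange[1L],
                                   config$conservationRange[2L])
      for (src in names(config$msaDepths))
        msas[[src]][[g]] <- .generateMsa(g, query, conservation,
                                         config$msaDepths[[src]],
                                         config$gapRate, src)
      structures[[g]] <- .generateStructure(g, L, config$contactCutoffA)
      qChars <- strsplit(query, "")[[1L]]
      muts <- lapply(seq_len(L), function(p)
        sample(setdiff(AA_STANDARD, qChars[p]), config$mutsPerPosition))
      keys <- variantKeys(
        gene = g,
        position = rep(seq_len(L), each = config$mutsPerPosition),
        wt = rep(qChars, each = config$mutsPerPosition),
        mut = unlist(muts))
      keysList[[g]] <- keys
      cons <- cbind(
        conservationFeatures(msas$vert100[[g]], keys),
        conservationFeatures(msas$mamm30[[g]], keys))
      struct <- structureFeatures(structures[[g]], msas$deep[[g]], keys)
      # fitness axis from conservation + burial; external predictors are
      # noisy monotone readouts of it
      damage <- 2 * cons[, "vert100_wt_freq_log"] -
        2 * cons[, "mamm30_mut_freq_log"] +
        0.02 * ifelse(is.na(struct[, "contact_count"]), 0,
                      struct[, "contact_count"])
      z <- -(damage - mean(damage)) / max(stats::sd(damage), 1e-8)
      n <- nrow(keys)
      ext <- cbind(esm_llr = 0.9 * z + stats::rnorm(n, 0, 0.30),
                   eve_logp = 0.8 * z + stats::rnorm(n, 0, 0.45),
                   mpnn_llr = 0.6 * z + stats::rnorm(n, 0, 0.60))
      feats <- cbind(cons, struct, ext)
      featList[[g]] <- feats
      w <- config$latentWeights
      absent <- setdiff(names(w), colnames(feats))
      if (length(absent))
        stop(sprintf("latent weight on unknown feature '%s'", absent[1L]))
      latent <- drop(feats[, names(w), drop = FALSE] %*% w)
      if (anyNA(latent))
        stop("latent weights must load on fully observed features")
      a <- stats::rnorm(1L, 0, config$offsetSd)
      b <- stats::runif(1L, config$scaleRange[1L], config$scaleRange[2L])
      noise <- stats::rnorm(n, 0, config$noiseSd * stats::sd(latent))
      score <- a + b * latent + noise
      thr <- stats::quantile(latent, config$labelFraction, names = FALSE)
      truth$offsets[g] <- a
      truth$scales[g] <- b
      truth$thresholds[g] <- thr
      truth$latent[[g]] <- latent
      esm[[g]] <- data.frame(keys, value = ext[, "esm_llr"])
      eve[[g]] <- data.frame(keys, value = ext[, "eve_logp"])
      mpnn[[g]] <- data.frame(keys, value = ext[, "mpnn_llr"])
      dmsTabs[[g]] <- DMSDataset(g, data.frame(
        keys[, c("position", "wt", "mut")], score = score))
      labTabs[[g]] <- data.frame(keys,
                                 label = as.numeric(latent < thr))
    }
    truth$features <- featList
    structure(list(
      genes = genes, queries = queries, msas = msas,
      structures = structures,
      scoreTables = list(esm_llr = do.call(rbind, esm),
                         eve_logp = do.call(rbind, eve),
                         mpnn_llr = do.call(rbind, mpnn)),
      dms = dmsTabs,
      labels = LabeledVariantSet(do.call(rbind, labTabs)),
      truth = truth, config = config), class = "CPTFamily")
  })
}

#' @export
print.CPTFamily <- function(x, ...) {
  cat(sprintf("CPTFamily: %d genes (%s), %d variants, seed %d\n",
              length(x$genes), paste(x$genes, collapse = ", "),
              nrow(x$labels@records), x$config$seed))
  invisible(x)
}

#' Generative ground truth of a synthetic family
#'
#' @param bundle A \code{\link{generateFamily}} bundle.
#' @return List with the latent weights, per-gene label thresholds and
#'   latent values, and per-protein affine batch parameters.
#' @export
groundTruth <- function(bundle) bundle$truth

#' Write a synthetic family to disk in the standard formats
#'
#' Aligned FASTA per gene and source, contact TSV + pLDDT per gene,
#' keyed score TSVs, DMS TSVs, a label TSV and the generator seed.
#'
#' @param bundle A \code{\link{generateFamily}} bundle.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeFamily <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (src in names(bundle$msas))
    for (g in names(bundle$msas[[src]]))
      writeAnchoredMSA(bundle$msas[[src]][[g]],
                       file.path(dir, sprintf("%s_%s.fasta", g, src)))
  for (g in names(bundle$structures))
    writeStructure(bundle$structures[[g]],
                   file.path(dir, sprintf("%s_contacts.tsv", g)),
                   file.path(dir, sprintf("%s_plddt.txt", g)))
  for (nm in names(bundle$scoreTables))
    writeScoreTable(bundle$scoreTables[[nm]],
                    file.path(dir, sprintf("scores_%s.tsv", nm)))
  for (g in names(bundle$dms))
    writeScoreTable(data.frame(gene = g, bundle$dms[[g]]@records),
                    file.path(dir, sprintf("%s_dms.tsv", g)))
  writeScoreTable(bundle$labels@records, file.path(dir, "labels.tsv"))
  jsonlite::write_json(list(genes = bundle$genes,
                            seed = bundle$config$seed),
                       file.path(dir, "family.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a written synthetic family back from disk
#'
#' Inverse of \code{\link{writeFamily}} for the data components
#' (alignments, structures, score tables, DMS tables, labels).
#'
#' @param dir Directory written by \code{\link{writeFamily}}.
#' @return List with msas, structures, scoreTables, dms and labels.
#' @export
readFamily <- function(dir) {
  info <- jsonlite::read_json(file.path(dir, "family.json"),
                              simplifyVector = TRUE)
  genes <- info$genes
  msas <- list()
  for (src in c("vert100", "mamm30", "deep")) {
    msas[[src]] <- list()
    for (g in genes)
      msas[[src]][[g]] <- readAnchoredMSA(
        file.path(dir, sprintf("%s_%s.fasta", g, src)), source = src,
        gene = g)
  }
  structures <- list()
  for (g in genes)
    structures[[g]] <- readStructure(
      file.path(dir, sprintf("%s_contacts.tsv", g)),
      format = "contacts",
      plddt = file.path(dir, sprintf("%s_plddt.txt", g)), gene = g,
      nResidues = msaLength(msas$vert100[[g]]))
  scoreTables <- list()
  for (nm in c("esm_llr", "eve_logp", "mpnn_llr"))
    scoreTables[[nm]] <- readScoreTable(
      file.path(dir, sprintf("scores_%s.tsv", nm)))
  dms <- list()
  for (g in genes)
    dms[[g]] <- readDMSTable(file.path(dir, sprintf("%s_dms.tsv", g)))
  labels <- readLabelTable(file.path(dir, "labels.tsv"))
  list(genes = genes, msas = msas, structures = structures,
       scoreTables = scoreTables, dms = dms, labels = labels)
}
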