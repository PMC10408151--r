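#' Read a query-anchored MSA from aligned FASTA
#'
#' The first record is taken as the query and must contain no gaps;
#' all records must share one length. Lowercase letters are uppercased
#' and \code{"."} gaps converted to \code{"-"}.
#'
#' @param path Aligned FASTA file.
#' @param source Source label stored on the object.
#' @param gene Gene identifier; defaults to the first record's name.
#' @return An \linkS4class{AnchoredMSA}.
#' @export
readAnchoredMSA <- function(path, source = "vert100", gene = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) < 1L)
    stop(sprintf("%s: no FASTA records", path))
  rows <- toupper(gsub("\\.", "-", as.character(aa)))
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L)
    stop(sprintf("%s: ragged alignment; record '%s' has length %d, expected %d",
                 path, names(aa)[which(lens != lens[1L])[1L]],
                 lens[lens != lens[1L]][1L], lens[1L]))
  if (grepl("-", rows[1L], fixed = TRUE))
    stop(sprintf("%s: query record '%s' contains gaps", path, names(aa)[1L]))
  if (is.null(gene)) gene <- sub("\\s.*$", "", names(aa)[1L])
  AnchoredMSA(gene = gene, rows = unname(rows), source = source)
}

#' Write an AnchoredMSA to aligned FASTA
#'
#' @param msa An \linkS4class{AnchoredMSA}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeAnchoredMSA <- function(msa, path) {
  aa <- Biostrings::AAStringSet(msa@rows)
  names(aa) <- c(msa@gene,
                 sprintf("%s_row%d", msa@gene, seq_along(msa@rows)[-1L]))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read per-residue structure information
#'
#' Accepts either a PDB/mmCIF atomic model (per-residue confidence in the
#' B-factor column, as released by structure predictors) or a plain-text
#' contact list. For atomic models, sidechain-sidechain contacts are
#' derived with \code{\link{extractContacts}}. For the TSV dialect the
#' file has columns \code{pos_i}, \code{pos_j} (one contact pair per
#' line) and a companion pLDDT file/vector must be supplied.
#'
#' @param path PDB file, or contact TSV.
#' @param format \code{"auto"} (by extension), \code{"pdb"} or
#'   \code{"contacts"}.
#' @param plddt For \code{format = "contacts"}: numeric vector of
#'   per-residue confidences, or path to a one-column text file.
#' @param gene Gene identifier (default: file basename).
#' @param nResidues For contact TSVs: protein length; defaults to the
#'   larger of \code{length(plddt)} and the maximum contact index.
#' @param spec \link{contactSpec} used for atomic models.
#' @param fragmentId Fragment identifier.
#' @return A \linkS4class{StructureInfo} with symmetrised contacts and
#'   pLDDT clamped to [0, 100].
#' @export
readStructure <- function(path, format = c("auto", "pdb", "contacts"),
                          plddt = NULL, gene = NULL, nResidues = NULL,
                          spec = contactSpec(), fragmentId = 1L) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(pdb|ent|cif)$", path, ignore.case = TRUE))
      "pdb" else "contacts"
  if (is.null(gene))
    gene <- sub("\\.[^.]*$", "", basename(path))
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path)
    atoms <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM") &
                        !is.na(pdb$atom$resno), , drop = FALSE]
    atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
    if (!nrow(atoms)) stop(sprintf("%s: no ATOM records", path))
    if (all(is.na(atoms$b)))
      stop(sprintf("%s: no per-residue confidence in the B-factor column",
                   path))
    resno <- sort(unique(atoms$resno))
    n <- max(resno)
    plddtVec <- rep(NA_real_, n)
    sidechains <- vector("list", n)
    for (r in resno) {
      a <- atoms[atoms$resno == r, , drop = FALSE]
      plddtVec[r] <- a$b[1L]
      sc <- a[!a$elety %in% c("N", "CA", "C", "O", "OXT") &
                !grepl("^H", a$elety), , drop = FALSE]
      sidechains[[r]] <- as.matrix(sc[, c("x", "y", "z"), drop = FALSE])
    }
    contacts <- extractContacts(sidechains, spec = spec)
    StructureInfo(gene = gene, plddt = plddtVec, contacts = contacts,
                  fragmentId = fragmentId)
  } else {
    tab <- utils::read.table(path, header = FALSE, col.names = c("i", "j"))
    if (is.character(plddt) && length(plddt) == 1L)
      plddt <- scan(plddt, quiet = TRUE)
    if (is.null(plddt))
      stop(sprintf("%s: contact lists need a companion pLDDT vector", path))
    if (is.null(nResidues))
      nResidues <- max(length(plddt), tab$i, tab$j, 0L)
    if (length(plddt) < nResidues)
      plddt <- c(plddt, rep(NA_real_, nResidues - length(plddt)))
    StructureInfo(gene = gene, plddt = plddt,
                  contacts = cbind(tab$i, tab$j), fragmentId = fragmentId)
  }
}

#' Write a StructureInfo as a contact TSV plus pLDDT file
#'
#' @param structure A \linkS4class{StructureInfo}.
#' @param contactPath Output contact TSV (\code{pos_i<TAB>pos_j}, each
#'   unordered pair once).
#' @param plddtPath Output one-value-per-line pLDDT file.
#' @return \code{contactPath}, invisibly.
#' @export
writeStructure <- function(structure, contactPath, plddtPath) {
  adj <- structure@contacts
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  utils::write.table(idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE],
                     contactPath, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(format(structure@plddt, trim = TRUE, digits = 15), plddtPath)
  invisible(contactPath)
}

.readKeyedTable <- function(path, valueCol) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(gene = "character",
                                          wt = "character",
                                          mut = "character"))
  need <- c("gene", "position", "wt", "mut", valueCol)
  if (!all(need %in% names(tab)))
    stop(sprintf("%s: expected header with columns %s", path,
                 paste(need, collapse = ", ")))
  if (nrow(tab)) {
    v <- tab[[valueCol]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v) & v != "NA")
      if (length(bad))
        stop(sprintf("%s: non-numeric %s '%s' at row %d", path, valueCol,
                     v[bad[1L]], bad[1L]))
      tab[[valueCol]] <- parsed
    }
    ks <- paste(tab$gene, tab$position, tab$wt, tab$mut, sep = "|")
    if (anyDuplicated(ks))
      stop(sprintf("%s: duplicate variant key %s", path,
                   ks[duplicated(ks)][1L]))
  }
  tab
}

#' Read a variant score table
#'
#' TSV with header \code{gene position wt mut value} (a different value
#' column name can be given). Duplicate keys and non-numeric values are
#' rejected with located errors.
#'
#' @param path TSV file.
#' @param column Value column name (default \code{"value"}).
#' @return data.frame with gene, position, wt, mut, value columns.
#' @export
readScoreTable <- function(path, column = "value") {
  tab <- .readKeyedTable(path, column)
  tab[, c("gene", "position", "wt", "mut", column)]
}

#' Write a variant score table
#' @param tab data.frame with gene, position, wt, mut and a value column.
#' @param path Output TSV.
#' @return \code{path}, invisibly.
#' @export
writeScoreTable <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a DMS assay table
#'
#' TSV with header \code{gene position wt mut score}; all rows must share
#' one gene.
#'
#' @param path TSV file.
#' @return A \linkS4class{DMSDataset}.
#' @export
readDMSTable <- function(path) {
  tab <- .readKeyedTable(path, "score")
  genes <- unique(tab$gene)
  if (length(genes) != 1L)
    stop(sprintf("%s: DMS table must contain exactly one gene (found %d)",
                 path, length(genes)))
  DMSDataset(gene = genes, records = tab[, c("position", "wt", "mut",
                                             "score")])
}

#' Read a benign/pathogenic label table
#'
#' TSV with header \code{gene position wt mut label}; labels are 0
#' (benign) or 1 (pathogenic).
#'
#' @param path TSV file.
#' @return A \linkS4class{LabeledVariantSet}.
#' @export
readLabelTable <- function(path) {
  tab <- .readKeyedTable(path, "label")
  LabeledVariantSet(tab[, c("gene", "position", "wt", "mut", "label")])
}

#' Read an amino-acid descriptor table
#'
#' CSV with a first column of amino-acid one-letter codes followed by
#' named numeric scales; exactly the 20 standard letters must each appear
#' once.
#'
#' @param path CSV file.
#' @return Numeric matrix, 20 rows named by amino-acid letter.
#' @export
readDescriptorTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  aa <- toupper(tab[[1L]])
  dup <- aa[duplicated(aa)]
  if (length(dup))
    stop(sprintf("%s: duplicate descriptor rows for '%s'", path, dup[1L]))
  missing <- setdiff(AA_STANDARD, aa)
  if (length(missing))
    stop(sprintf("%s: missing descriptor row for amino acid '%s'", path,
                 missing[1L]))
  extra <- setdiff(aa, AA_STANDARD)
  if (length(extra))
    stop(sprintf("%s: unexpected letter '%s' in descriptor table", path,
                 extra[1L]))
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop(sprintf("%s: descriptor values must be numeric", path))
  rownames(m) <- aa
  m[AA_STANDARD, , drop = FALSE]
}

#' Write an amino-acid descriptor table
#' @param table 20-row matrix named by amino-acid letter.
#' @param path Output CSV.
#' @return \code{path}, invisibly.
#' @export
writeDescriptorTable <- function(table, path) {
  utils::write.csv(data.frame(aa = rownames(table), table,
                              check.names = FALSE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default amino-acid descriptor table
#'
#' A compact set of published amino-acid indices (hydropathy, volume,
#' polarity, isoelectric point, flexibility, bulkiness and related
#' scales) drawn from the aaindex collection, covering the property
#' classes (charge, polarity, hydrophobicity, size, flexibility) that
#' descriptor featurisations encode. Any user table read with
#' \code{\link{readDescriptorTable}} can be used instead.
#'
#' @param indices aaindex accession codes to include.
#' @return 20 x length(indices) numeric matrix, rows named by letter.
#' @export
defaultDescriptorTable <- function(indices = c(
    "KYTJ820101",  # Kyte-Doolittle hydropathy
    "GRAR740102",  # Grantham polarity
    "GRAR740103",  # Grantham volume
    "ZIMJ680104",  # isoelectric point
    "BHAR880101",  # average flexibility
    "ZIMJ680102",  # bulkiness
    "FAUJ880103",  # normalized van der Waals volume
    "CHOP780201"   # helix propensity
  )) {
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  aaindex <- env$aaindex
  three <- c(A = "Ala", C = "Cys", D = "Asp", E = "Glu", F = "Phe",
             G = "Gly", H = "His", I = "Ile", K = "Lys", L = "Leu",
             M = "Met", N = "Asn", P = "Pro", Q = "Gln", R = "Arg",
             S = "Ser", T = "Thr", V = "Val", W = "Trp", Y = "Tyr")
  m <- vapply(indices, function(id) {
    v <- aaindex[[id]]$I
    unname(v[three[AA_STANDARD]])
  }, numeric(20L))
  rownames(m) <- AA_STANDARD
  m
}

#' Serialize a CPT model to JSON
#'
#' Models are stored as explicit named coefficients in JSON (schema
#' version 1); no binary serialization is used.
#'
#' @param model A \linkS4class{CPTModel}.
#' @param path Output JSON file.
#' @return \code{path}, invisibly.
#' @export
writeCPTModel <- function(model, path) {
  obj <- list(
    schema = "cpt-model/1",
    task = model@task,
    selected_features = model@selectedFeatures,
    scale = as.list(model@scale),
    config = model@config,
    per_protein_models = lapply(model@perProteinModels, function(m)
      list(coefficients = as.list(m$coefficients),
           intercept = m$intercept)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a CPT model from JSON
#' @param path JSON file written by \code{\link{writeCPTModel}}.
#' @return A \linkS4class{CPTModel}.
#' @export
readCPTModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$schema, "cpt-model/1"))
    stop(sprintf("%s: unknown model schema '%s'", path, obj$schema))
  feats <- unlist(obj$selected_features)
  scale <- unlist(obj$scale)[feats]
  models <- lapply(obj$per_protein_models, function(m) {
    co <- unlist(m$coefficients)[feats]
    list(coefficients = co, intercept = m$intercept)
  })
  new("CPTModel", selectedFeatures = feats, scale = scale,
      perProteinModels = models, task = obj$task,
      config = lapply(obj$config, identity))
}
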