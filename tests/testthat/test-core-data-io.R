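test_that("aligned FASTA reading anchors the query and validates shape", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">q", "ACD", ">r1", "A-D"), path)
  msa <- readAnchoredMSA(path, source = "vert100")
  expect_s4_class(msa, "AnchoredMSA")
  expect_equal(msaLength(msa), 3)
  expect_equal(msaDepth(msa), 2)
  expect_equal(msa@query, "ACD")

  writeLines(c(">q", "ACD", ">r1", "A-DE"), path)
  expect_error(readAnchoredMSA(path), "ragged")

  writeLines(c(">q", "A-D", ">r1", "ACD"), path)
  expect_error(readAnchoredMSA(path), "query.*gaps")
})

test_that("MSA write -> read round trip is identity", {
  msa <- makeMsa(c("ACDEF", "AC-EF", "GCDEX"))
  path <- withr::local_tempfile(fileext = ".fasta")
  writeAnchoredMSA(msa, path)
  back <- readAnchoredMSA(path, source = msa@source, gene = msa@gene)
  expect_equal(back@rows, msa@rows)
  expect_equal(back@query, msa@query)
})

test_that("PDB parsing extracts per-residue confidence and contacts", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeToyPDB(path, c(90, 80, 70))
  st <- readStructure(path)
  expect_equal(st@plddt, c(90, 80, 70))
  # CB atoms 3.8 apart: within the 4.5 A cutoff for adjacent residues
  expect_true(st@contacts[1, 2])
  expect_false(st@contacts[1, 3])

  writeToyPDB(path, c(90, 80, 70), dropBfactor = TRUE)
  expect_error(readStructure(path), "B-factor|confidence")
})

test_that("contact TSVs are symmetrised on read", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("2\t5", path)
  st <- readStructure(path, format = "contacts",
                      plddt = c(90, 90, 90, 90, 90))
  expect_true(st@contacts[2, 5])
  expect_true(st@contacts[5, 2])
  expect_equal(sum(st@contacts), 2)
})

test_that("structure write -> read round trip preserves the object", {
  st <- StructureInfo("G1", plddt = c(88, 72, 95, 40),
                      contacts = rbind(c(1, 3), c(2, 4)))
  cp <- withr::local_tempfile(fileext = ".tsv")
  pp <- withr::local_tempfile(fileext = ".txt")
  writeStructure(st, cp, pp)
  back <- readStructure(cp, format = "contacts", plddt = pp, gene = "G1")
  expect_equal(back@contacts, st@contacts)
  expect_equal(back@plddt, st@plddt)
})

test_that("score tables reject duplicates and locate bad values", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tposition\twt\tmut\tvalue",
               "G1\t3\tA\tV\t-1.5", "G1\t4\tC\tW\t0.25"), path)
  tab <- readScoreTable(path)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$value, c(-1.5, 0.25))

  writeLines(c("gene\tposition\twt\tmut\tvalue",
               "G1\t3\tA\tV\t-1.5", "G1\t3\tA\tV\t0.2"), path)
  expect_error(readScoreTable(path), "duplicate")

  writeLines(c("gene\tposition\twt\tmut\tvalue",
               "G1\t3\tA\tV\toops"), path)
  expect_error(readScoreTable(path), "row 1")

  writeLines("gene\tposition\twt\tmut\tvalue", path)
  expect_equal(nrow(readScoreTable(path)), 0)
})

test_that("descriptor tables must cover the 20 letters exactly once", {
  tab <- matrix(rnorm(60), 20, dimnames = list(AA_STANDARD,
                                               c("s1", "s2", "s3")))
  path <- withr::local_tempfile(fileext = ".csv")
  writeDescriptorTable(tab, path)
  back <- readDescriptorTable(path)
  expect_equal(back, tab)

  writeDescriptorTable(tab[-which(AA_STANDARD == "W"), ], path)
  expect_error(readDescriptorTable(path), "'W'")

  dup <- rbind(tab, tab["A", , drop = FALSE])
  rownames(dup)[21] <- "A"
  writeDescriptorTable(dup, path)
  expect_error(readDescriptorTable(path), "duplicate.*'A'")
})

test_that("variant keys are validated against the query sequence", {
  expect_silent(variantKeys("G1", 3, "A", "V"))
  expect_error(variantKeys("G1", 0, "A", "V"), ">= 1")
  expect_error(variantKeys("G1", 3, "A", "A"), "differ")
  expect_error(variantKeys("G1", 2, "A", "V",
                           query = c(G1 = "MCD")), "mismatch")
  expect_silent(variantKeys("G1", 2, "C", "V", query = c(G1 = "MCD")))
})

test_that("model JSON serialisation round trips", {
  fam <- plantedFamily(nGenes = 2, n = 40,
                       coef = c(f1 = 2, f2 = -1, f3 = 0.5))
  model <- fitCPT(fam$tables, fam$dms, c("f1", "f2", "f3"),
                  trainingConfig(task = "regression"))
  path <- withr::local_tempfile(fileext = ".json")
  writeCPTModel(model, path)
  back <- readCPTModel(path)
  expect_equal(back@selectedFeatures, model@selectedFeatures)
  expect_equal(back@scale, model@scale)
  expect_equal(back@task, model@task)
  for (g in names(model@perProteinModels)) {
    expect_equal(back@perProteinModels[[g]]$coefficients,
                 model@perProteinModels[[g]]$coefficients)
    expect_equal(back@perProteinModels[[g]]$intercept,
                 model@perProteinModels[[g]]$intercept)
  }
  tab <- fam$tables[[1]]
  expect_equal(predictEnsemble(back, tab), predictEnsemble(model, tab))
})

test_that("DMS and label tables round trip and validate", {
  dms <- DMSDataset("G1", data.frame(position = 1:12,
                                     wt = rep("A", 12),
                                     mut = rep(c("V", "W"), 6),
                                     score = rnorm(12)))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeScoreTable(data.frame(gene = "G1", dms@records), path)
  back <- readDMSTable(path)
  expect_equal(back@records$score, dms@records$score)
  expect_equal(back@gene, "G1")

  lab <- LabeledVariantSet(data.frame(gene = "G1", position = 1:4,
                                      wt = "A", mut = c("V", "W", "Y", "C"),
                                      label = c(0, 1, 1, 0)))
  writeScoreTable(lab@records, path)
  expect_equal(readLabelTable(path)@records$label, c(0, 1, 1, 0))
  expect_error(LabeledVariantSet(data.frame(
    gene = "G1", position = 1, wt = "A", mut = "V", label = 2)))
})
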